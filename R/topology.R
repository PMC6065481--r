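# 3-D digital topology: simple points, Euler characteristic, connected
# components, and EDT-based binary morphology.

# exact squared Euclidean distance to the seed set, in physical units
edt_distance <- function(seed, spacing = c(1, 1, 1), seed_cost = NULL) {
  f <- array(1e30, dim(seed))
  if (is.null(seed_cost)) f[seed != 0] <- 0
  else f[seed != 0] <- pmax(seed_cost[seed != 0], 0)^2
  d2 <- cpp_edt_sq(as.numeric(f), dim(seed), as.numeric(spacing))
  array(sqrt(pmin(d2, 1e30)), dim(seed))
}

#' Test whether a voxel is a simple point
#'
#' A voxel is simple when flipping it between foreground and background
#' changes neither the local topology of the foreground nor that of the
#' background: the topological numbers of both sets, computed on the
#' geodesic neighborhood appropriate to the chosen digital connectivity
#' pair, equal one.
#'
#' @param neighborhood a 3x3x3 binary array (or length-27 vector in
#'   column-major order, or an n x 27 matrix of neighborhoods) giving the
#'   foreground around the candidate voxel; the center value is ignored.
#' @param connectivity_pair foreground/background adjacency pair, one of
#'   `c(6,26)`, `c(26,6)`, `c(6,18)`, `c(18,6)`.
#' @return Logical (vector for matrix input).
#' @export
is_simple_point <- function(neighborhood, connectivity_pair = c(6, 26)) {
  pair <- check_connectivity_pair(connectivity_pair)
  if (is.matrix(neighborhood) && ncol(neighborhood) == 27L) {
    m <- matrix(as.integer(neighborhood != 0), nrow(neighborhood), 27L)
  } else {
    v <- as.integer(as.vector(neighborhood) != 0)
    if (length(v) != 27L)
      cx_stop("neighborhood must contain 27 voxels", "cx_validation_error")
    m <- matrix(v, 1L, 27L)
  }
  res <- cpp_is_simple_batch(m, pair[1], pair[2])
  if (nrow(m) == 1L) res[1L] else res
}

#' Euler characteristic of a binary volume
#'
#' Counts vertices, edges, faces and cubes of the cubical complex spanned by
#' the foreground voxels (each voxel a closed unit cube) and returns
#' chi = V - E + F - C. A solid ball gives 1, a hollow shell 2, a solid
#' torus 0. The complex of closed cubes realises 26-adjacent foreground; for
#' the well-composed masks this package evolves, the value is independent of
#' the admissible pair, which is accepted for interface symmetry.
#'
#' @param mask binary 3-D array or mask `cx_volume`.
#' @param connectivity_pair admissible digital pair (validated, see Details).
#' @return Integer Euler characteristic.
#' @export
euler_characteristic <- function(mask, connectivity_pair = c(6, 26)) {
  check_connectivity_pair(connectivity_pair)
  a <- if (is_volume(mask)) mask$data else mask
  a <- array(a != 0, dim(a))
  d <- dim(a)
  place_or <- function(grow) {
    out <- array(FALSE, d + grow)
    offs <- expand.grid(lapply(grow, function(g) if (g) 0:1 else 0))
    for (r in seq_len(nrow(offs))) {
      o <- as.integer(offs[r, ])
      out[(1 + o[1]):(d[1] + o[1]), (1 + o[2]):(d[2] + o[2]),
          (1 + o[3]):(d[3] + o[3])] <-
        out[(1 + o[1]):(d[1] + o[1]), (1 + o[2]):(d[2] + o[2]),
            (1 + o[3]):(d[3] + o[3])] | a
    }
    sum(out)
  }
  V <- place_or(c(1L, 1L, 1L))
  E <- place_or(c(0L, 1L, 1L)) + place_or(c(1L, 0L, 1L)) +
       place_or(c(1L, 1L, 0L))
  F <- place_or(c(1L, 0L, 0L)) + place_or(c(0L, 1L, 0L)) +
       place_or(c(0L, 0L, 1L))
  C <- sum(a)
  as.integer(V - E + F - C)
}

#' Label connected components of a binary volume
#'
#' @param mask binary 3-D array or mask `cx_volume`.
#' @param connectivity 6, 18 or 26.
#' @return Integer array of component labels (0 = background), or an int
#'   `cx_volume` when a volume was supplied.
#' @export
connected_components <- function(mask, connectivity = 6) {
  a <- if (is_volume(mask)) mask$data else mask
  lab <- cpp_label_components(as.integer(a != 0), dim(a),
                              as.integer(connectivity))
  lab <- array(lab, dim(a))
  if (is_volume(mask)) vol_like(lab, mask, "int") else lab
}

# keep only the largest connected component
largest_component <- function(a, connectivity = 6) {
  lab <- connected_components(a, connectivity)
  if (max(lab) == 0L) return(array(FALSE, dim(a)))
  tab <- tabulate(lab[lab > 0L])
  array(lab == which.max(tab), dim(a))
}

# fill internal cavities: background components not touching the volume
# border become foreground
fill_holes <- function(a, background_connectivity = 6) {
  a <- array(a != 0, dim(a))
  lab <- connected_components(!a, background_connectivity)
  if (max(lab) == 0L) return(a)
  d <- dim(a)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                     lab[, , c(1, d[3])]))
  border <- border[border > 0L]
  a | (lab > 0L & !(lab %in% border))
}

# EDT-based binary morphology, radius in voxels (isotropic in index space)
dilate_mask <- function(a, radius) {
  if (radius <= 0) return(array(a != 0, dim(a)))
  edt_distance(a != 0, c(1, 1, 1)) <= radius + 1e-9
}

erode_mask <- function(a, radius) {
  if (radius <= 0) return(array(a != 0, dim(a)))
  edt_distance(!(a != 0), c(1, 1, 1)) > radius + 1e-9
}

close_mask <- function(a, radius) erode_mask(dilate_mask(a, radius), radius)
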