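# Synthetic brain phantoms with known ground truth, emulating an MP2RAGE
# acquisition triplet (second inversion, T1-weighted, quantitative T1 map).

#' Phantom label table
#'
#' Integer ids and names of the structures a phantom can contain. The
#' `nested_spheres`, `folded_cortex` and `slab` geometries use the left-
#' hemisphere labels only; `two_hemispheres` adds a disjoint right shell
#' with its own labels so region extraction has a genuine left/right choice.
#'
#' @return `data.frame` with columns `id`, `name`.
#' @export
phantom_labels <- function() {
  data.frame(
    id = 0:9,
    name = c("background", "csf", "gm_left", "wm_left", "subcortex_left",
             "ventricle_left", "gm_right", "wm_right", "subcortex_right",
             "ventricle_right"),
    stringsAsFactors = FALSE)
}

#' Default tissue intensity parameters
#'
#' Per-class mean/sd for each simulated contrast, loosely modeled on 7T
#' MP2RAGE behavior: the second inversion (`inv2`) has a dark (zero-mean)
#' background, the uniform T1-weighted image (`t1w`) is bright in white
#' matter, and the quantitative T1 map (`t1map`, ms) is long in CSF and has
#' a high-variance noise background as MP2RAGE T1 fitting produces outside
#' the head.
#'
#' @return Nested list `tissue_params[[contrast]][[class]] = c(mean, sd)`.
#' @export
default_tissue_params <- function() {
  tab <- list(
    #            inv2          t1w           t1map
    background = list(c(0, 30),   c(0, 60),     c(2800, 1500)),
    csf        = list(c(500, 50), c(900, 120),  c(4300, 250)),
    gm         = list(c(700, 50), c(1800, 120), c(1900, 120)),
    wm         = list(c(800, 50), c(2800, 120), c(1200, 80)),
    subcortex  = list(c(750, 50), c(2300, 120), c(1600, 100)),
    ventricle  = list(c(520, 50), c(950, 120),  c(4200, 250)))
  cls <- function(base) tab[[base]]
  per_class <- list(
    background = cls("background"), csf = cls("csf"),
    gm_left = cls("gm"), wm_left = cls("wm"),
    subcortex_left = cls("subcortex"), ventricle_left = cls("ventricle"),
    gm_right = cls("gm"), wm_right = cls("wm"),
    subcortex_right = cls("subcortex"), ventricle_right = cls("ventricle"))
  out <- list()
  for (ci in seq_along(c("inv2", "t1w", "t1map"))) {
    cn <- c("inv2", "t1w", "t1map")[ci]
    out[[cn]] <- lapply(per_class, function(p) p[[ci]])
  }
  out
}

#' Specify a synthetic brain phantom
#'
#' @param shape grid dimensions (scalar or length 3).
#' @param voxel_size voxel size in mm.
#' @param geometry one of `"nested_spheres"`, `"folded_cortex"`, `"slab"`,
#'   `"two_hemispheres"`. Radii and fold parameters are in voxels.
#' @param r_inner,r_outer radii of the white-matter and pial boundaries.
#' @param fold_amplitude,fold_frequency sinusoidal radial perturbation of
#'   the boundaries (the inner boundary is perturbed twice as strongly as
#'   the outer one, so cortical thickness varies with the folds).
#' @param csf_thickness thickness of the CSF shell around the cortex.
#' @param tissue_params see [default_tissue_params()].
#' @param noise_sd global multiplier on the per-class noise sd.
#' @param seed integer; fixes all randomness of the phantom.
#' @export
phantom_spec <- function(shape = 64, voxel_size = c(0.7, 0.7, 0.7),
                         geometry = c("folded_cortex", "nested_spheres",
                                      "slab", "two_hemispheres"),
                         r_inner = NULL, r_outer = NULL,
                         fold_amplitude = 2.5, fold_frequency = 3,
                         csf_thickness = 3,
                         tissue_params = default_tissue_params(),
                         noise_sd = 0.1, seed = 42L) {
  geometry <- match.arg(geometry)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  shape <- as.integer(shape)
  if (is.null(r_inner))
    r_inner <- if (geometry == "two_hemispheres") 7 else 12
  if (is.null(r_outer))
    r_outer <- if (geometry == "two_hemispheres") 10 else 17
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  spec <- structure(list(
    shape = shape, voxel_size = voxel_size, geometry = geometry,
    r_inner = r_inner, r_outer = r_outer,
    fold_amplitude = fold_amplitude, fold_frequency = fold_frequency,
    csf_thickness = csf_thickness, tissue_params = tissue_params,
    noise_sd = noise_sd, seed = as.integer(seed)), class = "cx_phantomspec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(s) {
  if (!(s$r_inner > 0 && s$r_inner < s$r_outer))
    cx_stop("need 0 < r_inner < r_outer", "cx_validation_error")
  lim <- min(s$shape) / 2
  amp <- if (s$geometry %in% c("folded_cortex", "two_hemispheres"))
    abs(s$fold_amplitude) else 0
  if (s$geometry %in% c("nested_spheres", "folded_cortex") &&
      s$r_outer + s$csf_thickness + amp >= lim)
    cx_stop("r_outer + csf + fold amplitude must fit inside half the grid",
            "cx_validation_error")
  if (s$geometry == "two_hemispheres" &&
      s$r_outer + s$csf_thickness + amp >= lim / 2)
    cx_stop("two_hemispheres radii must fit inside a quarter of the grid",
            "cx_validation_error")
  if (s$noise_sd < 0)
    cx_stop("noise_sd must be non-negative", "cx_validation_error")
  invisible(s)
}

# label ids (see phantom_labels)
.lab <- list(bg = 0L, csf = 1L, gm_l = 2L, wm_l = 3L, sub_l = 4L, ven_l = 5L,
             gm_r = 6L, wm_r = 7L, sub_r = 8L, ven_r = 9L)

# one radially-perturbed cortical shell; labels written into `lab`
paint_shell <- function(lab, X, Y, Z, center, s, ids, subcortex) {
  x <- X - center[1]; y <- Y - center[2]; z <- Z - center[3]
  r <- sqrt(x^2 + y^2 + z^2)
  r0 <- pmax(r, 1e-9)
  P <- if (s$geometry %in% c("folded_cortex", "two_hemispheres")) {
    f <- s$fold_frequency
    s$fold_amplitude * sin(f * pi * x / r0) * sin(f * pi * y / r0) *
      sin(f * pi * z / r0)
  } else 0
  Rin <- s$r_inner + P
  Rout <- s$r_outer + 0.5 * P
  lab[r < Rout + s$csf_thickness] <- .lab$csf
  lab[r < Rout] <- ids$gm
  lab[r < Rin] <- ids$wm
  if (subcortex) {
    lab[r < 0.45 * s$r_inner] <- ids$sub
    lab[r < 0.22 * s$r_inner] <- ids$ven
  }
  lab
}

#' Generate a synthetic brain phantom
#'
#' Builds ground-truth labels for the requested geometry and simulates the
#' three MP2RAGE-like contrasts on top of them. Generation is a pure
#' function of the spec: identical spec (including seed) gives identical
#' volumes.
#'
#' @param spec a [phantom_spec()].
#' @return A `cx_phantom`: list with `truth_labels` (int `cx_volume`),
#'   `contrasts` (named list of `cx_volume`s: inv2, t1w, t1map) and `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  validate_phantom_spec(spec)
  d <- spec$shape
  X <- array(rep(seq_len(d[1]), times = d[2] * d[3]), d)
  Y <- array(rep(rep(seq_len(d[2]), each = d[1]), times = d[3]), d)
  Z <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  ctr <- (d + 1) / 2
  lab <- array(.lab$bg, d)
  if (spec$geometry %in% c("nested_spheres", "folded_cortex")) {
    lab <- paint_shell(lab, X, Y, Z, ctr, spec,
                       list(gm = .lab$gm_l, wm = .lab$wm_l,
                            sub = .lab$sub_l, ven = .lab$ven_l),
                       subcortex = FALSE)
  } else if (spec$geometry == "two_hemispheres") {
    off <- floor(min(d) / 4)
    lab <- paint_shell(lab, X, Y, Z, ctr - c(off, 0, 0), spec,
                       list(gm = .lab$gm_l, wm = .lab$wm_l,
                            sub = .lab$sub_l, ven = .lab$ven_l),
                       subcortex = TRUE)
    lab <- paint_shell(lab, X, Y, Z, ctr + c(off, 0, 0), spec,
                       list(gm = .lab$gm_r, wm = .lab$wm_r,
                            sub = .lab$sub_r, ven = .lab$ven_r),
                       subcortex = TRUE)
    # interhemispheric CSF bridge: real heads are one connected body, and
    # the brain mask relies on that
    cyl <- (Y - ctr[2])^2 + (Z - ctr[3])^2 < 4.5^2 &
      abs(X - ctr[1]) <= off
    lab[cyl & lab == .lab$bg] <- .lab$csf
  } else { # slab: two parallel planar boundaries, constant GM thickness
    th <- spec$r_outer - spec$r_inner
    z0 <- ctr[3] - th / 2
    z1 <- ctr[3] + th / 2
    lab[Z < z0] <- .lab$wm_l
    lab[Z >= z0 & Z < z1] <- .lab$gm_l
    lab[Z >= z1 & Z < z1 + spec$csf_thickness] <- .lab$csf
  }
  truth <- volume(lab, voxel_size = spec$voxel_size, dtype_tag = "int")
  contrasts <- simulate_contrasts(truth, spec$tissue_params, spec$noise_sd,
                                  spec$seed)
  structure(list(truth_labels = truth, contrasts = contrasts, spec = spec),
            class = "cx_phantom")
}

#' @export
print.cx_phantom <- function(x, ...) {
  cat(sprintf("<cx_phantom> %s, %s, labels: %s\n", x$spec$geometry,
              paste(x$spec$shape, collapse = "x"),
              paste(sort(unique(as.vector(x$truth_labels$data))),
                    collapse = " ")))
  invisible(x)
}

#' Simulate imaging contrasts from a label volume
#'
#' Every voxel gets its class mean plus zero-mean Gaussian noise of scale
#' `noise_sd` times the per-class sd. With `noise_sd = 0` the images are
#' piecewise constant at the class means.
#'
#' @param truth_labels int `cx_volume` of class labels.
#' @param tissue_params nested list, see [default_tissue_params()].
#' @param noise_sd global noise multiplier (>= 0).
#' @param seed integer seed; the global RNG state is restored on exit.
#' @param contrasts names of the contrasts to simulate.
#' @return Named list of `cx_volume`s.
#' @export
simulate_contrasts <- function(truth_labels, tissue_params = default_tissue_params(),
                               noise_sd = 0.1, seed = 42L,
                               contrasts = names(tissue_params)) {
  lab <- truth_labels$data
  ids <- sort(unique(as.vector(lab)))
  ltab <- phantom_labels()
  missing_contr <- setdiff(contrasts, names(tissue_params))
  if (length(missing_contr))
    cx_stop(sprintf("unknown contrast name(s): %s",
                    paste(missing_contr, collapse = ", ")),
            "cx_validation_error")
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)
  out <- list()
  for (cn in contrasts) {
    pars <- tissue_params[[cn]]
    img <- array(0, dim(lab))
    for (id in ids) {
      nm <- ltab$name[match(id, ltab$id)]
      if (is.na(nm) || is.null(pars[[nm]]))
        cx_stop(sprintf("no %s parameters for class id %d (%s)", cn, id,
                        if (is.na(nm)) "unknown" else nm),
                "cx_validation_error")
      sel <- lab == id
      n <- sum(sel)
      p <- pars[[nm]]
      img[sel] <- p[1] + noise_sd * p[2] * rnorm(n)
    }
    out[[cn]] <- vol_like(img, truth_labels, "float")
  }
  out
}

#' Voxel-count ratio between two isotropic sampling resolutions
#'
#' For a fixed field of view, the factor by which the number of voxels grows
#' when resampling from `res_from` to `res_to` mm isotropic (e.g. 1.0 mm to
#' 0.7 mm roughly triples the data size).
#'
#' @param fov_mm field of view per axis in mm (scalar or length 3).
#' @param res_from,res_to isotropic voxel edge lengths in mm.
#' @return The voxel-count ratio (> 1 when `res_to` is finer).
#' @export
voxel_count_ratio <- function(fov_mm = 192, res_from = 1.0, res_to = 0.7) {
  if (length(fov_mm) == 1L) fov_mm <- rep(fov_mm, 3L)
  prod(round(fov_mm / res_to)) / prod(round(fov_mm / res_from))
}
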