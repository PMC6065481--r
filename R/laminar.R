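# Equivolumetric intracortical depth and laminae from the gray-white and
# pial level sets.

#' Equivolumetric position for a target volume fraction
#'
#' Along a cortical column whose cross-sectional area varies linearly from
#' `A_in` at the inner boundary to `A_out` at the outer boundary, returns
#' the relative position `alpha` in \[0, 1\] at which the accumulated volume
#' equals the fraction `rho` of the column volume:
#' `alpha = (-A_in + sqrt(rho*A_out^2 + (1-rho)*A_in^2)) / (A_out - A_in)`,
#' with the flat limit `alpha = rho` when the areas are (nearly) equal.
#' This is what shifts laminae towards the outer boundary at gyral crowns
#' and towards the inner boundary in sulci.
#'
#' @param rho volume fraction(s) in \[0, 1\].
#' @param A_in,A_out positive relative boundary areas (vectorized).
#' @return `alpha` in \[0, 1\], monotone in `rho`.
#' @export
equivolume_fraction <- function(rho, A_in, A_out) {
  if (any(!is.finite(A_in)) || any(!is.finite(A_out)) ||
      any(A_in <= 0) || any(A_out <= 0))
    cx_stop("boundary areas must be positive", "cx_validation_error")
  if (any(rho < -1e-9) || any(rho > 1 + 1e-9))
    cx_stop("rho must lie in [0, 1]", "cx_validation_error")
  rho <- pmin(pmax(rho, 0), 1)
  n <- max(length(rho), length(A_in), length(A_out))
  rho <- rep_len(rho, n); A_in <- rep_len(A_in, n); A_out <- rep_len(A_out, n)
  flat <- abs(A_out - A_in) < 1e-9 * pmax(A_in, A_out)
  alpha <- rho
  if (any(!flat)) {
    i <- !flat
    alpha[i] <- (-A_in[i] + sqrt(rho[i] * A_out[i]^2 +
                                   (1 - rho[i]) * A_in[i]^2)) /
      (A_out[i] - A_in[i])
  }
  pmin(pmax(alpha, 0), 1)
}

# forward map: volume fraction accumulated up to position alpha under the
# linear area model (the inverse of equivolume_fraction)
equivolume_depth <- function(alpha, A_in, A_out) {
  (2 * A_in * alpha + (A_out - A_in) * alpha^2) / (A_in + A_out)
}

as_levelset <- function(x) {
  if (is_levelset(x)) x
  else if (is_volume(x)) levelset(x)
  else cx_stop("expected a cx_levelset or cx_volume", "cx_validation_error")
}

#' Equivolumetric cortical layering
#'
#' Computes a continuous cortical depth coordinate (0 at the gray-white
#' boundary, 1 at the pial boundary; see `invert`) that preserves the volume
#' of cortical segments, discrete laminae labels, and level sets of the
#' intracortical boundary surfaces. For every voxel the equidistant
#' coordinate `d_in / (d_in + d_out)` is corrected through the local column
#' area model: the inner-boundary curvature (sampled from the inner level
#' set and corrected to its zero crossing) sets the area ratio
#' `A_out/A_in = (1 + kappa * t)^2` of the column, and the linear-area
#' volume balance maps position to volume fraction. Where the column is
#' thinner than one voxel the area estimate is unstable and the equidistant
#' coordinate is used directly (the count is reported as attribute
#' `n_thin`).
#'
#' @param inner_levelset,outer_levelset gray-white and pial boundaries
#'   ([levelset()]s or `phi` `cx_volume`s), inner nested in outer.
#' @param n_layers number of laminae (>= 1).
#' @param invert set the depth origin at the pial surface instead.
#' @return Output set with `depth` (continuous, in \[0, 1\]), `layers` (int, 0
#'   outside cortex, 1..n_layers inside) and `boundaries` (stack of
#'   `n_layers + 1` nested level-set volumes from gray-white to pial).
#' @export
volumetric_layering <- function(inner_levelset, outer_levelset, n_layers = 4,
                                invert = FALSE) {
  inner <- as_levelset(inner_levelset)
  outer <- as_levelset(outer_levelset)
  check_same_grid(list(inner$phi, outer$phi))
  if (!is.numeric(n_layers) || length(n_layers) != 1L || n_layers < 1 ||
      n_layers != round(n_layers))
    cx_stop("n_layers must be a positive integer", "cx_validation_error")
  n_layers <- as.integer(n_layers)
  inner <- reinitialize(levelset(inner$phi, Inf))
  outer <- reinitialize(levelset(outer$phi, Inf))
  phi_in <- inner$phi$data
  phi_out <- outer$phi$data
  vs <- inner$phi$voxel_size
  hmin <- min(vs)
  # reinitialization can jitter coincident surfaces by a fraction of a
  # voxel; only a gross violation means the inputs are not nested
  if (any(phi_out > phi_in + 0.5 * hmin))
    cx_stop("inner level set must be nested inside the outer one",
            "cx_validation_error")
  phi_out <- pmin(phi_out, phi_in)
  d_in <- pmax(phi_in, 0)
  d_out <- pmax(-phi_out, 0)
  t_col <- d_in + d_out
  alpha <- ifelse(t_col > 1e-9, d_in / pmax(t_col, 1e-9),
                  as.numeric(phi_in > 0))
  cortex <- phi_in > 0 & phi_out <= 0
  # Local column area model: the surface mean curvature at the column foot
  # points sets the area ratio A_out/A_in = (1 + kappa_in t)^2 (tube
  # formula; equivalently 1/(1 - kappa_out t)^2 from the outer side). The
  # voxelwise level-set curvature is corrected to the zero crossing through
  # kappa_surf = kappa/(1 - kappa*phi), box-smoothed to tame discretization
  # noise, and both one-sided estimates are averaged.
  box3 <- function(a) {
    out <- array(0, dim(a)); n <- array(0, dim(a))
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      sh <- shift3(a, c(dx, dy, dz), fill = NA)
      ok <- !is.na(sh)
      out[ok] <- out[ok] + sh[ok]; n[ok] <- n[ok] + 1
    }
    out / pmax(n, 1)
  }
  surf_curv <- function(ls, phi) {
    kv <- box3(mean_curvature(ls)$data)
    denom <- 1 - kv * phi
    ifelse(abs(denom) > 0.2, kv / denom, kv / (0.2 * sign(denom)))
  }
  k_in <- surf_curv(inner, phi_in)
  k_out <- surf_curv(outer, phi_out)
  A_from_in <- pmax(1 + k_in * t_col, 0.2)^2
  A_from_out <- 1 / pmax(1 - k_out * t_col, 0.2)^2
  A_out <- sqrt(A_from_in * A_from_out)
  stable <- cortex & t_col >= hmin
  depth <- alpha
  depth[stable] <- equivolume_depth(alpha[stable], 1, A_out[stable])
  n_thin <- sum(cortex & t_col < hmin)
  depth_geo <- depth # gray-white -> pial orientation, used for the surfaces
  if (invert) depth <- 1 - depth
  layers <- array(0L, dim(depth))
  layers[cortex] <- as.integer(
    pmin(pmax(ceiling(depth[cortex] * n_layers), 1), n_layers))
  rho <- seq(0, 1, length.out = n_layers + 1L)
  bounds <- vector("list", n_layers + 1L)
  bounds[[1L]] <- phi_in
  bounds[[n_layers + 1L]] <- phi_out
  if (n_layers > 1L) for (j in 2:n_layers) {
    u <- depth_geo - rho[j]
    bounds[[j]] <- sdf_from_field(u, vs, refine = TRUE)
  }
  for (j in 2:(n_layers + 1L))
    bounds[[j]] <- pmin(bounds[[j]], bounds[[j - 1L]])
  proto <- inner$phi
  res <- output_set(list(
    depth = vol_like(pmin(pmax(depth, 0), 1), proto),
    layers = vol_like(layers, proto, "int"),
    boundaries = lapply(bounds, function(b) vol_like(b, proto))), "layering")
  attr(res, "levelsets") <- lapply(bounds, function(b)
    levelset(vol_like(b, proto)))
  attr(res, "n_thin") <- n_thin
  class(res) <- c("cx_layering", class(res))
  res
}
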