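# MP2RAGE-oriented brain extraction from the second-inversion image.

#' Skull stripping from an MP2RAGE second-inversion image
#'
#' The second inversion has bright brain tissue on a dark background, which
#' makes it the natural contrast for masking. The background noise level
#' `sigma_bg` is estimated by a half-normal fit to the sub-mode tail of the
#' intensity histogram; voxels above `k * sigma_bg` are kept, closed
#' morphologically, reduced to the largest 6-connected component, and
#' internal holes are filled. The mask is computed from the second inversion
#' only and then applied to any companion image supplied (e.g. the
#' T1-weighted image and the quantitative T1 map); zeroed regions inside the
#' head (such as defaced areas in companions) survive as in-mask zeros.
#'
#' @param second_inversion `cx_volume`, the INV2 image.
#' @param t1_weighted,t1_map optional companion `cx_volume`s on the same
#'   grid, masked on return.
#' @param k threshold in background-noise units (default 5).
#' @param r_close morphological closing radius in voxels (default 2).
#' @return Output set with `brain_mask` and, per companion given,
#'   `t1w_masked` / `t1map_masked` / `inv2_masked`.
#' @export
mp2rage_skullstripping <- function(second_inversion, t1_weighted = NULL,
                                   t1_map = NULL, k = 5, r_close = 2) {
  if (!is_volume(second_inversion))
    cx_stop("second_inversion must be a cx_volume", "cx_validation_error")
  check_same_grid(list(second_inversion, t1_weighted, t1_map))
  v <- second_inversion$data
  sigma <- estimate_background_sigma(v)
  thr <- k * sigma
  fg <- v > thr
  if (!any(fg) || all(fg))
    cx_stop(sprintf(
      "degenerate contrast: threshold %.3g leaves %s foreground", thr,
      if (any(fg)) "only" else "no"), "cx_degenerate_error")
  fg <- close_mask(fg, r_close)
  fg <- largest_component(fg, 6)
  fg <- fill_holes(fg, 6)
  mask <- vol_like(fg, second_inversion, "mask")
  out <- list(brain_mask = mask)
  out$inv2_masked <- vol_like(v * fg, second_inversion)
  if (!is.null(t1_weighted))
    out$t1w_masked <- vol_like(t1_weighted$data * fg, t1_weighted)
  if (!is.null(t1_map))
    out$t1map_masked <- vol_like(t1_map$data * fg, t1_map)
  output_set(out, "strip")
}

# half-normal fit to the sub-mode tail of the intensity histogram: the
# background mode m is located on a coarse histogram, and sigma is the RMS
# deviation of the values at or below m (for N(m, sigma) those are a
# half-normal sample with E[(v-m)^2] = sigma^2)
estimate_background_sigma <- function(v) {
  rng <- range(v)
  if (rng[1] == rng[2]) return(0)
  h <- hist(v, breaks = 256, plot = FALSE)
  # search the mode in the lower half of the intensity range
  lower <- h$mids <= rng[1] + 0.5 * (rng[2] - rng[1])
  m <- h$mids[lower][which.max(h$counts[lower])]
  tail_vals <- v[v <= m]
  if (length(tail_vals) < 2L) return(0)
  sqrt(mean((tail_vals - m)^2))
}
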