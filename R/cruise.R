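# Cortical reconstruction: grow the gray-white and pial boundaries from a
# topologically spherical white-matter initialization by topology-preserving
# level-set evolution, with thin-sulcus (fundus) CSF enhancement.

#' Enhance CSF evidence in thin sulci
#'
#' Detects ridge voxels where two gray-matter banks approach within a small
#' gap — the buried sulcal fundi that a pial surface would otherwise bridge —
#' and raises the CSF probability there to at least the gray-matter
#' probability plus `delta`. Everywhere else the input is returned
#' unchanged; the output is clipped to \[0, 1\] and is voxelwise >= the input.
#'
#' @param gm_proba,csf_proba probability `cx_volume`s on one grid.
#' @param max_gap maximal gap width in voxels that counts as a thin sulcus.
#' @param delta margin by which CSF must dominate GM on ridge voxels.
#' @return Enhanced CSF probability `cx_volume`.
#' @export
ace_enhance_csf <- function(gm_proba, csf_proba, max_gap = 2, delta = 0.05) {
  check_same_grid(list(gm_proba, csf_proba))
  gm <- gm_proba$data
  csf <- csf_proba$data
  gmhigh <- gm >= 0.5
  ridge <- array(FALSE, dim(gm))
  # a non-GM voxel lies on a fundus ridge when GM banks flank it within
  # max_gap voxels on both sides along some grid axis
  for (ax in 1:3) {
    up <- array(FALSE, dim(gm)); dn <- array(FALSE, dim(gm))
    for (step in seq_len(max_gap)) {
      s <- c(0L, 0L, 0L); s[ax] <- step
      up <- up | shift3(gmhigh, s, fill = FALSE)
      s[ax] <- -step
      dn <- dn | shift3(gmhigh, s, fill = FALSE)
    }
    ridge <- ridge | (up & dn)
  }
  ridge <- ridge & !gmhigh
  out <- csf
  out[ridge] <- pmax(csf[ridge], pmin(gm[ridge] + delta, 1))
  out <- pmax(out, csf) # monotone enhancement, never below the input
  vol_like(pmin(pmax(out, 0), 1), csf_proba)
}

#' Cortical boundary reconstruction from membership maps
#'
#' Uses the membership functions as a guide and the white-matter mask as a
#' (topologically spherical) starting point to grow refined boundaries: the
#' gray-white boundary (`gwb`) evolves under the white-vs-rest posterior
#' balance, then the pial boundary (`cgb`) grows outward from it under the
#' (white+gray)-vs-CSF balance with thin-sulcus CSF enhancement, constrained
#' to stay outside the gray-white boundary (`phi_cgb <= phi_gwb` is enforced
#' by clamping after every step). Both evolutions preserve the topology of
#' the initialization.
#'
#' @param init_image mask `cx_volume`, the initial white-matter interior.
#' @param wm_image,gm_image,csf_image membership `cx_volume`s.
#' @param normalize_probabilities divide the three memberships by their
#'   voxelwise sum (epsilon-guarded) before use.
#' @param curvature_weight curvature regularization weight (mm).
#' @param max_iter iteration cap per boundary.
#' @param topology_preserving logical; on non-spherical initializations the
#'   given topology is preserved, not corrected (a warning is issued).
#' @param track_topology record per-iteration topology of both evolutions.
#' @return Output set with `gwb` and `cgb` (level-set `phi` volumes, also
#'   available as [levelset()]s via attribute `levelsets`) and `cortex_mask`.
#' @export
cruise_cortex_extraction <- function(init_image, wm_image, gm_image,
                                     csf_image,
                                     normalize_probabilities = TRUE,
                                     curvature_weight = 0.2, max_iter = 60,
                                     topology_preserving = TRUE,
                                     track_topology = FALSE) {
  check_same_grid(list(init_image, wm_image, gm_image, csf_image))
  init <- init_image$data != 0
  if (!any(init))
    cx_stop("empty initialization mask", "cx_degenerate_error")
  wm <- wm_image$data; gm <- gm_image$data; csf <- csf_image$data
  if (normalize_probabilities) {
    tot <- pmax(wm + gm + csf, 1e-6)
    wm <- wm / tot; gm <- gm / tot; csf <- csf / tot
  }
  if (mean(wm[init] >= 0.5) < 0.5)
    cx_warn("initialization lies mostly outside the high-probability white matter")
  if (topology_preserving) {
    chi <- euler_characteristic(init)
    ncomp <- max(connected_components(init, 6))
    if (chi != 1L || ncomp != 1L)
      cx_warn(sprintf(
        "initialization is not a single genus-0 component (chi=%d, %d components); its topology will be preserved, not corrected",
        chi, ncomp))
  }
  csf_e <- ace_enhance_csf(vol_like(gm, gm_image), vol_like(csf, csf_image))$data
  gm_e <- pmin(gm, 1 - csf_e)

  init_ls <- probability_to_levelset(vol_like(init, init_image))
  speed_gwb <- vol_like(tanh(3 * (wm - gm_e - csf_e)), wm_image)
  gwb <- evolve_levelset(init_ls, speed_gwb,
                         curvature_weight = curvature_weight,
                         preserve_topology = topology_preserving,
                         max_iter = max_iter, track_topology = track_topology)
  speed_cgb <- vol_like(tanh(3 * (wm + gm_e - csf_e)), wm_image)
  cgb <- evolve_levelset(gwb, speed_cgb,
                         curvature_weight = curvature_weight,
                         preserve_topology = topology_preserving,
                         max_iter = max_iter, constraint = gwb$phi,
                         track_topology = track_topology)
  phi_gwb <- gwb$phi$data
  phi_cgb <- pmin(cgb$phi$data, phi_gwb)
  cortex <- phi_gwb > 0 & phi_cgb <= 0
  res <- output_set(list(
    gwb = gwb$phi,
    cgb = vol_like(phi_cgb, gwb$phi),
    cortex_mask = vol_like(cortex, gwb$phi, "mask")), "cruise")
  attr(res, "levelsets") <- list(gwb = gwb,
                                 cgb = levelset(vol_like(phi_cgb, gwb$phi)))
  if (track_topology)
    attr(res, "topology_trace") <- list(
      gwb = attr(gwb, "topology_trace"), cgb = attr(cgb, "topology_trace"))
  class(res) <- c("cx_cruise", class(res))
  res
}
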