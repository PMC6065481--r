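# Turn a whole-head segmentation into the region/inside/background triplet
# that cortical reconstruction consumes.

#' Region grouping recipes
#'
#' Which structure labels form the cortical sheet ("region"), the filled
#' interior ("inside": white matter plus subcortical structures and
#' ventricles) and the surround ("background") for each extractable region.
#' Recipes are data: a plain-text tab-separated table with columns
#' `region`, `group`, `label`; built-ins cover the phantom label set.
#'
#' @param path optional path to a custom recipe table; defaults to the
#'   built-in one.
#' @return `data.frame` with columns `region`, `group`, `label`.
#' @export
region_recipes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "phantom_recipes.tsv", package = "cortexr",
                        mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Extract the membership triplet for one brain region
#'
#' Groups the ranked memberships of a segmentation into three probability
#' maps: the cortical gray matter of the chosen structure (`region`), its
#' white matter with filled subcortex and ventricles (`inside`), and
#' everything else (`background`), renormalized to sum to one at every
#' voxel. The `inside` mask is hole-filled (with the probabilities adjusted
#' accordingly) so that, when the input topology permits, it is a single
#' filled component suitable as a topologically spherical initialization.
#'
#' @param seg result of [mgdm_segmentation()].
#' @param extracted_region one of the recipe names, e.g. `"left_cerebrum"`,
#'   `"right_cerebrum"`, `"cerebrum"`.
#' @param recipes recipe table, see [region_recipes()].
#' @return Output set with `region_proba`, `inside_proba`,
#'   `background_proba`, `region_mask`, `inside_mask`, `background_mask`.
#' @export
extract_brain_region <- function(seg, extracted_region,
                                 recipes = region_recipes()) {
  if (!inherits(seg, "cx_mgdm"))
    cx_stop("seg must be an mgdm segmentation result", "cx_validation_error")
  structures <- attr(seg, "structures")
  rec <- recipes[recipes$region == extracted_region, , drop = FALSE]
  if (!nrow(rec))
    cx_stop(sprintf("unknown region '%s'; available: %s", extracted_region,
                    paste(unique(recipes$region), collapse = ", ")),
            "cx_validation_error")
  region_labs <- structures$id[structures$name %in%
                                 rec$label[rec$group == "region"]]
  inside_labs <- structures$id[structures$name %in%
                                 rec$label[rec$group == "inside"]]
  if (!length(region_labs) || !length(inside_labs))
    cx_stop(sprintf(
      "region '%s' maps to no labels of the active structure set",
      extracted_region), "cx_degenerate_error")
  proto <- seg$segmentation
  d <- dim(proto$data)
  p_region <- p_inside <- array(0, d)
  total <- array(0, d)
  for (r in seq_along(seg$memberships)) {
    mem <- seg$memberships[[r]]$data
    lab <- seg$labels[[r]]$data
    p_region <- p_region + mem * (lab %in% region_labs)
    p_inside <- p_inside + mem * (lab %in% inside_labs)
    total <- total + mem
  }
  p_background <- pmax(total - p_region - p_inside, 0)
  if (sum(p_region >= pmax(p_inside, p_background)) == 0L)
    cx_stop(sprintf("region '%s' is empty after membership grouping",
                    extracted_region), "cx_degenerate_error")
  # masks = argmax of the triplet (ties resolved region > inside > background)
  m_region <- p_region >= p_inside & p_region >= p_background
  m_inside <- !m_region & p_inside >= p_background
  # the inside compartment must be a single filled body (it seeds the
  # topologically spherical reconstruction): keep the largest component,
  # demote stray scraps to background, fill internal cavities, and pull the
  # probabilities along so the argmax contract still holds everywhere
  main <- largest_component(m_inside, 6)
  scraps <- m_inside & !main
  if (any(scraps)) {
    p_background[scraps] <- pmax(p_background[scraps],
                                 pmax(p_region[scraps], p_inside[scraps]) +
                                   0.01)
    m_inside <- main
  }
  filled <- fill_holes(m_inside, 6)
  add <- filled & !m_inside
  if (any(add)) {
    p_inside[add] <- pmax(p_inside[add],
                          pmax(p_region[add], p_background[add]) + 0.01)
    m_inside <- filled
    m_region <- m_region & !m_inside
  }
  m_background <- !m_region & !m_inside
  norm <- pmax(p_region + p_inside + p_background, 1e-12)
  res <- output_set(list(
    region_proba = vol_like(p_region / norm, proto),
    inside_proba = vol_like(p_inside / norm, proto),
    background_proba = vol_like(p_background / norm, proto),
    region_mask = vol_like(m_region, proto, "mask"),
    inside_mask = vol_like(m_inside, proto, "mask"),
    background_mask = vol_like(m_background, proto, "mask")), "xmask")
  class(res) <- c("cx_region", class(res))
  res
}
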