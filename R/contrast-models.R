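# Named Gaussian intensity models: a contrast type maps every structure
# label to an expected intensity and spread, so segmentation can be invoked
# with short contrast-type names.

#' Define a contrast model
#'
#' @param name short model name (e.g. `"PhantomT1w"`).
#' @param class_means named numeric, expected intensity per structure name.
#' @param class_sds named numeric, positive spreads on the same names.
#' @export
contrast_model <- function(name, class_means, class_sds) {
  if (!is.character(name) || !nzchar(name))
    cx_stop("model name must be a non-empty string", "cx_validation_error")
  if (is.null(names(class_means)) || is.null(names(class_sds)) ||
      !setequal(names(class_means), names(class_sds)))
    cx_stop("class_means and class_sds must be named over the same classes",
            "cx_validation_error")
  if (any(!is.finite(class_sds)) || any(class_sds <= 0))
    cx_stop("class sds must be positive", "cx_validation_error")
  structure(list(name = name, class_means = class_means,
                 class_sds = class_sds[names(class_means)]),
            class = "cx_contrastmodel")
}

#' Register a contrast model by name
#'
#' Registered models back the `contrast_types` strings accepted by
#' [mgdm_segmentation()]. Re-registration overwrites with a message.
#'
#' @param model a [contrast_model()].
#' @export
register_contrast_model <- function(model) {
  if (!inherits(model, "cx_contrastmodel"))
    cx_stop("model must be a cx_contrastmodel", "cx_validation_error")
  if (!is.null(.cx_env$models[[model$name]]))
    message(sprintf("contrast model '%s' re-registered", model$name))
  if (is.null(.cx_env$models)) .cx_env$models <- list()
  .cx_env$models[[model$name]] <- model
  invisible(model)
}

#' @export
get_contrast_model <- function(name) {
  m <- .cx_env$models[[name]]
  if (is.null(m))
    cx_stop(sprintf("unknown contrast type '%s'; registered: %s", name,
                    paste(names(.cx_env$models), collapse = ", ")),
            "cx_validation_error")
  m
}

#' @export
list_contrast_models <- function() names(.cx_env$models)

# Build and register models for the phantom contrasts from tissue parameters.
# Returns the model names keyed by contrast.
#' Register contrast models matching the phantom's tissue parameters
#'
#' @param tissue_params see [default_tissue_params()].
#' @param prefix name prefix for the registered models.
#' @export
register_phantom_models <- function(tissue_params = default_tissue_params(),
                                    prefix = "Phantom") {
  out <- character(0)
  for (cn in names(tissue_params)) {
    pars <- tissue_params[[cn]]
    mu <- vapply(pars, `[`, numeric(1), 1L)
    sdv <- vapply(pars, `[`, numeric(1), 2L)
    sdv <- pmax(sdv, 1e-6)
    nm <- paste0(prefix, toupper(substring(cn, 1, 1)), substring(cn, 2))
    suppressMessages(register_contrast_model(contrast_model(nm, mu, sdv)))
    out[cn] <- nm
  }
  out
}
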