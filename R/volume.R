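#' Create a 3-D image volume
#'
#' The `cx_volume` is the universal image carrier of the package: a 3-D scalar
#' grid together with its voxel size (mm), a 4x4 voxel-to-world affine, and a
#' storage-type tag. Voxel indices are 0-based in world computations; world
#' coordinates come only from the affine and no axis reordering is ever
#' applied.
#'
#' @param data 3-D numeric or logical array.
#' @param voxel_size positive length-3 numeric, voxel edge lengths in mm.
#' @param affine invertible 4x4 voxel-to-world transform. Defaults to a
#'   diagonal scaling by `voxel_size`.
#' @param dtype_tag one of `"float"`, `"int"`, `"mask"`. Masks must contain
#'   only 0/1; int volumes only whole numbers.
#' @return A `cx_volume` object.
#' @export
volume <- function(data, voxel_size = c(1, 1, 1), affine = NULL,
                   dtype_tag = c("float", "int", "mask")) {
  dtype_tag <- match.arg(dtype_tag)
  if (is.logical(data)) data <- array(as.integer(data), dim(data))
  if (length(dim(data)) != 3L)
    cx_stop(sprintf("volume data must have exactly 3 axes, got %d",
                    length(dim(data))), "cx_dim_error")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    cx_stop("voxel_size must be three positive lengths (mm)",
            "cx_validation_error")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !is.finite(det(affine)) ||
      abs(det(affine)) < 1e-12)
    cx_stop("affine must be an invertible 4x4 matrix", "cx_validation_error")
  if (dtype_tag == "mask" && !all(data %in% c(0, 1)))
    cx_stop("mask volumes may contain only 0 and 1", "cx_validation_error")
  if (dtype_tag == "int" && any(data != round(data)))
    cx_stop("int volumes must hold whole numbers", "cx_validation_error")
  structure(list(data = data, voxel_size = voxel_size,
                 affine = unname(affine), dtype_tag = dtype_tag),
            class = "cx_volume")
}

#' @export
is_volume <- function(x) inherits(x, "cx_volume")

#' @export
print.cx_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<cx_volume> %d x %d x %d, voxel %s mm, dtype %s\n",
              d[1], d[2], d[3],
              paste(format(x$voxel_size, digits = 3), collapse = " x "),
              x$dtype_tag))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.cx_volume <- function(x) dim(x$data)

#' @export
as.array.cx_volume <- function(x, ...) x$data

# new volume on the same grid
vol_like <- function(data, vol, dtype_tag = "float") {
  if (is.logical(data)) data <- array(as.integer(data), dim(data))
  if (is.null(dim(data))) dim(data) <- dim(vol$data)
  volume(data, voxel_size = vol$voxel_size, affine = vol$affine,
         dtype_tag = dtype_tag)
}

same_grid <- function(a, b, tol = 1e-5) {
  all(dim(a$data) == dim(b$data)) &&
    max(abs(a$voxel_size - b$voxel_size)) < tol &&
    max(abs(a$affine - b$affine)) < tol
}

check_same_grid <- function(vols) {
  vols <- Filter(is_volume, vols)
  if (length(vols) < 2L) return(invisible(TRUE))
  for (i in seq_along(vols)[-1])
    if (!same_grid(vols[[1L]], vols[[i]]))
      cx_stop("input volumes must share grid shape, voxel size and affine",
              "cx_validation_error")
  invisible(TRUE)
}

#' Read a NIfTI-1 volume
#'
#' Loads a `.nii` or `.nii.gz` file into a [volume()]; gzip compression is
#' handled transparently. Only 3-D images are accepted.
#'
#' @param path path to a NIfTI-1 file.
#' @param dtype_tag storage tag to attach; `"auto"` infers `"int"` for
#'   integer on-disk types (and `"mask"` if only 0/1 present), else `"float"`.
#' @return A `cx_volume` with grid shape, voxel size and affine taken from
#'   the file header.
#' @export
read_volume <- function(path, dtype_tag = "auto") {
  if (!file.exists(path))
    cx_stop(sprintf("file not found: %s", path), "cx_not_found_error")
  img <- tryCatch(RNifti::readNifti(path, internal = FALSE),
                  error = function(e)
                    cx_stop(sprintf("not a readable NIfTI-1 file: %s (%s)",
                                    path, conditionMessage(e)),
                            "cx_format_error"))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) d <- d[1:3] # degenerate singleton volume
  if (length(d) != 3L)
    cx_stop(sprintf(
      "expected a 3-D volume but %s has %d axes (offending axis %d of extent %d)",
      path, length(d), length(d), d[length(d)]), "cx_dim_error")
  hdr <- RNifti::niftiHeader(img)
  arr <- array(as.numeric(img), dim = d)
  aff <- unname(structure(RNifti::xform(img), imagedim = NULL, code = NULL))
  attributes(aff) <- list(dim = c(4L, 4L))
  vs <- abs(hdr$pixdim[2:4])
  if (dtype_tag == "auto") {
    int_codes <- c(2L, 4L, 8L, 256L, 512L, 768L)
    if (hdr$datatype %in% int_codes) {
      dtype_tag <- if (all(arr %in% c(0, 1))) "mask" else "int"
    } else dtype_tag <- "float"
  }
  volume(arr, voxel_size = vs, affine = aff, dtype_tag = dtype_tag)
}

#' Write a volume to NIfTI-1
#'
#' Float volumes are stored as 32-bit floats, `int` and `mask` volumes with an
#' integer on-disk type. A `.nii.gz` suffix yields a gzip-compressed file.
#'
#' @param vol a [volume()] or a list of volumes sharing one grid (written as a
#'   4-D stack, used for ranked membership and boundary outputs).
#' @param path destination file name (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stacked <- !is_volume(vol)
  if (stacked) {
    check_same_grid(vol)
    proto <- vol[[1L]]
    arr <- array(unlist(lapply(vol, function(v) v$data), use.names = FALSE),
                 dim = c(dim(proto$data), length(vol)))
    tag <- proto$dtype_tag
  } else {
    proto <- vol
    arr <- vol$data
    tag <- vol$dtype_tag
  }
  dir <- dirname(path)
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    cx_stop(sprintf("cannot create directory: %s", dir), "cx_io_error")
  dt <- switch(tag, float = "float", int = "int32", mask = "uint8")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- proto$voxel_size
  RNifti::qform(img) <- structure(proto$affine, code = 2L)
  RNifti::sform(img) <- structure(proto$affine, code = 2L)
  ok <- tryCatch({RNifti::writeNifti(img, path, datatype = dt); TRUE},
                 error = function(e) FALSE)
  if (!ok || !file.exists(path))
    cx_stop(sprintf("could not write %s", path), "cx_io_error")
  invisible(path)
}

#' Compose an output file name from naming modifiers
#'
#' Output files are named by appending the producing function's tag and the
#' specific output key to the base name, e.g. base `sub001_sess1`, tag
#' `layering`, key `depth` gives `sub001_sess1_layering_depth.nii.gz`.
#'
#' @param base base file name (no path separators).
#' @param function_tag short name of the producing stage.
#' @param output_key name of the specific output.
#' @return The composed file name.
#' @export
derive_output_name <- function(base, function_tag, output_key) {
  if (!is.character(base) || length(base) != 1L || !nzchar(base))
    cx_stop("base file name must be a non-empty string", "cx_validation_error")
  for (s in c(base, function_tag, output_key))
    if (grepl("[/\\\\]", s))
      cx_stop(sprintf("name component contains a path separator: %s", s),
              "cx_validation_error")
  sprintf("%s_%s_%s.nii.gz", base, function_tag, output_key)
}

#' Bundle stage outputs into an output set
#'
#' Stage functions return their multiple outputs as a named set of volumes
#' (the R analogue of a result dictionary). All entries must share one grid.
#'
#' @param entries named list; each element a `cx_volume` or a list of
#'   `cx_volume`s (a stack).
#' @param function_tag tag naming the producing stage, used in file names.
#' @export
output_set <- function(entries, function_tag) {
  if (length(entries) == 0L)
    cx_stop("output set must contain at least one entry", "cx_validation_error")
  if (is.null(names(entries)) || any(!nzchar(names(entries))))
    cx_stop("output set entries must be named", "cx_validation_error")
  flat <- list()
  for (e in entries) {
    if (is_volume(e)) flat <- c(flat, list(e))
    else if (is.list(e) && all(vapply(e, is_volume, logical(1))))
      flat <- c(flat, e)
    else cx_stop("output set entries must be volumes or lists of volumes",
                 "cx_validation_error")
  }
  check_same_grid(flat)
  structure(entries, class = "cx_outputset", function_tag = function_tag)
}

#' @export
print.cx_outputset <- function(x, ...) {
  cat(sprintf("<cx_outputset> stage '%s': %s\n", attr(x, "function_tag"),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Save every entry of an output set
#'
#' Writes one NIfTI file per entry using [derive_output_name()]. Existing
#' files are never overwritten unless `overwrite = TRUE`.
#'
#' @param outputs a [output_set()] (or plain named list of volumes plus a
#'   `function_tag` argument).
#' @param output_dir destination directory, created if absent.
#' @param file_name base file name.
#' @param overwrite logical; opt-in clobbering of existing files.
#' @param function_tag override of the set's stage tag.
#' @return Named character vector mapping output key to written path.
#' @export
save_output_set <- function(outputs, output_dir, file_name, overwrite = FALSE,
                            function_tag = NULL) {
  function_tag <- function_tag %||% attr(outputs, "function_tag")
  if (is.null(function_tag))
    cx_stop("a function_tag is required to name outputs", "cx_validation_error")
  keep <- vapply(outputs, function(e)
    is_volume(e) || (is.list(e) && length(e) > 0L &&
                       all(vapply(e, is_volume, logical(1)))), logical(1))
  outputs <- outputs[keep]
  if (length(outputs) == 0L)
    cx_stop("output set must contain at least one entry", "cx_validation_error")
  paths <- vapply(names(outputs), function(k)
    file.path(output_dir, derive_output_name(file_name, function_tag, k)),
    character(1))
  if (!overwrite) {
    hit <- paths[file.exists(paths)]
    if (length(hit))
      cx_stop(sprintf("output exists and overwrite is not set: %s",
                      paste(hit, collapse = ", ")), "cx_overwrite_error")
  }
  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  for (k in names(outputs)) write_volume(outputs[[k]], paths[[k]])
  paths
}
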