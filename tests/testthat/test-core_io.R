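test_that("volume construction enforces its invariants", {
  expect_s3_class(volume(array(0, c(4, 4, 4))), "cx_volume")
  expect_error(volume(array(0, c(4, 4))), class = "cx_dim_error")
  expect_error(volume(array(0, c(4, 4, 4)), voxel_size = c(1, 0, 1)),
               class = "cx_validation_error")
  expect_error(volume(array(0, c(4, 4, 4)), affine = matrix(0, 4, 4)),
               class = "cx_validation_error")
  expect_error(volume(array(2, c(4, 4, 4)), dtype_tag = "mask"),
               class = "cx_validation_error")
  expect_error(volume(array(0.5, c(4, 4, 4)), dtype_tag = "int"),
               class = "cx_validation_error")
})

test_that("write/read round-trips data, voxel size and affine", {
  aff <- diag(c(0.7, 0.7, 0.7, 1)); aff[1:3, 4] <- c(-20, -24, -18)
  set.seed(1)
  v <- volume(array(rnorm(16^3), c(16, 16, 16)), voxel_size = c(0.7, 0.7, 0.7),
              affine = aff)
  path <- file.path(tempdir(), "rt.nii.gz")
  write_volume(v, path)
  r <- read_volume(path)
  # on-disk storage is float32; round-trip exact at that precision
  expect_lt(max(abs(r$data - v$data)), 1e-5)
  expect_equal(r$voxel_size, c(0.7, 0.7, 0.7), tolerance = 1e-6)
  expect_equal(r$affine, aff, tolerance = 1e-4)
  unlink(path)
})

test_that("mask volumes are stored with an integer on-disk type", {
  m <- ball_volume(12, 4)
  path <- file.path(tempdir(), "mask.nii")
  write_volume(m, path)
  hdr <- RNifti::niftiHeader(path)
  expect_true(hdr$datatype %in% c(2L, 4L, 8L, 256L, 512L))
  r <- read_volume(path)
  expect_equal(r$dtype_tag, "mask")
  expect_identical(r$data, m$data)
  unlink(path)
})

test_that("a .nii.gz path yields a gzip-compressed file equal to its .nii twin", {
  v <- ball_volume(10, 3)
  pgz <- file.path(tempdir(), "twin.nii.gz")
  pnii <- file.path(tempdir(), "twin.nii")
  write_volume(v, pgz)
  write_volume(v, pnii)
  expect_identical(readBin(pgz, "raw", 2), as.raw(c(0x1f, 0x8b)))
  a <- read_volume(pgz); b <- read_volume(pnii)
  expect_identical(a$data, b$data)
  expect_equal(a$affine, b$affine)
  unlink(c(pgz, pnii))
})

test_that("read_volume rejects missing files, junk payloads and 4-D images", {
  expect_error(read_volume(file.path(tempdir(), "nope.nii")),
               class = "cx_not_found_error")
  junk <- file.path(tempdir(), "junk.nii")
  writeBin(as.raw(1:64), junk)
  suppressWarnings(
    expect_error(read_volume(junk), class = "cx_format_error"))
  unlink(junk)
  p4 <- file.path(tempdir(), "four.nii")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 3))), p4)
  expect_error(read_volume(p4), class = "cx_dim_error")
  expect_match(tryCatch(read_volume(p4), error = conditionMessage), "axis")
  unlink(p4)
})

test_that("derive_output_name composes the stage/output modifiers", {
  expect_identical(derive_output_name("sub001_sess1", "layering", "depth"),
                   "sub001_sess1_layering_depth.nii.gz")
  expect_identical(derive_output_name("x", "f", "o"), "x_f_o.nii.gz")
  expect_error(derive_output_name("", "f", "o"), class = "cx_validation_error")
  expect_error(derive_output_name("a/b", "f", "o"),
               class = "cx_validation_error")
})

test_that("save_output_set writes one correctly named file per entry", {
  v <- ball_volume(10, 3)
  s <- output_set(list(gwb = vol_like2(v, v$data + 1),
                       cgb = vol_like2(v, v$data + 2)), "cruise")
  dir <- file.path(tempdir(), "outset")
  paths <- save_output_set(s, dir, "sub001_sess1")
  expect_setequal(basename(paths),
                  c("sub001_sess1_cruise_gwb.nii.gz",
                    "sub001_sess1_cruise_cgb.nii.gz"))
  expect_true(all(file.exists(paths)))
  # reload onto the same grid
  r <- lapply(paths, read_volume)
  expect_true(all(vapply(r, function(x)
    all(dim(x$data) == dim(v$data)), logical(1))))
  # collisions error unless overwrite is set, and leave files untouched
  before <- file.mtime(paths[1])
  expect_error(save_output_set(s, dir, "sub001_sess1"),
               class = "cx_overwrite_error")
  expect_identical(file.mtime(paths[1]), before)
  expect_silent(save_output_set(s, dir, "sub001_sess1", overwrite = TRUE))
  expect_error(output_set(list(), "x"), class = "cx_validation_error")
  unlink(dir, recursive = TRUE)
})
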