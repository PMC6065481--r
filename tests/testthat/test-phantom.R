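test_that("nested-spheres white matter volume matches the analytic ball", {
  ph <- make_phantom(phantom_spec(shape = 64, geometry = "nested_spheres",
                                  r_inner = 10, r_outer = 14, noise_sd = 0,
                                  seed = 1))
  wm <- sum(ph$truth_labels$data == 3)
  expect_lt(abs(wm - 4 / 3 * pi * 10^3) / (4 / 3 * pi * 10^3), 0.02)
  # oracle: count of voxel centers closer than r_inner
  g <- coord_grids(64)
  expect_identical(wm, sum(radius_field(g) < 10))
})

test_that("slab geometry gives two parallel planar boundaries of constant thickness", {
  ph <- make_phantom(phantom_spec(shape = 48, geometry = "slab",
                                  r_inner = 10, r_outer = 14, noise_sd = 0,
                                  seed = 1))
  lab <- ph$truth_labels$data
  gm_cols <- apply(lab == 2, c(1, 2), sum)
  expect_true(all(gm_cols == gm_cols[1, 1])) # constant GM thickness
  zprof <- apply(lab == 2, 3, sum)
  on <- which(zprof > 0)
  expect_identical(on, seq(min(on), max(on))) # one contiguous z-range
})

test_that("phantom generation is a pure function of its spec", {
  s <- phantom_spec(shape = 32, geometry = "folded_cortex", r_inner = 7,
                    r_outer = 10, noise_sd = 0.2, seed = 77)
  a <- make_phantom(s); b <- make_phantom(s)
  expect_identical(a$truth_labels$data, b$truth_labels$data)
  for (cn in names(a$contrasts))
    expect_identical(a$contrasts[[cn]]$data, b$contrasts[[cn]]$data)
})

test_that("white matter of sphere-like geometries is one 6-connected genus-0 body", {
  for (geo in c("nested_spheres", "folded_cortex")) {
    ph <- make_phantom(phantom_spec(shape = 48, geometry = geo, r_inner = 9,
                                    r_outer = 13, noise_sd = 0, seed = 2))
    wm <- ph$truth_labels$data == 3
    expect_identical(max(connected_components(wm, 6)), 1L)
    expect_identical(euler_characteristic(wm), 1L)
  }
})

test_that("the folded cortex has gyral and sulcal (sign-changing) curvature", {
  ph <- make_phantom(phantom_spec(shape = 48, voxel_size = c(1, 1, 1),
                                  geometry = "folded_cortex", r_inner = 9,
                                  r_outer = 13, noise_sd = 0, seed = 2))
  wm <- ph$truth_labels$data == 3
  ls <- probability_to_levelset(vol_like2(ph$truth_labels, wm * 1))
  k <- mean_curvature(ls)$data
  near <- abs(ls$phi$data) < 1
  expect_gt(sum(k[near] > 0.02), 100)
  expect_gt(sum(k[near] < -0.02), 100)
})

test_that("simulated contrasts have the requested class means and noise scale", {
  ph <- make_phantom(phantom_spec(shape = 64, geometry = "nested_spheres",
                                  noise_sd = 0, seed = 3))
  tp <- default_tissue_params()
  for (cn in names(ph$contrasts)) {
    img <- ph$contrasts[[cn]]$data
    expect_equal(unname(img[ph$truth_labels$data == 3][1]),
                 tp[[cn]]$wm_left[1])
    expect_lte(length(unique(as.vector(img))),
               length(unique(as.vector(ph$truth_labels$data))))
  }
  # noise sd within 5% of nominal on ~1e5 background voxels
  phn <- make_phantom(phantom_spec(shape = 64, geometry = "nested_spheres",
                                   noise_sd = 0.1, seed = 3))
  bg <- phn$truth_labels$data == 0
  expect_gt(sum(bg), 1e5)
  nominal <- 0.1 * tp$inv2$background[2]
  expect_lt(abs(sd(phn$contrasts$inv2$data[bg]) - nominal) / nominal, 0.05)
})

test_that("contrast simulation validates its inputs", {
  ph <- make_phantom(phantom_spec(shape = 24, geometry = "nested_spheres",
                                  r_inner = 5, r_outer = 8, noise_sd = 0,
                                  seed = 1))
  expect_error(simulate_contrasts(ph$truth_labels, contrasts = "swi"),
               class = "cx_validation_error")
  broken <- default_tissue_params()
  broken$inv2$wm_left <- NULL
  expect_error(simulate_contrasts(ph$truth_labels, broken),
               class = "cx_validation_error")
  expect_error(phantom_spec(r_inner = 12, r_outer = 10),
               class = "cx_validation_error")
  expect_error(phantom_spec(shape = 24, r_inner = 10, r_outer = 14),
               class = "cx_validation_error")
})

test_that("the resolution change from 1.0 mm to 0.7 mm triples the voxel count", {
  expect_identical(round(voxel_count_ratio(192, 1.0, 0.7)), 3)
  expect_identical(round(voxel_count_ratio(c(192, 224, 168), 1.0, 0.7)), 3)
})
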