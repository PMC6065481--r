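test_that("a binary ball becomes a signed distance function with the right depth", {
  ball <- ball_volume(41, 10, c(21, 21, 21))
  ls <- probability_to_levelset(ball)
  expect_lte(abs(ls$phi$data[21, 21, 21] - (-10)), 0.5 + 1e-9)
  # oracle: exact Euclidean distance transform to the background voxels
  edt <- cortexr:::edt_distance(!(ball$data != 0), c(1, 1, 1))
  expect_lte(abs(abs(ls$phi$data[21, 21, 21]) - edt[21, 21, 21]), 0.5 + 1e-9)
  # interior negative, exterior positive
  expect_true(all(ls$phi$data[ball$data == 1] <= 0))
  expect_true(all(ls$phi$data[ball$data == 0] > 0))
})

test_that("the zero crossing sits on the 0.5 isosurface", {
  g <- coord_grids(41)
  r <- radius_field(g)
  p <- volume(1 / (1 + exp((r - 10) * 2)))
  ls <- probability_to_levelset(p)
  half <- abs(p$data - 0.5) < 0.05
  expect_true(all(abs(ls$phi$data[half]) <= 1))
  # sub-voxel: phi approximates r - 10 near the surface
  near <- abs(ls$phi$data) < 2
  expect_lt(max(abs(ls$phi$data[near] - (r[near] - 10))), 0.35)
})

test_that("degenerate classifications are rejected", {
  expect_error(probability_to_levelset(volume(array(1, c(8, 8, 8)))),
               class = "cx_degenerate_error")
  expect_error(probability_to_levelset(volume(array(0, c(8, 8, 8)))),
               class = "cx_degenerate_error")
  expect_error(probability_to_levelset(volume(array(2, c(8, 8, 8)))),
               class = "cx_validation_error")
})

test_that("levelset_to_mask inverts probability_to_levelset on binary input", {
  ball <- ball_volume(41, 10, c(21, 21, 21))
  m <- levelset_to_mask(probability_to_levelset(ball))
  expect_gte(dice(m$data, ball$data), 0.99)
  # uniform positive phi -> empty mask
  up <- levelset(volume(array(3, c(8, 8, 8))))
  expect_true(all(levelset_to_mask(up)$data == 0))
})

test_that("reinitialization restores the distance property without moving the surface", {
  g <- coord_grids(41)
  r <- radius_field(g)
  sdf <- volume(r - 10)
  # doubled input comes back as the distance to the same sphere
  re <- reinitialize(levelset(volume(2 * (r - 10))))
  band <- abs(sdf$data) <= 5
  expect_lt(max(abs(re$phi$data[band] - sdf$data[band])), 0.5)
  # idempotence on an already-valid SDF
  re2 <- reinitialize(levelset(sdf))
  expect_lt(max(abs(re2$phi$data[band] - sdf$data[band])), 0.3)
  # sign preserved voxelwise away from the boundary
  away <- abs(sdf$data) > 1
  expect_true(all(sign(re2$phi$data[away]) == sign(sdf$data[away])))
  expect_error(reinitialize(levelset(volume(array(1, c(8, 8, 8))))),
               class = "cx_degenerate_error")
})

test_that("the Eikonal property holds in the band after creation", {
  set.seed(42)
  for (i in 1:5) {
    ls <- probability_to_levelset(random_smooth_proba(48))
    expect_lte(max(eikonal_residual(ls, band = 5)), 0.1)
  }
})

test_that("mean curvature matches the analytic sphere and slab values", {
  g <- coord_grids(48)
  r <- radius_field(g)
  k10 <- mean_curvature(levelset(volume(r - 10)))$data
  near10 <- abs(r - 10) < 1
  expect_lt(abs(mean(k10[near10]) - 0.1) / 0.1, 0.15)
  k20 <- mean_curvature(levelset(volume(r - 20)))$data
  near20 <- abs(r - 20) < 1
  expect_lt(abs(mean(k20[near20]) / mean(k10[near10]) - 0.5), 0.1)
  slab <- volume(abs(g$Z - g$center[3]) - 8)
  ks <- mean_curvature(levelset(slab))$data
  expect_lt(max(abs(ks[abs(slab$data) < 2])), 0.02)
})

test_that("evolution is stationary under zero forcing", {
  ls <- probability_to_levelset(ball_volume(41, 10, c(21, 21, 21)))
  e <- evolve_levelset(ls, 0, curvature_weight = 0, max_iter = 20)
  near <- abs(ls$phi$data) < 1
  expect_lt(max(abs(e$phi$data[near] - ls$phi$data[near])), 0.5)
  expect_identical(attr(e, "reason"), "converged")
})

test_that("uniform unit outward speed grows a sphere by about k steps of dt", {
  ls <- probability_to_levelset(ball_volume(48, 10, c(24, 24, 24)))
  g <- coord_grids(48, c(24, 24, 24))
  r <- radius_field(g)
  e <- evolve_levelset(ls, 1, max_iter = 10, tol = 1e-6, dt = 0.4)
  cross <- abs(e$phi$data) < 1
  radius <- mean(r[cross] - e$phi$data[cross])
  expect_lt(abs(radius - (9.5 + 10 * 0.4)), 1.0)
  expect_error(evolve_levelset(ls, volume(array(NaN, c(48, 48, 48)))),
               class = "cx_validation_error")
})

test_that("topology preservation keeps two inflating balls separate", {
  g <- coord_grids(48)
  r1 <- sqrt((g$X - 17)^2 + (g$Y - 24)^2 + (g$Z - 24)^2)
  r2 <- sqrt((g$X - 31)^2 + (g$Y - 24)^2 + (g$Z - 24)^2)
  two <- volume((r1 < 5 | r2 < 5) * 1)
  ls <- probability_to_levelset(two)
  e <- evolve_levelset(ls, 1, preserve_topology = TRUE, max_iter = 12,
                       tol = 1e-6, track_topology = TRUE)
  mask <- levelset_to_mask(e)$data
  expect_identical(max(connected_components(mask, 6)), 2L)
  tr <- attr(e, "topology_trace")
  expect_true(all(tr$euler == 2L))
  expect_true(all(tr$components == 2L))
  # without preservation the fronts merge
  en <- evolve_levelset(ls, 1, preserve_topology = FALSE, max_iter = 12,
                        tol = 1e-6)
  expect_identical(max(connected_components(levelset_to_mask(en)$data, 6)),
                   1L)
})
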