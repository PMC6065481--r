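test_that("the equivolume position solves the linear-area volume balance", {
  # boundary conditions and flat limit hold for any areas
  for (a in list(c(1, 1), c(100, 196), c(3, 0.5))) {
    expect_equal(equivolume_fraction(0, a[1], a[2]), 0)
    expect_equal(equivolume_fraction(1, a[1], a[2]), 1)
  }
  expect_equal(equivolume_fraction(c(0.2, 0.7), 5, 5), c(0.2, 0.7))
  # sphere r 10 -> 14: closed form vs an independent numeric root of the
  # volume-conservation integral under the linear area model
  a_in <- 100; a_out <- 196
  target <- function(alpha, rho) {
    num <- integrate(function(t) a_in + (a_out - a_in) * t, 0, alpha)$value
    den <- integrate(function(t) a_in + (a_out - a_in) * t, 0, 1)$value
    num / den - rho
  }
  for (rho in c(0.25, 0.5, 0.9)) {
    root <- uniroot(target, c(0, 1), rho = rho, tol = 1e-10)$root
    expect_equal(equivolume_fraction(rho, a_in, a_out), root,
                 tolerance = 1e-7)
  }
  expect_equal(equivolume_fraction(0.5, 100, 196), 0.579, tolerance = 1e-3)
  # and the corresponding radius is close to the exact equivolume sphere
  r_mid <- 10 + equivolume_fraction(0.5, 100, 196) * 4
  expect_lt(abs(r_mid - ((10^3 + 14^3) / 2)^(1 / 3)), 0.05)
  # monotone in rho
  al <- equivolume_fraction(seq(0, 1, 0.05), 100, 196)
  expect_true(all(diff(al) > 0))
  expect_error(equivolume_fraction(0.5, -1, 2), class = "cx_validation_error")
})

sphere_layering <- function(n = 48, r_in = 10, r_out = 14, n_layers = 4) {
  g <- coord_grids(n)
  r <- radius_field(g)
  list(lay = volumetric_layering(levelset(volume(r - r_in)),
                                 levelset(volume(r - r_out)),
                                 n_layers = n_layers), r = r)
}

test_that("the mid-depth surface of nested spheres sits at the equivolume radius", {
  sl <- sphere_layering()
  phim <- sl$lay$boundaries[[3]]$data # rho = 0.5 with n_layers = 4
  sel <- abs(phim) < 1.5
  r_mid <- mean(sl$r[sel] - phim[sel])
  r_exact <- ((10^3 + 14^3) / 2)^(1 / 3)
  expect_lt(abs(r_mid - r_exact) / r_exact, 0.02)
})

test_that("laminae carve the cortical volume into near-equal parts", {
  sl <- sphere_layering()
  vols <- vapply(sl$lay$boundaries, levelset_volume, numeric(1))
  lam <- diff(vols)
  expect_lt(max(abs(lam / mean(lam) - 1)), 0.05)
  expect_identical(sort(unique(as.vector(
    sl$lay$layers$data[sl$lay$layers$data > 0]))), 1:4)
  expect_length(sl$lay$boundaries, 5L)
})

test_that("depth is a continuous [0,1] coordinate anchored on the two boundaries", {
  sl <- sphere_layering()
  depth <- sl$lay$depth$data
  expect_gte(min(depth), 0)
  expect_lte(max(depth), 1)
  inner <- sl$lay$boundaries[[1]]$data
  outer <- sl$lay$boundaries[[5]]$data
  # anchored exactly on the boundaries: 0 at/inside the gray-white
  # crossing, 1 at/outside the pial crossing
  expect_true(all(depth[inner <= 0] == 0))
  expect_true(all(depth[outer > 0] == 1))
  # and within 0.02 of the exact equivolume depth through the cortex
  ctx <- sl$lay$layers$data > 0
  dex <- (sl$r^3 - 10^3) / (14^3 - 10^3)
  expect_lt(max(abs(depth[ctx] - dex[ctx])), 0.02)
  # laminae labels match the depth bins inside the cortex
  ctx <- sl$lay$layers$data > 0
  expect_true(all(abs(sl$lay$layers$data[ctx] -
                        pmin(pmax(ceiling(depth[ctx] * 4), 1), 4)) == 0))
  # boundaries nested voxelwise
  for (j in 2:5)
    expect_true(all(sl$lay$boundaries[[j]]$data <=
                      sl$lay$boundaries[[j - 1]]$data + 1e-9))
})

test_that("a flat slab reduces to the equidistant model", {
  g <- coord_grids(40)
  inner <- levelset(volume(g$Z - 14))
  outer <- levelset(volume(g$Z - 24))
  lay <- volumetric_layering(inner, outer, n_layers = 4)
  ctx <- lay$layers$data > 0
  d_in <- pmax(g$Z - 14, 0); d_out <- pmax(24 - g$Z, 0)
  alpha <- d_in / pmax(d_in + d_out, 1e-9)
  expect_lt(max(abs(lay$depth$data[ctx] - alpha[ctx])), 0.02)
})

test_that("curvature shifts the mid-surface outward on crowns and inward in sulci", {
  ph <- make_phantom(phantom_spec(shape = 48, voxel_size = c(1, 1, 1),
                                  geometry = "folded_cortex", r_inner = 9,
                                  r_outer = 13, noise_sd = 0, seed = 2))
  lab <- ph$truth_labels$data
  inner <- probability_to_levelset(volume(array((lab == 3) * 1, dim(lab))))
  outer <- probability_to_levelset(volume(array((lab %in% 2:3) * 1,
                                                dim(lab))))
  lay <- volumetric_layering(inner, outer, n_layers = 2)
  d_in <- pmax(inner$phi$data, 0)
  d_out <- pmax(-outer$phi$data, 0)
  alpha_eq <- d_in / pmax(d_in + d_out, 1e-9)
  ctx <- lay$layers$data > 0 & d_in + d_out > 2
  # classify columns from the phantom's own fold field: crests of the
  # radial perturbation are gyral crowns (inner surface convex), dips are
  # sulcal fundi — independent of the package's curvature estimate
  g <- coord_grids(48)
  x <- g$X - g$center[1]; y <- g$Y - g$center[2]; z <- g$Z - g$center[3]
  r0 <- pmax(sqrt(x^2 + y^2 + z^2), 1e-9)
  P <- 2.5 * sin(3 * pi * x / r0) * sin(3 * pi * y / r0) *
    sin(3 * pi * z / r0)
  gyral <- ctx & P > 2
  sulcal <- ctx & P < -2
  expect_gt(sum(gyral), 50)
  expect_gt(sum(sulcal), 50)
  # depth < alpha_eq on crowns (mid surface pushed outward), reversed in
  # sulci
  expect_gt(mean(lay$depth$data[gyral] < alpha_eq[gyral] - 1e-6), 0.9)
  expect_gt(mean(lay$depth$data[sulcal] > alpha_eq[sulcal] + 1e-6), 0.9)
})

test_that("invalid layering inputs are rejected", {
  g <- coord_grids(24)
  r <- radius_field(g)
  inner <- levelset(volume(r - 8)); outer <- levelset(volume(r - 5))
  expect_error(volumetric_layering(inner, outer, 4),
               class = "cx_validation_error")
  expect_error(volumetric_layering(levelset(volume(r - 5)),
                                   levelset(volume(r - 8)), 0),
               class = "cx_validation_error")
})
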