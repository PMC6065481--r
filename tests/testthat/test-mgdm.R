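# helpers: contrast models matched to the phantom at a given noise level
phantom_models <- function(noise_sd, prefix = "Test") {
  tp <- default_tissue_params()
  for (cn in names(tp))
    tp[[cn]] <- lapply(tp[[cn]], function(p) c(p[1], max(noise_sd, 0.02) *
                                                 p[2]))
  register_phantom_models(tp, prefix = prefix)
}

folded_seg <- function(noise_sd = 0.1, seed = 4, shape = 48,
                       r_in = 9, r_out = 13) {
  ph <- make_phantom(phantom_spec(shape = shape, voxel_size = c(1, 1, 1),
                                  geometry = "folded_cortex", r_inner = r_in,
                                  r_outer = r_out, noise_sd = noise_sd,
                                  seed = seed))
  mods <- phantom_models(noise_sd)
  structures <- phantom_labels()[1:4, ]
  seg <- mgdm_segmentation(list(ph$contrasts$t1w, ph$contrasts$t1map),
                           c(mods[["t1w"]], mods[["t1map"]]), structures)
  list(ph = ph, seg = seg, structures = structures)
}

test_that("a noiseless two-class phantom is classified exactly", {
  ball <- ball_volume(32, 9, c(16, 16, 16))
  lab <- vol_like2(ball, ball$data * 3) # background(0) and white matter(3)
  lab$dtype_tag <- "int"
  contr <- simulate_contrasts(lab, noise_sd = 0, seed = 1,
                              contrasts = "t1w")
  mods <- phantom_models(0)
  structures <- phantom_labels()[c(1, 4), ]
  seg <- mgdm_segmentation(list(contr$t1w), mods[["t1w"]], structures)
  expect_true(all(seg$segmentation$data == lab$data))
  expect_true(all(seg$memberships[[1]]$data >= 0.99))
})

test_that("the 4-class folded phantom is recovered at 10% noise with Dice >= 0.9", {
  fs <- folded_seg(0.1)
  for (id in 0:3)
    expect_gte(dice(fs$seg$segmentation$data == id,
                    fs$ph$truth_labels$data == id), 0.9)
})

test_that("the result exposes segmentation, distance, memberships and labels", {
  fs <- folded_seg(0.05, shape = 32, r_in = 7, r_out = 10)
  expect_true(all(c("segmentation", "distance", "memberships", "labels") %in%
                    names(fs$seg)))
  expect_length(fs$seg$memberships, 4L)
  m <- fs$seg
  # ranks descending, sum bounded, rank-1 agrees with the segmentation
  for (r in 2:4)
    expect_true(all(m$memberships[[r]]$data <=
                      m$memberships[[r - 1]]$data + 1e-9))
  tot <- Reduce(`+`, lapply(m$memberships, function(v) v$data))
  expect_lte(max(tot), 1 + 1e-6)
  expect_identical(m$segmentation$data, m$labels[[1]]$data)
  # distance is zero exactly on inter-structure boundary voxels
  expect_gte(min(m$distance$data), 0)
  bnd <- m$distance$data == 0
  expect_gt(sum(bnd), 0)
  # distance agrees with the level-set distance of the winning-label masks
  wm <- m$segmentation$data == 3
  ls <- probability_to_levelset(vol_like2(m$segmentation, wm * 1))
  near_wm <- abs(ls$phi$data) < 3 & wm
  expect_lt(max(abs(m$distance$data[near_wm] - abs(ls$phi$data[near_wm]))),
            1 + 1e-9)
})

test_that("topology preservation keeps every structure's Euler characteristic", {
  fs <- folded_seg(0.12, seed = 8)
  # genus-0 structures of the folded phantom
  for (id in c(2, 3)) {
    m <- fs$seg$segmentation$data == id
    expect_identical(euler_characteristic(m),
                     euler_characteristic(fs$ph$truth_labels$data == id))
  }
  # genus-1: torus-shaped structure embedded in background
  tor <- torus_mask(41, 10, 4)
  lab <- volume(array(tor * 3L, dim(tor)), dtype_tag = "int")
  contr <- simulate_contrasts(lab, noise_sd = 0.15, seed = 2,
                              contrasts = "t1w")
  mods <- phantom_models(0.15)
  seg <- mgdm_segmentation(list(contr$t1w), mods[["t1w"]],
                           phantom_labels()[c(1, 4), ])
  expect_identical(euler_characteristic(seg$segmentation$data == 3), 0L)
  expect_gte(dice(seg$segmentation$data == 3, tor), 0.95)
})

test_that("an informative second contrast does not hurt recovery", {
  # higher noise so the single-contrast run has room to improve
  d1 <- d2 <- numeric(0)
  for (seed in 1:10) {
    ph <- make_phantom(phantom_spec(shape = 32, voxel_size = c(1, 1, 1),
                                    geometry = "folded_cortex", r_inner = 7,
                                    r_outer = 10, noise_sd = 2,
                                    seed = seed))
    mods <- phantom_models(2)
    structures <- phantom_labels()[1:4, ]
    s1 <- mgdm_segmentation(list(ph$contrasts$t1w), mods[["t1w"]],
                            structures)
    s2 <- mgdm_segmentation(list(ph$contrasts$t1w, ph$contrasts$t1map),
                            c(mods[["t1w"]], mods[["t1map"]]), structures)
    gm <- ph$truth_labels$data == 2
    d1 <- c(d1, dice(s1$segmentation$data == 2, gm))
    d2 <- c(d2, dice(s2$segmentation$data == 2, gm))
  }
  expect_gte(mean(d2), mean(d1))
})

test_that("contrast model registration validates and errors as specified", {
  expect_error(mgdm_segmentation(list(ball_volume(8, 3)), "NoSuchModel",
                                 phantom_labels()[1:2, ]),
               class = "cx_validation_error")
  expect_error(contrast_model("bad", c(a = 1), c(a = 0)),
               class = "cx_validation_error")
  m <- contrast_model("TmpModel", c(background = 0, wm_left = 10),
                      c(background = 1, wm_left = 1))
  register_contrast_model(m)
  expect_identical(get_contrast_model("TmpModel")$class_means[["wm_left"]],
                   10)
  expect_message(register_contrast_model(m), "re-registered")
  # model lacking a needed class
  expect_error(
    mgdm_segmentation(list(ball_volume(8, 3)), "TmpModel",
                      phantom_labels()[1:4, ]),
    class = "cx_validation_error")
})
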