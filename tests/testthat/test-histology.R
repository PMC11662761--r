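# eYFP transection thresholding, EC/NR white-matter loss, and g-ratio
# remyelination classification.

test_that("standardized ratio averages per-image healthy-WM/GM ratios", {
  eq <- uniform_eyfp_image(gm = 50, wm = 50)
  expect_equal(eyfp_standardized_ratio(list(eq)), 1.0)
  two <- list(uniform_eyfp_image(gm = 100, wm = 120),
              uniform_eyfp_image(gm = 200, wm = 280))
  expect_equal(eyfp_standardized_ratio(two), 1.3) # mean of 1.2 and 1.4

  sims <- lapply(1:6, function(i)
    gen_eyfp_image(noise_sd = 2, seed = 40 + i)$image)
  expect_equal(eyfp_standardized_ratio(sims), 1.25, tolerance = 0.02)
})

test_that("mask invariants are enforced", {
  img <- matrix(1, 10, 10)
  m1 <- matrix(FALSE, 10, 10); m1[, 1:5] <- TRUE
  expect_error(image_with_masks(img, m1, m1), "overlap")
  expect_error(image_with_masks(img, m1, !m1, healthy_wm_mask = !m1), "subset")
  expect_error(image_with_masks(img, matrix(FALSE, 10, 10), m1), "empty")
})

test_that("suprathreshold percent matches construction and is strict", {
  healthy <- uniform_eyfp_image(gm = 100, wm = 125)
  res <- eyfp_percent_transection(healthy, ratio = 1, factor = 1.5)
  expect_equal(res$percent_transection, 0) # 125 < 150, nothing exceeds
  expect_equal(res$threshold, 150)

  sim <- gen_eyfp_image(target_fraction = 0.1, seed = 2)
  r <- eyfp_standardized_ratio(list(sim$image))
  out <- eyfp_percent_transection(sim$image, r, factor = 1.5)
  expect_equal(out$percent_transection, 10.0)
  expect_equal(out$percent_transection, sim$true_percent)

  # pixels exactly at threshold do not count (strictly greater)
  at <- uniform_eyfp_image(gm = 100, wm = 150)
  expect_equal(eyfp_percent_transection(at, ratio = 1, factor = 1.5)$percent_transection, 0)
})

test_that("eYFP percent is invariant to global intensity scaling", {
  sim <- gen_eyfp_image(target_fraction = 0.07, noise_sd = 3, seed = 9)
  r <- eyfp_standardized_ratio(list(sim$image))
  p1 <- eyfp_percent_transection(sim$image, r)$percent_transection
  scaled <- sim$image
  scaled$intensity <- scaled$intensity * 3
  r2 <- eyfp_standardized_ratio(list(scaled))
  expect_equal(r2, r, tolerance = 1e-12)
  expect_equal(eyfp_percent_transection(scaled, r2)$percent_transection, p1)
})

test_that("NR-positive fraction of white matter matches painted lesions", {
  h <- 20; w <- 40
  wm <- matrix(FALSE, h, w); wm[, 21:40] <- TRUE
  blue <- array(0, c(h, w, 3)); blue[, , 3] <- 0.8; blue[, , 1] <- 0.1
  expect_equal(nr_percent_wm_loss(blue, wm), 0)

  lesion <- blue
  lesion[, 36:40, 1] <- 0.9 # 25% of WM columns painted red
  lesion[, 36:40, 3] <- 0.2
  expect_equal(nr_percent_wm_loss(lesion, wm), 25.0)

  red <- blue
  red[, , 1] <- 0.9; red[, , 3] <- 0.2
  expect_equal(nr_percent_wm_loss(red, wm), 100)
  expect_error(nr_percent_wm_loss(blue[, , 1:2], wm), "three-channel")
})

test_that("concentric disks recover the analytic r/R g-ratio", {
  for (r_in in c(10, 20, 40, 80)) {
    side <- ceiling(2.6 * r_in / 0.8)
    ax <- matrix(0L, side, side)
    my <- matrix(0L, side, side)
    res <- eaequant:::rasterize_annulus(ax, my, side / 2, side / 2,
                                        r_in, r_in, r_in / 0.8, r_in / 0.8,
                                        0, 1L)
    rec <- gratio_records(res$axon, res$myelin, pixel_size_um = 0.01,
                          min_axon_area_px = 5)
    expect_equal(nrow(rec), 1)
    # discretization error shrinks with radius
    expect_lt(abs(rec$g - 0.8), 2 / r_in)
    if (r_in >= 40) expect_lt(abs(rec$g - 0.8), 0.01)
  }
})

test_that("axons with no myelin have g = 1 and are not myelinated", {
  af <- gen_axon_field(n_axons = 6, g_targets = 1, seed = 5)
  rec <- gratio_records(af$axon_mask, af$myelin_mask, af$pixel_size_um)
  expect_true(all(rec$g == 1))
  expect_true(all(!rec$myelinated))
  expect_true(all(!rec$remyelinating))
})

test_that("g-ratios equal an independent pixel-count oracle on random annuli", {
  af <- gen_axon_field(width = 800, height = 800, n_axons = 50, seed = 13)
  rec <- gratio_records(af$axon_mask, af$myelin_mask, af$pixel_size_um)
  expect_gte(nrow(rec), 40)
  for (i in seq_len(nrow(rec))) {
    expect_identical(rec$g[i],
                     oracle_g(af$axon_mask, af$myelin_mask, rec$label[i]))
  }
  expect_true(all(rec$g > 0 & rec$g <= 1))
})

test_that("border-touching axons, specks and orphan myelin are excluded", {
  ax <- matrix(0L, 40, 40)
  my <- matrix(0L, 40, 40)
  ax[18:22, 18:22] <- 1L # interior axon, 25 px
  my[16:24, 16:24] <- 1L
  my[18:22, 18:22] <- 0L
  ax[1:4, 10:14] <- 2L   # touches the border
  ax[30:31, 30:31] <- 3L # 4 px speck
  my[35:38, 2:5] <- 9L   # orphan myelin
  expect_warning(rec <- gratio_records(ax, my, pixel_size_um = 2),
                 "myelin labels without a matching axon.*9")
  expect_equal(rec$label, 1L)
  expect_equal(rec$axon_area_um2, 25 * 4)
  expect_equal(rec$g, sqrt(25 / 81))
})

test_that("remyelination summary counts strictly above the cutoff", {
  rec <- data.frame(label = 1:3, axon_area_um2 = 1, myelin_area_um2 = 1,
                    g = c(0.75, 0.85, 0.90), myelinated = TRUE,
                    remyelinating = NA)
  s <- remyelination_summary(rec, field_area_um2 = 100)
  expect_equal(s$n_remyelinating, 2)
  expect_equal(s$percent_remyelinating, 200 / 3, tolerance = 1e-12)

  exact <- rec; exact$g <- c(0.8, 0.8, 0.8)
  expect_equal(remyelination_summary(exact, 100)$n_remyelinating, 0)

  ten <- data.frame(label = 1:10, axon_area_um2 = 1, myelin_area_um2 = 1,
                    g = c(rep(0.9, 4), rep(0.7, 6)), myelinated = TRUE)
  s10 <- remyelination_summary(ten, field_area_um2 = 100)
  expect_equal(s10$density_remyelinating, 0.04)

  # permutation invariance and the myelinated-only denominator
  shuf <- ten[sample(10), ]
  expect_equal(remyelination_summary(shuf, 100), s10)
  ten$myelinated[5:10] <- FALSE
  ten$g[5:10] <- 1
  sm <- remyelination_summary(ten, 100, percent_denominator = "myelinated")
  expect_equal(sm$percent_remyelinating, 100)

  expect_warning(z <- remyelination_summary(ten[0, ], 100), "no axon records")
  expect_equal(z$n_axons, 0)
})
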