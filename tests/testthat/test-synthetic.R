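test_that("orientation sampling hits the uniform and concentrated limits", {
  gs0 <- sample_layout(synth_config(n_glands = 500, field_size = 2048,
                                    kappa = 0, seed = 2))
  th <- attr(gs0, "truth")$theta_deg
  a <- 2 * th * pi / 180
  resultant <- sqrt(mean(cos(a))^2 + mean(sin(a))^2)
  expect_lt(resultant, 0.1)   # uniform limit on the doubled circle
  gs_hi <- sample_layout(synth_config(n_glands = 100, field_size = 1024,
                                      kappa = 200, mu_deg = 45, seed = 2))
  th_hi <- attr(gs_hi, "truth")$theta_deg
  dev <- pmin(abs(th_hi - 45), 180 - abs(th_hi - 45))
  expect_true(all(dev <= 10))
})

test_that("layout generation is seed-deterministic and respects spacing", {
  cfg <- synth_config(n_glands = 20, kappa = 2, seed = 9)
  a <- sample_layout(cfg); b <- sample_layout(cfg)
  expect_identical(lapply(a$glands, `[[`, "boundary"),
                   lapply(b$glands, `[[`, "boundary"))
  tr <- attr(a, "truth")
  dmat <- as.matrix(dist(tr[, c("cx", "cy")]))
  diag(dmat) <- Inf
  expect_gt(min(dmat), cfg$min_gap)
  # impossible packing errors out rather than hanging
  expect_error(sample_layout(synth_config(n_glands = 50, field_size = 64,
                                          min_gap = 30, seed = 1)),
               "packing")
})

test_that("orientation dispersion decreases with concentration kappa", {
  disp <- sapply(c(0, 2, 20), function(k) {
    mean(sapply(1:20, function(s) {
      th <- attr(sample_layout(synth_config(n_glands = 40, kappa = k,
                                            seed = s)), "truth")$theta_deg
      glandrisk:::axial_dispersion(th)
    }))
  })
  expect_true(all(diff(disp) < 0))
})

test_that("renders put bright lumens inside darker rings on pink stroma", {
  gs0 <- sample_layout(synth_config(n_glands = 0, seed = 1))
  img0 <- render_image(gs0, 128, seed = 1)
  expect_lt(sd(img0$pixels[, , 1]), 5)   # uniform stroma up to pixel noise
  one <- gland_set("one", list(gland(1, ellipse_poly(30, 20, 0, c(64, 64)))),
                   provenance = "synthetic")
  img1 <- render_image(one, 128, seed = 1)
  lum <- 0.2126 * img1$pixels[, , 1] + 0.7152 * img1$pixels[, , 2] +
    0.0722 * img1$pixels[, , 3]
  lab <- glandrisk:::paint_labels(one$glands, c(128, 128)) > 0
  expect_gt(mean(lum[lab & lum > 200]), mean(lum[lab & lum <= 200]))
  # bright lumen pixels form one connected blob inside the gland
  bl <- EBImage::bwlabel(EBImage::Image(t(lab & lum > 220)))
  expect_equal(max(bl), 1)
  im_a <- render_image(one, 128, seed = 4)
  im_b <- render_image(one, 128, seed = 4)
  expect_identical(im_a$pixels, im_b$pixels)
})

test_that("outcome linkage obeys its null and censoring contracts", {
  cfgs <- lapply(1:1000, function(i) synth_config(kappa = runif(1, 0, 5), seed = i))
  co <- simulate_cohort(cfgs, synth_outcome_config(beta_disorder = 0, seed = 3))
  expect_lt(abs(mean(co$recurrence) - 0.5), 3 * sqrt(0.25 / 1000) + 0.02)
  co0 <- simulate_cohort(cfgs[1:50],
                         synth_outcome_config(censor_time = 0, seed = 3))
  expect_true(all(co0$event == 0))
  # same seed => identical cohort
  co_a <- simulate_cohort(cfgs[1:50], synth_outcome_config(seed = 8))
  co_b <- simulate_cohort(cfgs[1:50], synth_outcome_config(seed = 8))
  expect_identical(co_a, co_b)
})

test_that("with a null hazard ratio the log-rank test stays non-significant", {
  cfgs <- lapply(1:100, function(i) synth_config(kappa = 1, seed = i))
  sig <- sapply(1:100, function(r) {
    co <- simulate_cohort(cfgs, synth_outcome_config(
      hr_recurrence = 1, beta_disorder = 0, seed = 1000 + r))
    if (sum(co$recurrence) < 2 || sum(1 - co$recurrence) < 2) return(FALSE)
    g1 <- co$recurrence == 1
    logrank_test(co$survival_time[g1], co$event[g1],
                 co$survival_time[!g1], co$event[!g1])$p < 0.05
  })
  expect_gte(mean(!sig), 0.9)
})
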