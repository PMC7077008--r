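test_that("Kaplan-Meier estimates match hand-computed product limits", {
  km0 <- km_estimate(c(3, 8, 12, 20), rep(0, 4))
  expect_true(all(km0$survival == 1))
  km1 <- km_estimate(c(3, 4, 5, 6, 7), c(1, 0, 0, 0, 0))
  expect_equal(km_survival_at(km1, 3), 0.8)   # (n-1)/n with all 5 at risk
  # textbook set {6, 6, 6, 7, 10+, 13, 16+}
  km2 <- km_estimate(c(6, 6, 6, 7, 10, 13, 16), c(1, 1, 1, 1, 0, 1, 0))
  expect_equal(round(km_survival_at(km2, 6), 3), 0.571)
  expect_equal(round(km_survival_at(km2, 7), 3), 0.429)
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
  # no censoring => empirical survival function
  set.seed(2)
  tt <- rexp(40)
  km3 <- km_estimate(tt, rep(1, 40))
  expect_equal(km3$survival, 1 - ecdf(tt)(km3$times), tolerance = 1e-12)
})

test_that("log-rank is null on identical groups, symmetric, and powered at HR = 3", {
  tt <- c(2, 5, 7, 9, 12); ev <- c(1, 0, 1, 1, 0)
  lr <- logrank_test(tt, ev, tt, ev)
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  set.seed(4)
  t1 <- rexp(30, 0.02); t2 <- rexp(30, 0.05)
  a <- logrank_test(t1, rep(1, 30), t2, rep(1, 30))
  b <- logrank_test(t2, rep(1, 30), t1, rep(1, 30))
  expect_equal(a$chi2, b$chi2)
  expect_error(logrank_test(numeric(0), numeric(0), tt, ev), "non-empty")
  hits <- sapply(1:100, function(r) {
    withr::with_seed(500 + r, {
      t1 <- pmin(rexp(200, 0.01), 60); t2 <- pmin(rexp(200, 0.03), 60)
      logrank_test(t1, as.numeric(t1 < 60), t2, as.numeric(t2 < 60))$p < 0.05
    })
  })
  expect_gte(mean(hits), 0.95)
})

test_that("Cox fits recover known hazard ratios and flag degenerate inputs", {
  # constant covariate: no effect
  set.seed(6)
  cx0 <- cox_fit(data.frame(z = rep(1, 30)), rexp(30), rep(1, 30))
  expect_equal(cx0$hr, 1)
  # HR = 2 parameter recovery
  hrs <- sapply(1:20, function(r) {
    withr::with_seed(r, {
      x <- rep(0:1, each = 500)
      tt <- rexp(1000, 0.01 * 2^x)
      ev <- as.numeric(tt < 100)
      cox_fit(data.frame(x = x), pmin(tt, 100), ev)$hr
    })
  })
  expect_true(median(hrs) >= 1.8 && median(hrs) <= 2.2)
  # monotone likelihood (complete separation) is diagnosed
  x <- rep(0:1, each = 10)
  tt <- c(seq(10, 19), seq(1, 10) / 10)
  cs <- cox_fit(data.frame(x = x), tt, rep(1, 20))
  expect_false(cs$converged)
})

test_that("Cox agrees with direct partial-likelihood maximization on a tiny fixture", {
  set.seed(9)
  n <- 25
  x <- rbinom(n, 1, 0.4)
  tt <- round(rexp(n, 0.05 * 3^x), 6)   # continuous => no ties
  ev <- rbinom(n, 1, 0.8)
  got <- cox_fit(data.frame(x = x), tt, ev)$beta
  npll <- function(b) {   # untied Cox partial likelihood, written out
    s <- 0
    for (i in which(ev == 1)) {
      risk <- tt >= tt[i]
      s <- s + b * x[i] - log(sum(exp(b * x[risk])))
    }
    -s
  }
  want <- optimize(npll, c(-5, 5), tol = 1e-10)$minimum
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("95% CI coverage holds at a large simulated hazard ratio", {
  hr_true <- 9.65
  cover <- sapply(1:100, function(r) {
    withr::with_seed(2000 + r, {
      n <- 250
      x <- rbinom(n, 1, 0.12)
      tt <- rexp(n, 0.0015 * hr_true^x)
      ev <- as.numeric(tt < 100)
      fit <- cox_fit(data.frame(x = x), pmin(tt, 100), ev)
      fit$converged && fit$ci_lower <= hr_true && hr_true <= fit$ci_upper
    })
  })
  expect_gte(sum(cover), 90)
})

test_that("log-rank and Cox Wald p-values rank fixtures consistently", {
  set.seed(33)
  ps <- t(sapply(1:50, function(r) {
    n <- 80
    x <- rep(0:1, each = n / 2)
    hr <- exp(runif(1, -1.2, 1.2))
    tt <- pmin(rexp(n, 0.02 * hr^x), 80)
    ev <- as.numeric(tt < 80)
    lr <- logrank_test(tt[x == 0], ev[x == 0], tt[x == 1], ev[x == 1])$p
    cp <- cox_fit(data.frame(x = x), tt, ev)$p
    c(lr, cp)
  }))
  expect_gt(cor(rank(ps[, 1]), rank(ps[, 2])), 0.9)
})

test_that("chi-square, kappa and biomarker thresholds match their anchors", {
  ind <- matrix(c(25, 25, 25, 25), 2, 2)
  cs <- chi_square(ind)
  expect_equal(cs$chi2, 0)
  expect_equal(cs$p, 1)
  # CEA-by-classifier association
  cea <- matrix(c(65, 8, 9, 183), 2, 2)
  expect_lt(chi_square(cea)$p, 0.001)
  unb <- matrix(c(30, 10, 15, 45), 2, 2)
  expect_equal(chi_square(2 * unb)$chi2, 2 * chi_square(unb)$chi2,
               tolerance = 1e-9)
  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2, 2)), "marginal")
  # Cohen's kappa
  expect_equal(cohens_kappa(c("a", "b", "a"), c("a", "b", "a")), 1)
  ra <- c(rep("x", 20), rep("x", 5), rep("y", 10), rep("y", 15))
  rb <- c(rep("x", 20), rep("y", 5), rep("x", 10), rep("y", 15))
  expect_equal(round(cohens_kappa(ra, rb), 2), 0.40)
  set.seed(12)
  ka <- cohens_kappa(sample(0:1, 1e4, TRUE), sample(0:1, 1e4, TRUE))
  expect_lt(abs(ka), 0.05)
  expect_error(cohens_kappa(1:3, 1:4), "mismatch")
  # biomarker binarization at the clinical cutoffs
  bb <- binarize_biomarkers(c(14, 13.9), c(5, 5.1))
  expect_identical(bb$ki67, c("pos", "neg"))
  expect_identical(bb$cea, c("normal", "elevated"))
  expect_error(binarize_biomarkers(101, 1), "ki67")
})
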