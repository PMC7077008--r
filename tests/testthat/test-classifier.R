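test_that("mean +/- SD discretization yields three reusable levels", {
  x <- c(-10, 0, 10)
  d <- discretize(matrix(x, ncol = 1))
  expect_equal(as.integer(d$levels), c(0L, 1L, 2L))
  dc <- discretize(matrix(rep(5, 4), ncol = 1))
  expect_true(all(dc$levels == 1L))
  set.seed(3)
  X <- matrix(rnorm(60), 20, 3)
  d2 <- discretize(X)
  expect_identical(apply_discretization(X, d2$edges), d2$levels)
})

test_that("mutual information matches its analytic anchors", {
  a <- rep(c(0, 1), 50)
  expect_equal(mutual_information(a, a), 1.0)
  b <- rep(c(0, 0, 1, 1), 25)
  expect_lt(mutual_information(a, b), 0.02)   # independent by construction
  expect_equal(mutual_information(rep(1, 30), sample(0:1, 30, TRUE)), 0)
  expect_error(mutual_information(1:3, 1:4), "mismatch")
})

test_that("greedy mRMR equals brute-force per-step search on random tables", {
  set.seed(10)
  for (r in 1:50) {
    n <- 40
    p <- sample(3:6, 1)
    X <- matrix(sample(0:2, n * p, replace = TRUE), n, p,
                dimnames = list(NULL, paste0("f", 1:p)))
    y <- sample(0:1, n, replace = TRUE)
    m <- sample(2:p, 1)
    got <- mrmr_select(X, y, m)$selected
    # independent brute-force of the greedy objective at every step
    sel <- integer(0)
    for (step in seq_len(m)) {
      cand <- setdiff(seq_len(p), sel)
      obj <- sapply(cand, function(j) {
        rel <- mutual_information(X[, j], y)
        red <- if (length(sel)) mean(sapply(sel, function(s)
          mutual_information(X[, j], X[, s]))) else 0
        rel - red
      })
      sel <- c(sel, cand[which.max(obj)])
    }
    expect_identical(got, paste0("f", sel))
  }
})

test_that("mRMR penalizes a duplicated informative feature", {
  set.seed(77)
  n <- 400
  y <- rep(0:1, n / 2)
  flip <- function(v, rate) ifelse(runif(length(v)) < rate, 1 - v, v)
  f1 <- flip(y, 0.1)
  f2 <- f1                       # exact copy: fully redundant
  f3 <- flip(y, 0.2)             # independently noisy, so non-redundant
  X <- cbind(f1 = f1, f2 = f2, f3 = f3)
  expect_identical(mrmr_select(X, y, 1)$selected, "f1")
  expect_identical(sort(mrmr_select(X, y, 2)$selected), c("f1", "f3"))
  expect_warning(res <- mrmr_select(X, y, 10), "truncat")
  expect_equal(length(res$selected), 3)
})

test_that("cross-validation separates separable classes and not shuffled ones", {
  set.seed(5)
  n <- 200
  y <- rep(0:1, each = n / 2)
  X <- cbind(a = rnorm(n, y * 4), b = rnorm(n, y * 4))  # 4 SD apart
  for (mt in c("svm", "rf", "dac")) {
    fit <- crossval_train(X, y, mt, seed = 11)
    expect_gte(mean(fit$cv_metrics), 0.95)
  }
  fit1 <- crossval_train(X, y, "svm", seed = 3)
  fit2 <- crossval_train(X, y, "svm", seed = 3)
  expect_identical(fit1$fold_assignment, fit2$fold_assignment)
  expect_identical(fit1$cv_metrics, fit2$cv_metrics)
  null_acc <- sapply(1:20, function(r) {
    ys <- withr::with_seed(100 + r, sample(y))
    mean(crossval_train(X, ys, "dac", seed = r)$cv_metrics)
  })
  expect_lt(abs(mean(null_acc) - 0.5), 0.1)
  expect_error(crossval_train(X[1:6, ], y[c(1:3, 101:103)], "svm", folds = 5),
               "stratification")
})

test_that("lock-down picks the best mean CV accuracy with the svm tie-break", {
  mk <- function(type, accs) structure(list(model_type = type,
                                            cv_metrics = accs, locked = FALSE),
                                       class = "fitted_classifier")
  got <- lock_down(list(mk("svm", 0.88), mk("dac", 0.72), mk("rf", 0.75)))
  expect_identical(got$model_type, "svm")
  expect_true(got$locked)
  expect_identical(lock_down(list(mk("rf", 0.8)))$model_type, "rf")
  tie <- lock_down(list(mk("rf", 0.8), mk("svm", 0.8)))
  expect_identical(tie$model_type, "svm")
  expect_error(lock_down(list()), "candidate")
})

test_that("risk prediction binds by feature name and requires a locked model", {
  set.seed(8)
  n <- 200
  y <- rep(0:1, each = n / 2)
  X <- data.frame(a = rnorm(n, y * 4), b = rnorm(n, y * 4))
  fit <- crossval_train(X, y, "svm", seed = 2)
  expect_error(predict_risk(fit, X), "locked")
  model <- lock_down(list(fit))
  pred <- predict_risk(model, X)
  expect_gte(mean((pred == "ECAHBC-positive") == (y == 1)), 0.95)
  expect_identical(predict_risk(model, X[, c("b", "a")]), pred)
  expect_identical(predict_risk(model, X[0, ]), character(0))
  expect_error(predict_risk(model, X["a"]), "missing feature.*b")
})

test_that("confusion metrics reproduce printed counts and satisfy identities", {
  cm <- confusion_from_counts(tp = 48, fp = 26, tn = 189, fn = 6)
  expect_equal(round(cm$accuracy, 3), 0.881)
  expect_equal(round(cm$ppv, 3), 0.649)
  expect_equal(round(cm$npv, 3), 0.969)
  perfect <- confusion_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$ppv, 1)
  none <- confusion_metrics(c(0, 0), c(1, 0))
  expect_true(is.na(none$ppv))
  expect_true("ppv" %in% none$undefined)
  set.seed(21)
  for (r in 1:25) {
    n <- sample(5:60, 1)
    pred <- sample(0:1, n, TRUE); truth <- sample(0:1, n, TRUE)
    m <- confusion_metrics(pred, truth)
    expect_equal(m$tp + m$fp + m$tn + m$fn, n)
    expect_equal(m$accuracy, (m$tp + m$tn) / n)
    if (!is.na(m$ppv)) expect_equal(m$ppv, m$tp / (m$tp + m$fp))
    if (!is.na(m$npv)) expect_equal(m$npv, m$tn / (m$tn + m$fn))
  }
})
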