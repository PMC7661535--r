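test_that("age dichotomization bands", {
  expect_identical(dichotomize_age(c(30, 65, 50, 18, 38, 60, 79, 80, 17)),
                   c(1L, 0L, NA, 1L, 1L, 0L, 0L, NA, NA))
})

test_that("stratified split: sizes, determinism, balance", {
  set.seed(99)
  cohort <- data.frame(age = round(runif(3612, 18, 79)))
  cohort$label <- dichotomize_age(cohort$age)
  sp <- split_cohort(cohort, test_fraction = 0.25, seed = 11)
  expect_equal(nrow(sp$train), 2709)
  expect_equal(nrow(sp$test), 903)
  sp2 <- split_cohort(cohort, test_fraction = 0.25, seed = 11)
  expect_identical(sp$test$age, sp2$test$age)
  # age-decile label proportions agree between train and test (2000 subjects)
  co2 <- data.frame(age = round(runif(2000, 18, 79)))
  co2$label <- dichotomize_age(co2$age)
  s2 <- split_cohort(co2, seed = 5)
  breaks <- quantile(co2$age, 0:10 / 10)
  dec_tr <- cut(s2$train$age, breaks, include.lowest = TRUE)
  dec_te <- cut(s2$test$age, breaks, include.lowest = TRUE)
  p_tr <- tapply(s2$train$label == 1, dec_tr, mean, na.rm = TRUE)
  p_te <- tapply(s2$test$label == 1, dec_te, mean, na.rm = TRUE)
  expect_true(all(abs(p_tr - p_te) < 0.05, na.rm = TRUE))
})

test_that("robust standardization learns on train only", {
  tr <- cbind(x = c(3, 4, 5, 6, 7), y = c(0, 0, 10, 20, 20))
  te <- cbind(x = c(7, 5), y = c(10, 0))
  st <- robust_standardize(tr, te)
  expect_equal(unname(st$center["x"]), 5)
  expect_equal(unname(st$applied[1, "x"]), (7 - 5) / IQR(tr[, "x"]))
  expect_equal(unname(apply(st$train, 2, median)), c(0, 0))
  expect_equal(unname(apply(st$train, 2, IQR)), c(1, 1))
  expect_identical(attr(st$center, "standardized_on"), "train")
  # constant column -> flagged, zeros, warning
  expect_warning(z <- robust_standardize(cbind(c = rep(4, 6))), "zero-IQR")
  expect_true(all(z$train == 0))
  expect_equal(unname(z$flagged), 1L)
})

test_that("ridge ranking recovers a planted two-variable signal", {
  set.seed(10)
  n <- 300; p <- 10
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  y <- 2 * x[, 1] - 2 * x[, 2] + rnorm(n)
  lab <- as.integer(y > median(y))
  rk <- ridge_rank(x, y, lab, n_reps = 20, seed = 2)
  expect_setequal(rk$variable[1:2], c("x1", "x2"))
  # internal consistency: final score is the sum of the two mean ranks,
  # every mean rank lies in [1, p]
  expect_equal(rk$final_score, rk$linear_rank + rk$logistic_rank)
  expect_true(all(rk$linear_rank >= 1 & rk$linear_rank <= p))
  expect_true(all(rk$final_score >= 2 & rk$final_score <= 2 * p))
  rl <- attr(rk, "reps_linear")
  expect_equal(dim(rl), c(20, p))
  expect_true(all(sort(rl[1, ]) == 1:p))
})

test_that("independent pure-noise worlds give unrelated rankings", {
  n <- 200; p <- 10
  draw <- function(seed) {
    set.seed(seed)
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("n", 1:p)))
    rk <- ridge_rank(x, rnorm(n), as.integer(rbinom(n, 1, 0.5)),
                     n_reps = 15, seed = seed)
    rk$final_score[order(rk$variable)]
  }
  expect_lt(cor(draw(31), draw(32), method = "spearman"), 0.5)
})

test_that("kernel classifier: separable case, determinism", {
  set.seed(6)
  x <- rbind(matrix(rnorm(40, -3, 0.3), 20, 2), matrix(rnorm(40, 3, 0.3), 20, 2))
  y <- rep(c(0L, 1L), each = 20)
  cl <- fit_classifier(x, y, seed = 1)
  sc <- predict(cl, x)
  expect_equal(mean((sc > 0) == (y == 1)), 1)       # training accuracy 1.0
  cl2 <- fit_classifier(x, y, seed = 1)
  expect_identical(c(cl$C, cl$gamma), c(cl2$C, cl2$gamma))
  expect_error(fit_classifier(x, rep(1L, 40)), "single class")
})

test_that("ROC/AUC worked cases and null behaviour", {
  expect_equal(roc_curve(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_curve(c(0.9, 0.3, 0.8, 0.4), c(1, 1, 0, 0))$auc, 0.5)
  set.seed(8)
  sc <- rnorm(2000)
  lab <- rep(0:1, 1000)
  expect_equal(roc_curve(sc, lab)$auc, 0.5, tolerance = 0.05)
  r <- roc_curve(sc, lab)
  expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]), c(1, 1))
  expect_error(roc_curve(sc, rep(1, 2000)), "both classes")
})

test_that("evaluation reports Youden-point sensitivity and specificity", {
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.2)
  labels <- c(1, 1, 0, 1, 0, 0)
  r <- roc_curve(scores, labels)
  j <- which.max(r$tpr - r$fpr)
  expect_equal(r$auc, oracle_auc(scores, labels))
  expect_gte(r$tpr[j] - r$fpr[j], max(r$tpr - r$fpr) - 1e-12)
})

test_that("LOWESS trend reproduces noiseless linear predictions", {
  set.seed(13)
  n <- 240
  age <- round(runif(n, 20, 75))
  sex <- rep(c("male", "female"), n / 2)
  cohort <- data.frame(
    subject_id = as.character(1:n),
    a = 500 - 2 * age, tpr = 0.2 + 0.004 * age,
    sex = sex, weight = rnorm(n, 75, 8), height = rnorm(n, 172, 6),
    smoking = sample(c("yes", "no"), n, replace = TRUE),
    age = age, label = dichotomize_age(age))
  sp <- split_cohort(cohort, seed = 3)
  tr <- sex_stratified_trend(sp$train, sp$test)
  expect_false(is.null(tr$male))
  expect_false(is.null(tr$female))
  # predictions are exactly linear in age -> smoothed curve == identity line
  expect_equal(tr$male, tr$grid, tolerance = 0.01)
  expect_equal(tr$female, tr$grid, tolerance = 0.01)
})
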