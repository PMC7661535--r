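#' Dichotomize age into the HVA classes
#'
#' Young subjects (18-38 years) are coded 1 (a proxy for healthy vascular
#' aging), old subjects (60-79 years) are coded 0; everyone else (including
#' ages below 18) is excluded (`NA`).
#'
#' @param age numeric vector of ages in years.
#' @return integer vector in {1, 0, NA}.
#' @export
dichotomize_age <- function(age) {
  out <- rep(NA_integer_, length(age))
  out[!is.na(age) & age >= 18 & age <= 38] <- 1L
  out[!is.na(age) & age >= 60 & age <= 79] <- 0L
  out
}

#' Age-stratified train/test split
#'
#' Subjects are stratified by age decile and the test set is drawn within
#' each stratum, with largest-remainder allocation so the overall test size
#' is exactly `round(test_fraction * n)`. Empty or degenerate strata fall
#' back to a global random split with a warning.
#'
#' @param cohort a cohort data.frame with an `age` column.
#' @param test_fraction fraction held out for testing (default 0.25).
#' @param seed integer seed; the split is reproducible given the seed.
#' @return list `(train, test)` of disjoint row subsets.
#' @export
split_cohort <- function(cohort, test_fraction = 0.25, seed = 1L) {
  n <- nrow(cohort)
  if (n < 8L) stop("cohort too small to split")
  set.seed(as.integer(seed))
  n_test <- round(test_fraction * n)
  breaks <- unique(quantile(cohort$age, probs = 0:10 / 10, na.rm = TRUE))
  strata <- if (length(breaks) < 3L) {
    warning("degenerate age strata; falling back to a global random split")
    rep(1L, n)
  } else {
    as.integer(cut(cohort$age, breaks = breaks, include.lowest = TRUE))
  }
  sizes <- table(strata)
  raw_alloc <- n_test * as.numeric(sizes) / n
  alloc <- floor(raw_alloc)
  rem <- n_test - sum(alloc)
  if (rem > 0) {
    order_frac <- order(raw_alloc - alloc, decreasing = TRUE)
    alloc[order_frac[seq_len(rem)]] <- alloc[order_frac[seq_len(rem)]] + 1L
  }
  test_idx <- integer(0)
  for (s in seq_along(sizes)) {
    rows <- which(strata == as.integer(names(sizes))[s])
    k <- min(alloc[s], length(rows))
    test_idx <- c(test_idx, sample(rows, k))
  }
  list(train = cohort[-test_idx, , drop = FALSE],
       test = cohort[test_idx, , drop = FALSE])
}

#' Robust standardization by median and interquartile range
#'
#' Column-wise (x - median) / IQR with the parameters learned on the
#' training matrix only and applied unchanged to any other matrix.
#' Zero-IQR columns are flagged, standardized to 0, and reported with a
#' warning.
#'
#' @param train numeric matrix (or data.frame) to learn the parameters on.
#' @param apply_to optional matrix with the same columns to transform with
#'   the train parameters.
#' @return list `(train, applied, center, scale, flagged)`; the parameter
#'   vectors carry attribute `standardized_on = "train"`.
#' @export
robust_standardize <- function(train, apply_to = NULL) {
  train <- as.matrix(train)
  center <- apply(train, 2, median)
  scale <- apply(train, 2, IQR)
  flagged <- which(scale == 0)
  if (length(flagged) > 0L) {
    warning("zero-IQR column(s) standardized to 0: ",
            paste(colnames(train)[flagged], collapse = ", "))
    scale[flagged] <- Inf
  }
  attr(center, "standardized_on") <- "train"
  attr(scale, "standardized_on") <- "train"
  std <- function(m) sweep(sweep(as.matrix(m), 2, center), 2, scale, "/")
  list(train = std(train),
       applied = if (is.null(apply_to)) NULL else std(apply_to),
       center = center, scale = scale, flagged = flagged)
}

#' Repeated ridge-regression feature ranking
#'
#' The feature matrix is robustly standardized, then for each of `n_reps`
#' repetitions 2/3 of the rows are sampled and two ridge regressions are
#' fitted with 10-fold cross-validated penalties: a linear ridge on
#' continuous age and a logistic ridge on the binary HVA label. In each
#' repetition the variables are ranked by decreasing absolute coefficient
#' (rank 1 = largest). Ranks are averaged over the repetitions per model
#' and the final score is the sum of the two averages; lower is more
#' relevant.
#'
#' @param x numeric matrix of predictors (features and covariates).
#' @param age continuous age outcome.
#' @param label binary HVA label (0/1), no missing values.
#' @param n_reps number of repetitions (default 100).
#' @param seed integer seed.
#' @return data.frame of class `ppg_ranking`, sorted by `final_score`
#'   ascending, with columns `variable`, `linear_rank`, `logistic_rank`,
#'   `final_score`. Per-repetition rank matrices are in attributes
#'   `reps_linear` and `reps_logistic`.
#' @export
ridge_rank <- function(x, age, label, n_reps = 100L, seed = 1L) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 2L) stop("need at least 2 variables to rank")
  if (anyNA(label) || length(unique(label)) < 2L)
    stop("both label classes must be present")
  xs <- robust_standardize(x)$train
  n <- nrow(xs)
  lam <- 10^seq(3, -3, length.out = 30)
  rank_lin <- matrix(NA_real_, n_reps, p, dimnames = list(NULL, colnames(x)))
  rank_log <- rank_lin
  set.seed(as.integer(seed))
  for (r in seq_len(n_reps)) {
    idx <- sample(n, floor(2 * n / 3))
    foldid <- sample(rep(1:10, length.out = length(idx)))
    rank_lin[r, ] <- .cv_ridge_ranks(xs[idx, ], age[idx], "gaussian", lam, foldid)
    rank_log[r, ] <- .cv_ridge_ranks(xs[idx, ], label[idx], "binomial", lam, foldid)
  }
  out <- data.frame(variable = colnames(x),
                    linear_rank = colMeans(rank_lin),
                    logistic_rank = colMeans(rank_log))
  out$final_score <- out$linear_rank + out$logistic_rank
  out <- out[order(out$final_score), ]
  rownames(out) <- NULL
  attr(out, "reps_linear") <- rank_lin
  attr(out, "reps_logistic") <- rank_log
  class(out) <- c("ppg_ranking", "data.frame")
  out
}

# one cross-validated ridge fit -> variable ranks by |coefficient|;
# a failed fit is retried once with reshuffled folds before erroring
.cv_ridge_ranks <- function(x, y, family, lambda, foldid) {
  fit_once <- function(fid) {
    cv <- glmnet::cv.glmnet(x, y, family = family, alpha = 0,
                            lambda = lambda, foldid = fid,
                            standardize = FALSE)
    as.numeric(coef(cv, s = "lambda.min"))[-1L]
  }
  co <- tryCatch(fit_once(foldid), error = function(e) e)
  if (inherits(co, "error")) {
    warning("ridge fit failed (", conditionMessage(co), "); retrying with reshuffled folds")
    co <- fit_once(sample(foldid))
  }
  rank(-abs(co), ties.method = "first")
}

# ---- RBF least-squares SVM -------------------------------------------------
# No SVM library ships with the runtime, so the margin-based kernel
# classifier is a least-squares SVM (Suykens & Vandewalle): the dual system
# [0 1'; 1 K + I/C] [b; alpha] = [0; y] with an RBF kernel, solved exactly.

.rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

.lssvm_fit <- function(x, y01, C, gamma) {
  yy <- ifelse(y01 == 1, 1, -1)
  n <- nrow(x)
  K <- .rbf_kernel(x, x, gamma)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / C))
  sol <- solve(A, c(0, yy))
  list(x = x, alpha = sol[-1L], b = sol[1L], C = C, gamma = gamma)
}

.lssvm_score <- function(model, newx) {
  drop(.rbf_kernel(as.matrix(newx), model$x, model$gamma) %*% model$alpha) + model$b
}

#' Fit the HVA kernel classifier
#'
#' A margin-based RBF-kernel classifier (least-squares SVM) whose
#' regularization C and kernel width gamma are grid-tuned by 3-fold
#' cross-validated AUC on the training set: C in {0.1, 1, 10, 100}, gamma
#' in scale-based gamma0 * {0.1, 1, 10} where gamma0 = 1/(p * mean column
#' variance). Predictors should already be standardized.
#'
#' @param x numeric predictor matrix (train).
#' @param label binary 0/1 outcome, both classes present.
#' @param seed integer seed for the CV folds.
#' @return object of class `ppg_classifier`; use [predict.ppg_classifier]
#'   for continuous decision scores.
#' @export
fit_classifier <- function(x, label, seed = 1L) {
  x <- as.matrix(x)
  if (length(unique(label)) < 2L) stop("training labels contain a single class")
  p <- ncol(x)
  g0 <- 1 / (p * max(mean(apply(x, 2, var)), .Machine$double.eps))
  grid <- expand.grid(C = c(0.1, 1, 10, 100), gamma = g0 * c(0.1, 1, 10))
  set.seed(as.integer(seed))
  folds <- sample(rep(1:3, length.out = nrow(x)))
  cv_auc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    aucs <- vapply(1:3, function(f) {
      tr <- folds != f
      if (length(unique(label[!tr])) < 2L) return(NA_real_)
      m <- .lssvm_fit(x[tr, , drop = FALSE], label[tr], grid$C[g], grid$gamma[g])
      roc_curve(.lssvm_score(m, x[!tr, , drop = FALSE]), label[!tr])$auc
    }, numeric(1))
    cv_auc[g] <- mean(aucs, na.rm = TRUE)
  }
  best <- which.max(cv_auc)     # ties: first grid point (smallest C, gamma)
  model <- .lssvm_fit(x, label, grid$C[best], grid$gamma[best])
  model$cv <- cbind(grid, auc = cv_auc)
  class(model) <- "ppg_classifier"
  model
}

#' Decision scores of the HVA classifier
#' @param object a `ppg_classifier`.
#' @param newdata predictor matrix on the training standardization scale.
#' @param ... unused.
#' @return numeric decision scores (higher = more likely class 1).
#' @export
predict.ppg_classifier <- function(object, newdata, ...) {
  .lssvm_score(object, newdata)
}

#' ROC curve and trapezoidal AUC from decision scores
#'
#' The curve steps through the unique score values from the most to the
#' least confident, is anchored at (0,0) and (1,1), and the AUC is its
#' trapezoidal area (equal to the concordant-pair probability).
#'
#' @param scores continuous decision scores.
#' @param labels binary 0/1 labels, both classes present.
#' @return list `(fpr, tpr, thresholds, auc)`.
#' @export
roc_curve <- function(scores, labels) {
  if (length(unique(labels)) < 2L) stop("both classes required for a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # group tied scores so the curve moves diagonally through ties
  grp <- cumsum(!duplicated(s))
  tp <- tapply(y == 1, grp, sum)
  fp <- tapply(y == 0, grp, sum)
  tpr <- c(0, cumsum(tp) / sum(labels == 1))
  fpr <- c(0, cumsum(fp) / sum(labels == 0))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(fpr = as.numeric(fpr), tpr = as.numeric(tpr),
       thresholds = c(Inf, s[!duplicated(s)]), auc = auc)
}

#' Evaluate a classifier on a test set
#'
#' Computes the ROC curve and AUC of the decision scores and reports
#' sensitivity and specificity at the Youden-optimal point of the test ROC
#' (the threshold maximizing sensitivity + specificity - 1).
#'
#' @param classifier a `ppg_classifier`.
#' @param x test predictor matrix (already on the train standardization
#'   scale).
#' @param labels binary 0/1 test labels, both classes present.
#' @param name model name carried into the report.
#' @return list of class `ppg_eval`: `model`, `roc`, `auc`, `sensitivity`,
#'   `specificity`, `n_test`.
#' @export
evaluate_classifier <- function(classifier, x, labels, name = "model") {
  if (length(unique(labels)) < 2L) stop("test set must contain both classes")
  scores <- predict(classifier, x)
  roc <- roc_curve(scores, labels)
  j <- which.max(roc$tpr - roc$fpr)
  out <- list(model = name, roc = roc, auc = roc$auc,
              sensitivity = roc$tpr[j], specificity = 1 - roc$fpr[j],
              n_test = length(labels))
  class(out) <- "ppg_eval"
  out
}

#' @export
print.ppg_eval <- function(x, ...) {
  cat(sprintf("<ppg_eval> %s: AUC=%.3f  sens=%.3f  spec=%.3f  (n=%d)\n",
              x$model, x$auc, x$sensitivity, x$specificity, x$n_test))
  invisible(x)
}

# numeric design matrix for a cohort subset of columns
# (sex: female=0/male=1; smoking: no=0/yes=1)
.design_matrix <- function(cohort, cols) {
  m <- cohort[, cols, drop = FALSE]
  if ("sex" %in% cols) m$sex <- as.numeric(m$sex == "male")
  if ("smoking" %in% cols) m$smoking <- as.numeric(m$smoking == "yes")
  as.matrix(m)
}

.covariate_cols <- c("sex", "weight", "height", "smoking")

#' Compare the competing HVA models on one split
#'
#' Fits and evaluates, on the identical train/test split restricted to
#' labelled (young/old) subjects: (i) the four covariates; (ii) the two
#' best PPG features `a` and `tpr`; (iii) covariates plus those two
#' features; (v) covariates plus all 38 PPG features. Each model is
#' robustly standardized on its training columns and classified with
#' [fit_classifier].
#'
#' @param train,test cohort data.frames from [split_cohort].
#' @param seed integer seed (CV folds).
#' @param top_features the two headline PPG features (default `a`, `tpr`).
#' @return named list of `ppg_eval` reports: `i`, `ii`, `iii`, `v`.
#' @export
compare_models <- function(train, test, seed = 1L,
                           top_features = c("a", "tpr")) {
  train <- train[!is.na(train$label), , drop = FALSE]
  test <- test[!is.na(test$label), , drop = FALSE]
  specs <- list(
    i = .covariate_cols,
    ii = top_features,
    iii = c(.covariate_cols, top_features),
    v = c(.covariate_cols, ppg_feature_names())
  )
  out <- lapply(names(specs), function(nm) {
    cols <- specs[[nm]]
    std <- robust_standardize(.design_matrix(train, cols),
                              .design_matrix(test, cols))
    cl <- fit_classifier(std$train, train$label, seed = seed)
    evaluate_classifier(cl, std$applied, test$label, name = nm)
  })
  stats::setNames(out, names(specs))
}

#' Sex-stratified predicted-age trend
#'
#' Fits the linear model age ~ a + tpr + weight + height + smoking on the
#' training set (all ages, not only the labelled bands), predicts age on
#' the test set, and smooths predicted age against true age separately per
#' sex with LOWESS. Both curves are returned on a common true-age grid
#' spanning the overlap of the two sexes' age ranges.
#'
#' The sex dummy itself is excluded from the regression: it is the
#' stratification variable, and with it in the model least squares forces
#' the per-sex mean residual to zero, which would make the two curves
#' coincide by construction and hide exactly the sex difference the
#' analysis is after.
#'
#' @param train,test cohort data.frames.
#' @param grid_points number of grid points (default 25).
#' @param f LOWESS smoother span (default 2/3).
#' @return list with `grid` (true ages), `male`, `female` (smoothed
#'   predicted ages; `NULL` with a warning if a sex is absent), and `fit`
#'   (the linear model).
#' @export
sex_stratified_trend <- function(train, test, grid_points = 25L, f = 2/3) {
  cols <- c("a", "tpr", setdiff(.covariate_cols, "sex"))
  df_tr <- data.frame(.design_matrix(train, cols), age = train$age)
  fit <- lm(age ~ ., data = df_tr)
  df_te <- data.frame(.design_matrix(test, cols))
  pred <- predict(fit, newdata = df_te)
  out <- list(grid = NULL, male = NULL, female = NULL, fit = fit)
  ranges <- list()
  for (sx in c("male", "female")) {
    if (sum(test$sex == sx) < 5L) {
      warning("sex '", sx, "' absent or too sparse in the test set; curve omitted")
      next
    }
    # inner quantiles: LOWESS is unreliable where a sex has little support
    ranges[[sx]] <- quantile(test$age[test$sex == sx], c(0.05, 0.95))
  }
  if (length(ranges) == 0L) return(out)
  lo <- max(vapply(ranges, `[`, numeric(1), 1L))
  hi <- min(vapply(ranges, `[`, numeric(1), 2L))
  out$grid <- seq(lo, hi, length.out = grid_points)
  for (sx in names(ranges)) {
    sel <- test$sex == sx
    sm <- lowess(test$age[sel], pred[sel], f = f)
    out[[sx]] <- approx(sm$x, sm$y, xout = out$grid, rule = 2)$y
  }
  out
}
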