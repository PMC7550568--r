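#' Pearson association between a feature and age
#'
#' Standard Pearson correlation with a two-sided p-value from the t
#' distribution, via [stats::cor.test()].  Used to assess a morphometric
#' feature (e.g. cortical fractal dimension) as a marker of development
#' and aging.
#'
#' @param x feature values.
#' @param y ages (same length, `n >= 3`).
#' @return List with `r` and `p_value`.
#' @export
age_association <- function(x, y) {
  if (length(x) != length(y)) stop("LengthMismatch: x and y differ in length")
  if (length(x) < 3) stop("InvalidParams: need n >= 3")
  if (anyNA(x) || anyNA(y)) stop("MissingValues: NA in input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("ConstantInput: x and y must be non-constant")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

# One k-fold CV pass on a fixed design.  X: numeric feature matrix, y: ages.
# Rows are shuffled (caller seeds the RNG), split into contiguous folds with
# any remainder spread one per fold.  Per fold, features are standardized by
# the training-fold mean/sd only — the test set is never touched during
# learning — an OLS model with intercept is fitted on the training fold and
# the pooled absolute errors over all test predictions give the MAE.
cv_mae_once <- function(X, y, n_folds) {
  n <- length(y)
  ord <- sample.int(n)
  base <- n %/% n_folds
  sizes <- rep(base, n_folds)
  extra <- n %% n_folds
  if (extra > 0) sizes[seq_len(extra)] <- base + 1L
  stops <- cumsum(sizes)
  starts <- c(1L, stops[-n_folds] + 1L)

  abs_err <- numeric(n)
  pos <- 0L
  for (f in seq_len(n_folds)) {
    te <- ord[starts[f]:stops[f]]
    tr <- ord[-(starts[f]:stops[f])]
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0] <- 1  # constant feature in a fold: center only
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sdv, "/")
    cf <- stats::lm.fit(cbind(1, Xtr), y[tr])$coefficients
    cf[is.na(cf)] <- 0
    pred <- drop(cbind(1, Xte) %*% cf)
    abs_err[pos + seq_along(te)] <- abs(pred - y[te])
    pos <- pos + length(te)
  }
  mean(abs_err)
}

#' Individual age prediction by repeated cross-validated regression
#'
#' Evaluates how well a morphometric feature (plus nuisance covariates,
#' by default eTIV and sex) predicts individual age with an ordinary
#' least-squares linear model in a k-fold cross-validation loop.  Because
#' the score depends on how subjects fall into folds, the CV is repeated
#' `n_reps` times with fresh random splits and the per-repetition MAEs
#' (mean absolute error between predicted and actual age, pooled over all
#' test predictions of the repetition) are averaged.  Standardization of
#' each feature uses the training fold only, so no information leaks from
#' the test set.
#'
#' @param cohort a cohort `data.frame` (see [read_cohort()] /
#'   [simulate_cohort()]).
#' @param feature name of the feature column.
#' @param covariates further design columns (default `c("eTIV", "sex")`;
#'   use `character(0)` for the feature alone).
#' @param target name of the age column.
#' @param n_folds folds per CV (default 5).
#' @param n_reps CV repetitions (default 1000).
#' @param seed RNG seed; the full MAE vector is reproducible from it.
#' @return An object of class `age_cv`: `mean_mae`, `mae_per_repetition`,
#'   plus the configuration and data needed by [permutation_pvalue()].
#' @examples
#' co <- simulate_cohort(n = 40, seed = 7)
#' fit <- age_cv(co, "FD", n_reps = 10, seed = 1)
#' fit$mean_mae
#' @export
age_cv <- function(cohort, feature, covariates = c("eTIV", "sex"),
                   target = "age", n_folds = 5, n_reps = 1000, seed = 1) {
  cols <- c(feature, covariates)
  cohort <- validate_cohort(cohort, c("subject_id", target, cols))
  if (n_folds < 2) stop("InvalidParams: n_folds must be >= 2")
  if (n_reps < 1) stop("InvalidParams: n_reps must be >= 1")
  n <- nrow(cohort)
  if (n < 2 * n_folds)
    stop("TooFewSubjects: need at least ", 2 * n_folds, " rows")
  X <- as.matrix(cohort[, cols, drop = FALSE])
  y <- cohort[[target]]
  maes <- with_seed(substream_seed(seed, 0), {
    vapply(seq_len(n_reps), function(r) cv_mae_once(X, y, n_folds),
           numeric(1))
  })
  structure(
    list(mean_mae = mean(maes),
         mae_per_repetition = maes,
         n_folds = n_folds, n_reps = n_reps, seed = seed,
         feature = feature, covariates = covariates, target = target,
         X = X, y = y, n = n),
    class = "age_cv"
  )
}

#' @export
print.age_cv <- function(x, ...) {
  cat("Repeated cross-validated age prediction (OLS)\n")
  cat(sprintf("  features: %s\n",
              paste(c(x$feature, x$covariates), collapse = ", ")))
  cat(sprintf("  %d-fold CV x %d repetitions, n = %d subjects\n",
              x$n_folds, x$n_reps, x$n))
  cat(sprintf("  mean MAE = %.4f years\n", x$mean_mae))
  if (!is.null(x$p_value))
    cat(sprintf("  permutation p-value = %.4g (%d permutations)\n",
                x$p_value, length(x$null_maes)))
  invisible(x)
}

#' @export
summary.age_cv <- function(object, ...) {
  data.frame(
    feature = object$feature, n = object$n, n_folds = object$n_folds,
    n_reps = object$n_reps, mean_mae = object$mean_mae,
    sd_mae = stats::sd(object$mae_per_repetition),
    p_value = if (is.null(object$p_value)) NA_real_ else object$p_value
  )
}

#' Permutation significance of an age-prediction score
#'
#' Builds the null distribution of the CV MAE by dissociating features
#' from ages: for each permutation the age labels are randomly permuted
#' and the cross-validated MAE recomputed (by default one CV pass per
#' permuted dataset; `perm_reps` averages several).  The p-value uses the
#' add-one estimator `(1 + #{null <= observed}) / (1 + n_perm)`, so it is
#' never exactly zero — with 5000 permutations the smallest attainable
#' value is 1/5001 < 0.0002.
#'
#' @param object an [age_cv()] fit.
#' @param n_perm number of label permutations (default 5000).
#' @param perm_reps CV repetitions per permuted dataset (default 1).
#' @param seed RNG seed for the permutations.
#' @return The `age_cv` object with `p_value` and `null_maes` added.
#' @export
permutation_pvalue <- function(object, n_perm = 5000, perm_reps = 1,
                               seed = 1) {
  stopifnot(inherits(object, "age_cv"))
  if (n_perm < 1) stop("InvalidParams: n_perm must be >= 1")
  X <- object$X
  y <- object$y
  nf <- object$n_folds
  null_maes <- with_seed(substream_seed(seed, 1), {
    vapply(seq_len(n_perm), function(p) {
      yp <- y[sample.int(length(y))]
      mean(vapply(seq_len(perm_reps),
                  function(r) cv_mae_once(X, yp, nf), numeric(1)))
    }, numeric(1))
  })
  object$null_maes <- null_maes
  object$p_value <- (1 + sum(null_maes <= object$mean_mae)) / (1 + n_perm)
  object
}
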