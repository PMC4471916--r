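#' Standardize a predictor table
#'
#' Expands factor/character columns (e.g. study year) into reference-coded
#' indicator columns, then centres every column to mean 0 and scales to
#' sample standard deviation 1 (n - 1 denominator). The returned scaling
#' record allows the identical transformation to be applied to new rows
#' (essential inside leave-one-out rounds to avoid leakage) and supports
#' back-transformation of coefficients.
#'
#' @param x data frame (or matrix) of predictors.
#' @return List of class \code{standardized_features}: \code{x} (numeric
#'   matrix), \code{center}, \code{scale} (named vectors).
#' @export
standardize_features <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (nrow(x) < 2L) stop_input("standardization requires n >= 2 rows")
  cols <- list()
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- v
    } else {
      f <- factor(v)
      if (nlevels(f) < 2L) {
        stop_input(sprintf("predictor '%s' has a single level (zero variance)", nm))
      }
      for (lev in levels(f)[-1L]) {
        cols[[paste0(nm, lev)]] <- as.numeric(f == lev)
      }
    }
  }
  m <- do.call(cbind, cols)
  colnames(m) <- names(cols)
  ctr <- colMeans(m)
  scl <- apply(m, 2L, stats::sd)
  zero <- scl == 0 | !is.finite(scl)
  if (any(zero)) {
    stop_input(sprintf("zero-variance predictor(s): %s",
                       paste(colnames(m)[zero], collapse = ", ")))
  }
  z <- sweep(sweep(m, 2L, ctr), 2L, scl, "/")
  structure(list(x = z, center = ctr, scale = scl),
            class = "standardized_features")
}

#' Apply a stored standardization to new data
#'
#' @param record a \code{standardized_features} scaling record.
#' @param newdata data frame with the same original columns.
#' @return Numeric matrix on the standardized scale.
#' @export
apply_standardization <- function(record, newdata) {
  stopifnot(inherits(record, "standardized_features"))
  newdata <- as.data.frame(newdata, stringsAsFactors = FALSE)
  nms <- names(record$center)
  m <- matrix(0, nrow(newdata), length(nms), dimnames = list(NULL, nms))
  for (nm in nms) {
    if (nm %in% names(newdata)) {
      m[, nm] <- as.numeric(newdata[[nm]])
    } else {
      # indicator column "yearLEVEL" derived from a factor column
      src <- NULL
      for (cand in names(newdata)) {
        if (startsWith(nm, cand) && !is.numeric(newdata[[cand]])) src <- cand
      }
      if (is.null(src)) stop_input(sprintf("newdata lacks predictor '%s'", nm))
      lev <- substring(nm, nchar(src) + 1L)
      m[, nm] <- as.numeric(as.character(newdata[[src]]) == lev)
    }
  }
  sweep(sweep(m, 2L, record$center), 2L, record$scale, "/")
}

soft_threshold <- function(z, lambda) sign(z) * pmax(abs(z) - lambda, 0)

#' L1-penalised least squares path by cyclic coordinate descent
#'
#' Solves, for each penalty lambda on a decreasing grid,
#' \deqn{min_{b0, b} 1/(2n) ||y - b0 - X b||^2 + lambda ||b||_1}
#' by cyclic soft-threshold updates with warm starts, iterating until the
#' largest coefficient change in a sweep falls below \code{tol}. With a
#' centred response the intercept is mean(y) throughout. The default grid
#' runs from \code{lambda_max} (the smallest lambda with an all-zero
#' solution, \code{max |x_j' (y - mean(y))| / n}) down 100 log-spaced steps.
#'
#' Coefficients shrunk to zero are exactly zero: the update is a hard
#' soft-threshold, not a numerical approximation.
#'
#' @param x numeric predictor matrix (typically standardized).
#' @param y numeric response.
#' @param lambda optional penalty grid (decreasing); computed if NULL.
#' @param nlambda grid length when computed (default 100).
#' @param lambda_min_ratio smallest grid value as a fraction of lambda_max.
#' @param tol convergence tolerance on the max coefficient change (1e-7).
#' @param max_iter maximum sweeps per lambda.
#' @return List of class \code{lasso_path}: \code{lambda}, \code{beta}
#'   (p x nlambda matrix), \code{intercept}, \code{lambda_max}.
#' @export
lasso_path <- function(x, y, lambda = NULL, nlambda = 100L,
                       lambda_min_ratio = 1e-3, tol = 1e-7, max_iter = 1e5L) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  stopifnot(length(y) == n, n >= 2L)
  yc <- y - mean(y)
  d <- colSums(x^2) / n
  lambda_max <- max(abs(crossprod(x, yc))) / n
  if (is.null(lambda)) {
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = nlambda))
  } else {
    lambda <- sort(lambda, decreasing = TRUE)
  }
  beta <- tryCatch(
    cpp_lasso_path(x, yc, lambda, tol, as.integer(max_iter)),
    error = function(e) abort_ns(conditionMessage(e), "nightsong_convergence_error"))
  dimnames(beta) <- list(colnames(x), NULL)
  structure(list(lambda = lambda, beta = beta,
                 intercept = rep(mean(y), length(lambda)),
                 lambda_max = lambda_max),
            class = "lasso_path")
}

#' Cross-validated penalty selection for the LASSO path
#'
#' K-fold cross-validation of mean squared prediction error over the lambda
#' grid of the full-data path. Returns both the MSE-minimising lambda and
#' the largest lambda within one standard error of the minimum (the
#' parsimonious convention).
#'
#' @param x,y as in \code{\link{lasso_path}}.
#' @param nfolds number of folds (default 5).
#' @param foldid optional integer fold assignment (length n); drawn at
#'   random from the current RNG state when NULL.
#' @param ... passed to \code{\link{lasso_path}}.
#' @return List of class \code{cv_lasso}: \code{lambda}, \code{cvm},
#'   \code{cvsd}, \code{lambda_min}, \code{lambda_1se}, \code{path}.
#' @export
cv_lasso <- function(x, y, nfolds = 5L, foldid = NULL, ...) {
  x <- as.matrix(x)
  n <- nrow(x)
  full <- lasso_path(x, y, ...)
  lambda <- full$lambda
  if (is.null(foldid)) foldid <- sample(rep(seq_len(nfolds), length.out = n))
  errs <- matrix(NA_real_, n, length(lambda))
  for (f in sort(unique(foldid))) {
    test <- foldid == f
    fit <- lasso_path(x[!test, , drop = FALSE], y[!test], lambda = lambda)
    pred <- sweep(x[test, , drop = FALSE] %*% fit$beta, 2L, fit$intercept, "+")
    errs[test, ] <- (y[test] - pred)^2
  }
  cvm <- colMeans(errs)
  cvsd <- apply(errs, 2L, stats::sd) / sqrt(n)
  i_min <- which.min(cvm)
  ok <- cvm <= cvm[i_min] + cvsd[i_min]
  i_1se <- which(ok)[1L]  # grid is decreasing in lambda
  structure(list(lambda = lambda, cvm = cvm, cvsd = cvsd,
                 lambda_min = lambda[i_min], lambda_1se = lambda[i_1se],
                 path = full),
            class = "cv_lasso")
}

#' LASSO feature selection
#'
#' Fits the penalty path, chooses lambda by k-fold cross-validation and
#' returns the predictors with non-zero coefficients at the chosen lambda,
#' ordered by decreasing absolute coefficient. The default rule is the
#' "within one standard error of the minimum" convention, which favours
#' parsimonious selected sets; \code{rule = "min"} gives the MSE-minimising
#' lambda instead.
#'
#' @param x standardized predictor matrix.
#' @param y response vector.
#' @param rule \code{"1se"} (default) or \code{"min"}.
#' @param nfolds,foldid passed to \code{\link{cv_lasso}}.
#' @param ... passed to \code{\link{lasso_path}}.
#' @return List of class \code{lasso_selection}: \code{selected} (names,
#'   by decreasing |coefficient|), \code{coefficients} (named, non-zero
#'   only), \code{lambda}, \code{cv}.
#' @export
select_features <- function(x, y, rule = c("1se", "min"), nfolds = 5L,
                            foldid = NULL, ...) {
  rule <- match.arg(rule)
  cv <- cv_lasso(x, y, nfolds = nfolds, foldid = foldid, ...)
  lam <- if (rule == "1se") cv$lambda_1se else cv$lambda_min
  k <- which.min(abs(cv$lambda - lam))
  coefs <- cv$path$beta[, k]
  nz <- coefs[coefs != 0]
  if (length(nz) == 0L) {
    warning("LASSO selected no predictors at the chosen lambda")
  }
  nz <- nz[order(abs(nz), decreasing = TRUE)]
  structure(list(selected = names(nz), coefficients = nz, lambda = lam,
                 rule = rule, cv = cv),
            class = "lasso_selection")
}

#' @export
print.lasso_selection <- function(x, ...) {
  cat(sprintf("LASSO selection (rule = %s, lambda = %.4g): %d predictor(s)\n",
              x$rule, x$lambda, length(x$selected)))
  if (length(x$selected)) {
    print(round(x$coefficients, 4))
  }
  invisible(x)
}
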