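#' Leave-one-out SVR prediction of feeding rates
#'
#' For each of the n males, trains a support-vector regression on the other
#' n - 1 rows and predicts the held-out male's response. Standardization is
#' refit inside every round on the training rows only, so no information
#' about the held-out male leaks into his prediction. Optionally the LASSO
#' feature selection itself can also be re-run inside each round
#' (\code{reselect = TRUE}); the default follows the study design in which
#' features are selected once on the full table and leave-one-out prediction
#' runs on the reduced predictor set.
#'
#' @param features data frame of predictors, one row per male (numeric
#'   columns; factors are expanded by the standardizer).
#' @param response numeric response vector (median feeding rate, visits/h).
#' @param predictors character vector naming the predictor columns to use
#'   (ignored when \code{reselect = TRUE}).
#' @param male_id optional identifiers for the output table.
#' @param reselect re-run \code{\link{select_features}} inside each round on
#'   the n - 1 training rows; selected song measures are then joined with
#'   \code{always_keep}.
#' @param always_keep predictors forced into the model when
#'   \code{reselect = TRUE} (default \code{"n_hatchlings"} if present).
#' @param kernel,C,gamma,epsilon SVR hyperparameters
#'   (see \code{\link{svr_fit}}).
#' @param nfolds,rule cross-validation settings when \code{reselect = TRUE}.
#' @return Data frame of class \code{loo_prediction}: \code{male_id},
#'   \code{observed}, \code{predicted}; hyperparameters stored as attributes.
#' @export
loo_predict <- function(features, response, predictors = NULL, male_id = NULL,
                        reselect = FALSE, always_keep = NULL,
                        kernel = "rbf", C = 1, gamma = NULL, epsilon = 0.1,
                        nfolds = 5L, rule = "1se") {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  n <- nrow(features)
  stopifnot(length(response) == n)
  if (n < 3L) stop_input("leave-one-out prediction requires n >= 3")
  if (is.null(male_id)) male_id <- as.character(seq_len(n))
  if (!reselect) {
    if (is.null(predictors)) stop_input("predictors must be given unless reselect = TRUE")
    missing <- setdiff(predictors, names(features))
    if (length(missing)) {
      stop_input(sprintf("unknown predictor(s): %s", paste(missing, collapse = ", ")))
    }
  }
  if (is.null(always_keep) && "n_hatchlings" %in% names(features)) {
    always_keep <- "n_hatchlings"
  }
  predicted <- numeric(n)
  for (i in seq_len(n)) {
    train <- features[-i, , drop = FALSE]
    ytr <- response[-i]
    use <- predictors
    if (reselect) {
      std_all <- standardize_features(train)
      sel <- suppressWarnings(
        select_features(std_all$x, ytr, rule = rule, nfolds = nfolds))
      use <- union(intersect(sel$selected, names(features)), always_keep)
      if (length(use) == 0L) use <- always_keep %||% names(features)[1L]
    }
    std <- standardize_features(train[, use, drop = FALSE])
    fit <- svr_fit(std$x, ytr, kernel = kernel, C = C, gamma = gamma,
                   epsilon = epsilon)
    xt <- apply_standardization(std, features[i, use, drop = FALSE])
    predicted[i] <- predict(fit, xt)
  }
  out <- data.frame(male_id = male_id, observed = response,
                    predicted = predicted, stringsAsFactors = FALSE)
  attr(out, "hyperparameters") <- list(kernel = kernel, C = C, gamma = gamma,
                                       epsilon = epsilon, reselect = reselect)
  class(out) <- c("loo_prediction", "data.frame")
  out
}

#' Spearman rank correlation with tie correction
#'
#' Pearson correlation of midranks (the definitional tie-corrected form).
#' The two-tailed p-value uses the t approximation with n - 2 degrees of
#' freedom, adequate for n around 20; for n <= 8 an exact permutation
#' p-value is available.
#'
#' @param predicted,observed equal-length numeric vectors, n >= 3.
#' @param method \code{"t"} (default) or \code{"permutation"} (n <= 8).
#' @return List of class \code{evaluation_result}: \code{rho},
#'   \code{p_value}, \code{n}, \code{method}.
#' @export
spearman_eval <- function(predicted, observed, method = c("t", "permutation")) {
  method <- match.arg(method)
  n <- length(predicted)
  stopifnot(length(observed) == n)
  if (n < 3L) stop_input("Spearman evaluation requires n >= 3")
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    abort_ns("constant vector: Spearman correlation undefined",
             "nightsong_statistics_error")
  }
  rp <- rank(predicted, ties.method = "average")
  ro <- rank(observed, ties.method = "average")
  rho <- stats::cor(rp, ro)
  if (method == "t") {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  } else {
    if (n > 8L) stop_input("exact permutation p only enumerated for n <= 8")
    perms <- permutations_all(n)
    null_rho <- apply(perms, 1L, function(ix) stats::cor(rp[ix], ro))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
  }
  structure(list(rho = rho, p_value = min(p, 1), n = n, method = method),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: rho = %.3f, p = %.4g (n = %d, %s)\n",
              x$rho, x$p_value, x$n, x$method))
  invisible(x)
}

# All permutations of 1..n as rows (n <= 8).
permutations_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_all(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- nrow(sub)
    block <- cbind(rep(k, rows), sub + (sub >= k))
    out[r + seq_len(rows), ] <- block
    r <- r + rows
  }
  out
}
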