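#' @keywords internal
kernel_matrix <- function(x1, x2, kernel, gamma) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  if (kernel == "linear") return(x1 %*% t(x2))
  # RBF: exp(-gamma * ||a - b||^2)
  d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * x1 %*% t(x2)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

# Exact minimiser of the pairwise dual sub-problem: move beta_i by delta and
# beta_j by -delta (preserving sum(beta) = 0). The objective along delta is
# piecewise quadratic with kinks where beta_i + delta or beta_j - delta cross
# zero; the minimum lies at a segment stationary point, a kink, or a box
# endpoint, all of which are evaluated exactly.
svr_pair_delta <- function(bi, bj, gi, gj, eta, C, eps) {
  L <- max(-C - bi, bj - C)
  H <- min(C - bi, bj + C)
  if (H - L <= 1e-14) return(0)
  cands <- c(L, H)
  if (-bi > L && -bi < H) cands <- c(cands, -bi)
  if (bj > L && bj < H) cands <- c(cands, bj)
  if (eta > 1e-14) {
    for (si in c(-1, 1)) for (sj in c(-1, 1)) {
      d <- -(gi - gj + eps * (si - sj)) / eta
      if (d > L && d < H) cands <- c(cands, d)
    }
  }
  dW <- cands * (gi - gj) + 0.5 * eta * cands^2 +
    eps * (abs(bi + cands) - abs(bi) + abs(bj - cands) - abs(bj))
  best <- which.min(dW)
  if (dW[best] < -1e-12) cands[best] else 0
}

#' Fit epsilon-insensitive support-vector regression
#'
#' Solves the standard epsilon-SVR dual
#' \deqn{min_beta 1/2 beta' K beta - y' beta + epsilon ||beta||_1}
#' subject to \eqn{sum(beta) = 0} and \eqn{|beta_i| <= C}, by exact pairwise
#' coordinate minimisation (an SMO-style sweep over all index pairs until no
#' pair yields further improvement). The defaults mirror the historical
#' defaults of the classical libsvm-based tooling: RBF kernel,
#' \code{C = 1}, \code{gamma = 1/ncol(x)}, \code{epsilon = 0.1}. The bias is
#' recovered from the KKT conditions (averaged over free support vectors, or
#' the midpoint of the feasible interval when none are free).
#'
#' @param x numeric predictor matrix (rows = training cases), typically
#'   standardized.
#' @param y numeric response.
#' @param kernel \code{"rbf"} (default) or \code{"linear"}.
#' @param C box constraint (cost), default 1.
#' @param gamma RBF width; default \code{1/ncol(x)}.
#' @param epsilon half-width of the insensitive tube, default 0.1.
#' @param max_sweeps safety cap on full pair sweeps.
#' @param tol stop when the best single-pair improvement in a sweep is
#'   below this.
#' @return Object of class \code{svr} (predict method available).
#' @export
svr_fit <- function(x, y, kernel = c("rbf", "linear"), C = 1, gamma = NULL,
                    epsilon = 0.1, max_sweeps = 5000L, tol = 1e-10) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(length(y) == n, n >= 2L)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  K <- kernel_matrix(x, x, kernel, gamma)
  if (any(!is.finite(K))) {
    abort_ns("degenerate kernel matrix (non-finite entries)", "nightsong_solver_error")
  }
  beta <- numeric(n)
  g <- -y  # gradient of the smooth part: K beta - y
  dK <- diag(K)
  for (sweep in seq_len(max_sweeps)) {
    best_impr <- 0
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        eta <- dK[i] + dK[j] - 2 * K[i, j]
        d <- svr_pair_delta(beta[i], beta[j], g[i], g[j], eta, C, epsilon)
        if (d != 0) {
          impr <- -(d * (g[i] - g[j]) + 0.5 * eta * d^2 +
                      epsilon * (abs(beta[i] + d) - abs(beta[i]) +
                                 abs(beta[j] - d) - abs(beta[j])))
          beta[i] <- beta[i] + d
          beta[j] <- beta[j] - d
          g <- g + d * (K[, i] - K[, j])
          best_impr <- max(best_impr, impr)
        }
      }
    }
    if (best_impr < tol) break
  }
  f0 <- g + y  # K beta
  b <- svr_bias(beta, f0, y, C, epsilon)
  structure(list(x = x, beta = beta, b = b, kernel = kernel, C = C,
                 gamma = gamma, epsilon = epsilon),
            class = "svr")
}

svr_bias <- function(beta, f0, y, C, epsilon) {
  slack <- 1e-8 * max(C, 1)
  free <- abs(beta) > slack & abs(beta) < C - slack
  if (any(free)) {
    return(mean(y[free] - f0[free] - epsilon * sign(beta[free])))
  }
  lo <- -Inf
  hi <- Inf
  for (i in seq_along(beta)) {
    if (beta[i] >= C - slack) {
      hi <- min(hi, y[i] - f0[i] - epsilon)
    } else if (beta[i] <= -C + slack) {
      lo <- max(lo, y[i] - f0[i] + epsilon)
    } else {
      lo <- max(lo, y[i] - f0[i] - epsilon)
      hi <- min(hi, y[i] - f0[i] + epsilon)
    }
  }
  if (!is.finite(lo) && !is.finite(hi)) return(0)
  if (!is.finite(lo)) return(hi)
  if (!is.finite(hi)) return(lo)
  (lo + hi) / 2
}

#' @export
predict.svr <- function(object, newdata, ...) {
  Kt <- kernel_matrix(as.matrix(newdata), object$x, object$kernel, object$gamma)
  as.numeric(Kt %*% object$beta + object$b)
}

#' @export
print.svr <- function(x, ...) {
  cat(sprintf("<svr> kernel = %s, C = %g, gamma = %g, epsilon = %g, %d SV\n",
              x$kernel, x$C, x$gamma, x$epsilon, sum(x$beta != 0)))
  invisible(x)
}

# Maximum KKT violation of a fitted svr (internal; used to verify the solver
# contract in tests). 0 at the exact optimum.
svr_kkt_violation <- function(fit, y) {
  f <- predict(fit, fit$x)
  e <- y - f
  beta <- fit$beta
  C <- fit$C
  eps <- fit$epsilon
  slack <- 1e-8 * max(C, 1)
  v <- numeric(length(y))
  for (i in seq_along(y)) {
    if (beta[i] >= C - slack) {
      v[i] <- max(0, eps - e[i])
    } else if (beta[i] <= -C + slack) {
      v[i] <- max(0, e[i] + eps)
    } else if (beta[i] > slack) {
      v[i] <- abs(e[i] - eps)
    } else if (beta[i] < -slack) {
      v[i] <- abs(e[i] + eps)
    } else {
      v[i] <- max(0, abs(e[i]) - eps)
    }
  }
  max(v)
}
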