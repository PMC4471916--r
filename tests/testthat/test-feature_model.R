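test_that("standardization centres, scales, expands factors, and round-trips", {
  s <- standardize_features(data.frame(a = c(2, 4, 6)))
  expect_equal(as.numeric(s$x), c(-1, 0, 1))  # sample SD = 2
  s2 <- standardize_features(as.data.frame(s$x))
  expect_equal(unname(s2$x), unname(s$x), tolerance = 1e-12)

  f <- standardize_features(data.frame(x = 1:6,
                                       year = factor(rep(2010:2012, 2))))
  expect_equal(ncol(f$x), 3L)  # x + two reference-coded indicators
  expect_true(all(c("year2011", "year2012") %in% colnames(f$x)))
  expect_equal(unname(colMeans(f$x)), rep(0, 3), tolerance = 1e-12)

  expect_error(standardize_features(data.frame(a = c(1, 1, 1))),
               class = "nightsong_input_error")
  expect_error(standardize_features(data.frame(a = 1:3, b = "x")),
               class = "nightsong_input_error")

  # apply_standardization reproduces training transform on new rows
  tr <- data.frame(a = rnorm(10), year = factor(rep(c("2010", "2011"), 5)))
  st <- standardize_features(tr)
  expect_equal(unname(apply_standardization(st, tr)), unname(st$x),
               tolerance = 1e-12)
})

test_that("lasso path obeys the all-zero threshold and the orthonormal closed form", {
  set.seed(101)
  n <- 48L; p <- 6L
  X <- qr.Q(qr(matrix(rnorm(n * p), n))) * sqrt(n)  # X'X = n I
  beta_true <- c(2, -1.5, 0.8, 0, 0, 0)
  y <- as.numeric(X %*% beta_true + rnorm(n, 0, 0.3))
  yc <- y - mean(y)
  lam_max <- max(abs(crossprod(X, yc))) / n

  fit <- lasso_path(X, y, lambda = c(lam_max * 2, lam_max, lam_max / 2,
                                     lam_max / 8, lam_max / 64))
  # at lambda >= lambda_max every coefficient is exactly zero
  expect_true(all(fit$beta[, 1] == 0))
  expect_true(all(fit$beta[, 2] == 0))
  # orthonormal design: soft-threshold closed form, coordinate-wise
  z <- as.numeric(crossprod(X, yc)) / n
  for (k in 3:5) {
    closed <- sign(z) * pmax(abs(z) - fit$lambda[k], 0)
    expect_equal(unname(fit$beta[, k]), closed, tolerance = 1e-6)
  }
  expect_equal(fit$lambda_max, lam_max)
})

test_that("lasso at lambda = 0 matches OLS on a well-conditioned n > p problem", {
  set.seed(7)
  n <- 60L; p <- 5L
  X <- scale(matrix(rnorm(n * p), n))
  y <- as.numeric(X %*% c(1, -2, 0.5, 0, 1) + rnorm(n, 0, 0.4))
  fit <- lasso_path(X, y, lambda = c(0.5, 0.05, 0))
  ols <- coef(lm(y ~ X))
  expect_equal(unname(fit$beta[, 3]), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(fit$intercept[3], unname(ols[1]), tolerance = 1e-6)
  # sparsity is non-increasing in lambda on this path
  nz <- colSums(fit$beta != 0)
  expect_true(all(diff(nz) >= 0))
})

test_that("lasso path agrees with glmnet on the identical objective", {
  set.seed(42)
  n <- 30L; p <- 8L
  X <- scale(matrix(rnorm(n * p), n))
  attr(X, "scaled:center") <- NULL; attr(X, "scaled:scale") <- NULL
  y <- as.numeric(X %*% c(1.2, 0, -0.7, 0, 0, 0.4, 0, 0) + rnorm(n, 0, 0.5))
  mine <- lasso_path(X, y, nlambda = 30)
  ref <- glmnet::glmnet(X, y, lambda = mine$lambda, standardize = FALSE,
                        intercept = TRUE, thresh = 1e-14)
  expect_equal(unname(as.matrix(ref$beta)), unname(mine$beta), tolerance = 1e-4)
})

test_that("lasso solutions beat random perturbations of the objective", {
  obj <- function(X, y, b, lam) {
    mean((y - mean(y) - X %*% b)^2) / 2 + lam * sum(abs(b))
  }
  set.seed(17)
  n <- 20L; p <- 11L
  X <- scale(matrix(rnorm(n * p), n))
  y <- rnorm(n)
  fit <- lasso_path(X, y, nlambda = 12)
  for (k in c(3L, 7L, 12L)) {
    b0 <- fit$beta[, k]
    f0 <- obj(X, y, b0, fit$lambda[k])
    worse <- replicate(200, obj(X, y, b0 + rnorm(p, 0, 0.02), fit$lambda[k]))
    expect_true(all(worse >= f0 - 1e-10))
  }
})

test_that("feature selection recovers a single exact predictor", {
  set.seed(5)
  X <- scale(matrix(rnorm(40 * 4), 40))
  colnames(X) <- paste0("V", 1:4)
  y <- 3 * X[, 2]
  set.seed(6)
  sel <- select_features(X, y)
  expect_equal(sel$selected[1], "V2")
  expect_true(abs(sel$coefficients[[1]] - 3) < 0.5)
})

test_that("svr fits constants, linear tubes, and satisfies KKT", {
  # constant response -> constant prediction
  x <- matrix(rnorm(12), 6)
  f <- svr_fit(x, rep(5, 6))
  expect_equal(predict(f, matrix(rnorm(4), 2)), c(5, 5))

  # noiseless linear response, linear kernel, large C: within epsilon
  xg <- matrix(seq(-1, 1, length.out = 15), ncol = 1)
  yg <- 2 * xg[, 1]
  fl <- svr_fit(xg, yg, kernel = "linear", C = 100, epsilon = 0.1)
  expect_true(all(abs(predict(fl, xg) - yg) <= 0.1 + 1e-6))

  # duplicated training point as test input: within epsilon at large C
  set.seed(2)
  xr <- matrix(rnorm(30), 15)
  yr <- rowSums(xr) + rnorm(15, 0, 0.2)
  fr <- svr_fit(xr, yr, C = 100)
  expect_lt(abs(predict(fr, xr[4, , drop = FALSE]) - yr[4]), fr$epsilon + 1e-6)

  # KKT conditions hold to well within 1e-3 across random problems
  set.seed(77)
  for (i in 1:8) {
    xx <- matrix(rnorm(19 * 4), 19)
    yy <- rowSums(xx[, 1:2]) + rnorm(19, 0, 0.5)
    ff <- svr_fit(xx, yy)
    expect_lt(nightsong:::svr_kkt_violation(ff, yy), 1e-3)
  }
})

test_that("spearman evaluation matches the midrank oracle and endpoints", {
  v <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearman_eval(v, v)$rho, 1)
  expect_equal(spearman_eval(v, -v)$rho, -1)

  x <- c(1, 2, 2, 3, 5)   # tie present
  y <- c(2, 1, 4, 4, 5)
  ev <- spearman_eval(x, y)
  expect_equal(ev$rho, midrank_spearman(x, y), tolerance = 1e-12)

  expect_error(spearman_eval(rep(1, 5), v),
               class = "nightsong_statistics_error")

  # exact permutation p at small n is a valid probability and finds perfect rank order
  ep <- spearman_eval(1:6, c(2, 4, 6, 8, 10, 12), method = "permutation")
  expect_equal(ep$rho, 1)
  expect_equal(ep$p_value, 2 / factorial(6))
})

test_that("loo predictions never use the held-out row", {
  set.seed(31)
  feats <- data.frame(a = rnorm(8), b = rnorm(8), n_hatchlings = sample(2:5, 8, TRUE))
  y <- rnorm(8, 10, 2)
  p1 <- loo_predict(feats, y, predictors = c("a", "b", "n_hatchlings"))
  for (i in c(1L, 4L, 8L)) {
    y2 <- y
    y2[i] <- y2[i] + 100  # leak probe
    p2 <- loo_predict(feats, y2, predictors = c("a", "b", "n_hatchlings"))
    expect_equal(p2$predicted[i], p1$predicted[i], tolerance = 1e-10)
  }
  expect_equal(nrow(p1), 8L)
  expect_error(loo_predict(feats[1:2, ], y[1:2], predictors = "a"),
               class = "nightsong_input_error")
})

test_that("planted-link song measures carry positive signs when selected", {
  # parameter-recovery property over the four measures with planted positive
  # quality links (path length + the three category repertoire sizes);
  # other measures (e.g. transitivity) have emergent associations whose sign
  # the generator does not control. Replicate count kept moderate for runtime.
  planted <- c("average_shortest_path", "whistle_repertoire",
               "trill_repertoire", "buzz_repertoire")
  set.seed(909)
  reps <- 40
  ok <- logical(reps)
  for (r in seq_len(reps)) {
    study <- simulate_study(sim_config(), seed = 5000 + r)
    tab <- study_feature_table(study)
    std <- standardize_features(tab[, c(SONG_MEASURE_NAMES, "n_hatchlings", "year")])
    sel <- suppressWarnings(select_features(std$x, tab$median_rate))
    song_coefs <- sel$coefficients[names(sel$coefficients) %in% planted]
    ok[r] <- length(song_coefs) == 0 || all(song_coefs > 0)
  }
  expect_gte(mean(ok), 0.9)
})
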