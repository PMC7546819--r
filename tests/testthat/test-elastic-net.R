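seeded_instance <- function(seed = 7, n = 20, p = 3) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", seq_len(p))))
  y <- 50 + x %*% rnorm(p, 0, 3) + rnorm(n, 0, 2)
  list(x = x, y = as.vector(y))
}

test_that("an overwhelming lasso penalty returns the intercept-only model", {
  d <- seeded_instance(1)
  fit <- fit_elastic_net(d$x, d$y, alpha = 1, lambda = 1e9)
  expect_true(all(fit$coefficients$weight == 0))
  expect_equal(fit$intercept, mean(d$y))
})

test_that("ridge fits match the closed-form normal-equation solution", {
  for (seed in c(7, 8, 9)) {
    d <- seeded_instance(seed)
    lambda <- 3
    fit <- fit_elastic_net(d$x, d$y, alpha = 0, lambda = lambda, tol = 1e-12)
    xc <- scale(d$x, scale = FALSE)
    yc <- d$y - mean(d$y)
    # paper-scale penalty lambda/2 * ||w||^2 => (X'X + lambda/2 I) w = X'y
    w_ref <- solve(crossprod(xc) + diag(lambda / 2, ncol(xc)), crossprod(xc, yc))
    expect_equal(fit$coefficients$weight, as.vector(w_ref), tolerance = 1e-4)
  }
})

test_that("a vanishing penalty recovers ordinary least squares", {
  for (seed in c(7, 21)) {
    d <- seeded_instance(seed)
    fit <- fit_elastic_net(d$x, d$y, alpha = 0.5, lambda = 1e-8, tol = 1e-13)
    xc <- scale(d$x, scale = FALSE)
    yc <- d$y - mean(d$y)
    w_ols <- solve(crossprod(xc), crossprod(xc, yc))
    expect_equal(fit$coefficients$weight, as.vector(w_ols), tolerance = 1e-4)
  }
})

test_that("coefficients agree with an independent elastic-net solver", {
  skip_if_not_installed("glmnet")
  d <- seeded_instance(13, n = 40, p = 8)
  n <- nrow(d$x)
  # glmnet scales the residual term by 1/(2n) and, through its internal
  # response standardization, effectively divides the ridge term by the
  # population sd of y; matching the unscaled objective
  #   RSS + A*||w||_1 + (B/2)*||w||_2^2  (A = lambda*alpha, B = lambda*(1-alpha))
  # therefore requires lam_g = (A + B*sy)/(2n), alpha_g = A/(A + B*sy).
  sy <- sqrt(mean((d$y - mean(d$y))^2))
  for (alpha in c(0.25, 0.5, 1)) {
    lambda <- 2
    fit <- fit_elastic_net(d$x, d$y, alpha = alpha, lambda = lambda, tol = 1e-12)
    a_l1 <- lambda * alpha
    b_l2 <- lambda * (1 - alpha)
    lam_g <- (a_l1 + b_l2 * sy) / (2 * n)
    alpha_g <- a_l1 / (a_l1 + b_l2 * sy)
    # descending path ending at the target: single-lambda glmnet fits are
    # not converged tightly enough for a solver-vs-solver comparison
    g <- glmnet::glmnet(d$x, d$y, alpha = alpha_g, lambda = lam_g * c(64, 16, 4, 1),
                        standardize = FALSE, thresh = 1e-16, maxit = 1e7)
    expect_equal(fit$coefficients$weight,
                 as.vector(stats::coef(g, s = lam_g)[-1]), tolerance = 1e-4)
    expect_equal(fit$intercept, as.numeric(stats::coef(g, s = lam_g)[1]),
                 tolerance = 1e-4)
  }
})

test_that("the returned solution is objective-optimal against probes", {
  d <- seeded_instance(17, n = 30, p = 5)
  alpha <- 0.4; lambda <- 5
  fit <- fit_elastic_net(d$x, d$y, alpha = alpha, lambda = lambda, tol = 1e-10)
  w <- fit$coefficients$weight
  obj <- function(int, wt) txclock:::enet_objective(d$x, d$y, int, wt, alpha, lambda)
  f_star <- obj(fit$intercept, w)
  expect_lte(f_star, obj(mean(d$y), rep(0, 5)) + 1e-8)
  set.seed(99)
  for (i in 1:100) {
    expect_lte(f_star, obj(fit$intercept + rnorm(1, 0, 0.05),
                           w + rnorm(5, 0, 0.05)) + 1e-10)
  }
})

test_that("coefficient norms shrink monotonically along the lambda grid", {
  d <- seeded_instance(23, n = 25, p = 4)
  for (alpha in c(0, 0.5, 1)) {
    norms <- vapply(2^seq(-10, 10), function(lam) {
      sqrt(sum(fit_elastic_net(d$x, d$y, alpha = alpha, lambda = lam,
                               tol = 1e-11)$coefficients$weight^2))
    }, numeric(1))
    expect_true(all(diff(norms) <= 1e-8))
  }
})

test_that("internal standardization does not change the fitted predictions", {
  d <- seeded_instance(31, n = 30, p = 6)
  f1 <- fit_elastic_net(d$x, d$y, alpha = 0.6, lambda = 2,
                        standardize = TRUE, tol = 1e-12)
  f2 <- fit_elastic_net(d$x, d$y, alpha = 0.6, lambda = 2,
                        standardize = FALSE, tol = 1e-12)
  p1 <- predict_age(f1, t(d$x))
  p2 <- predict_age(f2, t(d$x))
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("invalid penalty parameters are rejected", {
  d <- seeded_instance(2)
  expect_error(fit_elastic_net(d$x, d$y, alpha = 1.2, lambda = 1), "alpha")
  expect_error(fit_elastic_net(d$x, d$y, alpha = -0.1, lambda = 1), "alpha")
  expect_error(fit_elastic_net(d$x, d$y, alpha = 0.5, lambda = 0), "lambda")
  expect_error(fit_elastic_net(d$x, d$y[-1], alpha = 0.5, lambda = 1), "align")
})

test_that("the packaged best-model equation evaluates as printed", {
  mod <- read_age_model(table4_path())
  expect_equal(nrow(mod$coefficients), 50L)
  # diagnostic all-zero profile returns the intercept
  expect_equal(unname(predict_age(mod, all_zero = TRUE)), 49.1)
  # single-gene evaluation of the printed equation
  profile <- setNames(rep(0, 50), mod$coefficients$gene_id)
  profile["RASSF8"] <- 1
  expect_equal(unname(predict_age(mod, profile)), 49.1 + 0.43450456)
  # missing genes are an error that names them
  expect_error(predict_age(mod, profile[-match("IGSF1", names(profile))]),
               "IGSF1")
})

test_that("predict_age is the stated linear form", {
  d <- seeded_instance(37, n = 20, p = 4)
  fit <- fit_elastic_net(d$x, d$y, alpha = 0.5, lambda = 1)
  x1 <- setNames(rnorm(4), colnames(d$x))
  x2 <- setNames(rnorm(4), colnames(d$x))
  p_combo <- predict_age(fit, 0.3 * x1 + 0.7 * x2)
  expect_equal(unname(p_combo),
               0.3 * unname(predict_age(fit, x1)) +
               0.7 * unname(predict_age(fit, x2)) +
               0 * fit$intercept,  # weights sum to 1: intercept carries over
               tolerance = 1e-10)
  zero_model <- fit_elastic_net(d$x, d$y, alpha = 1, lambda = 1e9)
  expect_equal(unname(predict_age(zero_model, x1)), zero_model$intercept)
})

test_that("rmse and pcc follow their definitions", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(60, 50), c(57, 54)), sqrt((9 + 16) / 2))
  expect_equal(rmse(41.5, 44), 2.5)
  expect_error(rmse(1:3, 1:2), "length mismatch")
  expect_equal(pcc(1:5, 1:5 + 2), 1)
  expect_equal(pcc(1:5, -(1:5) + 11), -1)
  expect_equal(pcc(1:4, c(1, 3, 2, 4)), 0.8)
})

test_that("age models round-trip through the coefficient-table layout", {
  d <- seeded_instance(41, n = 30, p = 6)
  fit <- fit_elastic_net(d$x, d$y, alpha = 1, lambda = 30)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_age_model(fit, path)
  back <- read_age_model(path)
  expect_equal(back$intercept, fit$intercept, tolerance = 1e-6)
  nz <- fit$coefficients[fit$coefficients$weight != 0, ]
  expect_setequal(back$coefficients$gene_id, nz$gene_id)
  m <- match(back$coefficients$gene_id, nz$gene_id)
  expect_equal(back$coefficients$weight, nz$weight[m], tolerance = 1e-6)
  # rows ordered by decreasing coefficient magnitude, as in published tables
  expect_true(all(diff(abs(back$coefficients$weight)) <= 1e-12))
  expect_equal(back$alpha, 1)       # sidecar metadata
  expect_equal(back$lambda, 30)
})
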