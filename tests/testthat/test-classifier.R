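make_toy <- function(n = 300, seed = 7) {
  set.seed(seed)
  X <- cbind(x1 = stats::rnorm(n), x2 = stats::rnorm(n))
  y <- stats::rbinom(n, 1, stats::plogis(0.4 + 1.2 * X[, 1] - 0.8 * X[, 2]))
  list(X = X, y = y)
}

test_that("huge penalty shrinks slopes to zero and the intercept to
           logit(mean(y))", {
  d <- make_toy()
  fit <- fit_recurrence_model(
    d$X, d$y, fit_config(lambda_grid = c(1e7, 1e6, 1e5), seed = 3))
  expect_lt(max(abs(fit$coefficients)), 1e-4)
  expect_equal(fit$intercept, stats::qlogis(mean(d$y)), tolerance = 1e-3)
})

test_that("the penalized fit agrees with a direct numerical minimizer of
           the stated objective", {
  d <- make_toy(400, seed = 11)
  lam <- 0.05
  grid <- c(0.8, 0.4, 0.2, 0.1, lam)
  fit <- fit_recurrence_model(d$X, d$y,
                              fit_config(lambda_grid = grid, seed = 5))
  # compare at a fixed lambda on the path via the oracle
  oracle <- ridge_logistic_oracle(d$X, d$y, lam)
  g <- glmnet::glmnet(d$X, d$y, family = "binomial", alpha = 0,
                      lambda = grid, standardize = FALSE, thresh = 1e-14)
  ours <- as.numeric(stats::coef(g, s = lam, exact = TRUE,
                                 x = d$X, y = d$y))
  expect_lt(max(abs(ours - oracle)), 1e-4)
  # and the model's own refit coefficients agree with the oracle at its
  # selected penalty
  oracle_1se <- ridge_logistic_oracle(d$X, d$y, fit$lambda_1se)
  expect_lt(max(abs(c(fit$intercept, unname(fit$coefficients)) -
                      oracle_1se)), 1e-3)
})

test_that("lambda.1se is at least lambda.min and obeys its definition", {
  for (seed in c(2, 9, 23)) {
    d <- make_toy(250, seed = seed)
    fit <- fit_recurrence_model(d$X, d$y, fit_config(seed = seed))
    expect_gte(fit$lambda_1se, fit$lambda_min)
    cv <- fit$cv_curve
    imin <- which.min(cv$mean_loss)
    thresh <- cv$mean_loss[imin] + cv$se_loss[imin]
    # largest lambda with mean loss within one SE of the minimum
    eligible <- cv$lambda[cv$mean_loss <= thresh]
    expect_equal(fit$lambda_1se, max(eligible))
  }
})

test_that("coefficient norm shrinks monotonically along increasing lambda", {
  d <- make_toy(200, seed = 4)
  grid <- c(2, 1, 0.5, 0.2, 0.1, 0.05, 0.02)
  g <- glmnet::glmnet(d$X, d$y, family = "binomial", alpha = 0,
                      lambda = grid, standardize = FALSE, thresh = 1e-12)
  norms <- sqrt(colSums(as.matrix(g$beta)^2))
  expect_true(all(diff(norms) >= -1e-8))  # path is fit large -> small lambda
})

test_that("fitting is deterministic given config and seed", {
  d <- make_toy(200, seed = 8)
  f1 <- fit_recurrence_model(d$X, d$y, fit_config(seed = 42))
  f2 <- fit_recurrence_model(d$X, d$y, fit_config(seed = 42))
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$cutoff, f2$cutoff)
  expect_identical(f1$foldid, f2$foldid)
  f3 <- fit_recurrence_model(d$X, d$y, fit_config(seed = 43))
  expect_false(identical(f1$foldid, f3$foldid))
})

test_that("input validation: single-class y and non-finite X are rejected", {
  d <- make_toy(50)
  expect_error(fit_recurrence_model(d$X, rep(1, 50), fit_config()),
               "both classes")
  Xb <- d$X; Xb[3, 2] <- NA
  expect_error(fit_recurrence_model(Xb, d$y, fit_config()), "x2")
})

test_that("cutoff selection maximizes F1 with ties broken toward 0.5", {
  cfg <- fit_config()
  fake <- list(config = cfg, oof_prob = c(0.9, 0.8, 0.1, 0.2))
  y <- c(1, 1, 0, 0)
  sel <- select_cutoff(fake, y)
  # any cutoff in (0.2, 0.8] is perfect; nearest grid point to 0.5 wins
  expect_equal(sel$cutoff, 0.5)
  expect_equal(sel$f1, 1)

  # all-identical probabilities fall back to 0.5 with a warning
  fake2 <- list(config = cfg, oof_prob = rep(0.6, 4))
  expect_warning(sel2 <- select_cutoff(fake2, y), "identical")
  expect_equal(sel2$cutoff, 0.5)

  # achieved F1 equals an independent recomputation at the chosen cutoff
  set.seed(31)
  probs <- stats::runif(200)
  yy <- stats::rbinom(200, 1, probs)
  fake3 <- list(config = cfg, oof_prob = probs)
  sel3 <- select_cutoff(fake3, yy)
  yhat <- as.integer(probs >= sel3$cutoff)
  tp <- sum(yy & yhat); fp <- sum(!yy & yhat); fn <- sum(yy & !yhat)
  expect_equal(sel3$f1, 2 * tp / (2 * tp + fp + fn))
})

test_that("prediction aligns columns by name and applies the stored
           standardization", {
  d <- make_toy(300, seed = 13)
  fit <- fit_recurrence_model(d$X, d$y, fit_config(seed = 2))
  # shuffled columns give identical probabilities
  p1 <- predict_prob(fit, d$X)
  p2 <- predict_prob(fit, d$X[, c("x2", "x1")])
  expect_equal(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
  # zero feature vector predicts plogis(intercept)
  z <- matrix(0, 1, 2, dimnames = list(NULL, c("x1", "x2")))
  expect_equal(predict_prob(fit, z), stats::plogis(fit$intercept))
  # cutoff 0 classifies everything positive
  expect_true(all(classify(fit, d$X, cutoff = 0) == 1L))
  expect_error(predict_prob(fit, z[, 1, drop = FALSE]), "x2")
  # hand-computed logistic on a 2x2 toy
  man <- stats::plogis(fit$intercept + d$X[1:2, ] %*% fit$coefficients)
  expect_equal(p1[1:2], as.numeric(man))
})

test_that("models survive a JSON round-trip", {
  d <- make_toy(150, seed = 6)
  fit <- fit_recurrence_model(d$X, d$y, fit_config(seed = 1))
  p <- tempfile(fileext = ".json")
  write_model_json(fit, p)
  back <- read_model_json(p)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(back$intercept, fit$intercept)
  expect_equal(back$cutoff, fit$cutoff)
  expect_equal(predict_prob(back, d$X), predict_prob(fit, d$X))
})

test_that("a sparse true logistic signal is recovered at lambda.1se", {
  set.seed(77)
  n <- 2000; p <- 30
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", 1:p)))
  beta <- rep(0, p)
  beta[1:5] <- c(2.0, -1.6, 1.2, -0.9, 0.7)
  y <- stats::rbinom(n, 1, stats::plogis(X %*% beta))
  fit <- fit_recurrence_model(X, y, fit_config(seed = 10))
  est <- fit$coefficients
  # signs of the five true effects recovered
  expect_true(all(sign(est[1:5]) == sign(beta[1:5])))
  # the top-5 features by |estimate| are the five true ones
  expect_setequal(names(sort(abs(est), decreasing = TRUE)[1:5]),
                  paste0("f", 1:5))
})
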