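test_that("forward pass matches closed-form cases", {
  # zero weights, sigmoid: every output is 0.5
  net <- lmnet(c(3, 2, 2), "sigmoid", seed = 1)
  net$weights <- lapply(net$weights, function(w) w * 0)
  net$biases <- lapply(net$biases, function(b) b * 0)
  acts <- nn_forward(net, c(0.3, -1, 2))
  expect_equal(acts[[3]], c(0.5, 0.5))

  # single linear identity layer
  id_net <- lmnet(c(3, 3), "linear", seed = 1, bias = FALSE)
  id_net$weights[[1]] <- diag(3)
  expect_equal(nn_forward(id_net, c(1, -2, 3))[[2]], c(1, -2, 3))

  # 2 -> 1 sigmoid with w = (1, 1), b = 0, x = (0, 0)
  n3 <- lmnet(c(2, 1), "sigmoid", seed = 1)
  n3$weights[[1]][] <- 1; n3$biases[[1]] <- 0
  expect_equal(nn_forward(n3, c(0, 0))[[2]], 0.5)

  expect_error(nn_forward(net, c(1, 2)), "length mismatch")
})

test_that("residuals stack sample-major and F = e'e", {
  net <- lmnet(c(1, 1), "linear", seed = 1, bias = FALSE)
  net$weights[[1]][] <- 1
  r <- nn_residuals(net, matrix(c(1, 2)), matrix(c(1, 2)))
  expect_equal(r$e, c(0, 0))
  expect_equal(r$f, 0)

  # one sample, one output: y = 0.5, t = 1 -> F = 0.25
  n2 <- lmnet(c(1, 1), "sigmoid", seed = 1)
  n2$weights[[1]][] <- 0; n2$biases[[1]] <- 0
  expect_equal(nn_residuals(n2, matrix(5), matrix(1))$f, 0.25)

  # residual ordering: two outputs, residual of sample i output o at
  # position (i-1)*2 + o
  n3 <- lmnet(c(1, 2), "linear", seed = 1, bias = FALSE)
  n3$weights[[1]] <- matrix(c(1, 2), 2, 1)
  r3 <- nn_residuals(n3, matrix(c(1, 2)), matrix(0, 2, 2))
  expect_equal(r3$e, c(1, 2, 2, 4))
  expect_error(nn_residuals(net, matrix(numeric(0)), matrix(numeric(0))), "empty")
})

test_that("analytic Jacobian matches hand case and zero-input rule", {
  # linear 1 -> 1 net y = w x + b, sample x = 2: row = (2, 1)
  net <- lmnet(c(1, 1), "linear", seed = 1)
  J <- nn_jacobian(net, matrix(2))
  expect_equal(J, matrix(c(2, 1), 1))

  # zero input sample: first-layer weight columns vanish
  net2 <- lmnet(c(2, 2, 1), "sigmoid", seed = 2)
  J2 <- nn_jacobian(net2, matrix(0, 1, 2))
  expect_true(all(J2[, 1:4] == 0))
})

test_that("analytic Jacobian agrees with central finite differences", {
  worst <- 0
  for (seed in 1:20) {
    f <- random_small_net(seed)
    Ja <- nn_jacobian(f$net, f$X)
    Jf <- fd_jacobian(f$net, f$X, h = 1e-6)
    rel <- max(abs(Ja - Jf)) / max(max(abs(Ja)), 1e-12)
    worst <- max(worst, rel)
  }
  expect_lte(worst, 1e-6)
  expect_error(fd_jacobian(random_small_net(1)$net, random_small_net(1)$X, h = 0), "positive")
})

test_that("one damped step on the scalar linear model matches the closed form", {
  # y = w x, data {(1, 1)}, w = 0, mu = 0.01: delta = -1/1.01, w' = 0.990099...
  net <- lmnet(c(1, 1), "linear", seed = 1, bias = FALSE)
  net$weights[[1]][] <- 0
  st <- lm_train_state(mu = 0.01)
  step <- lm_step(net, st, matrix(1), matrix(1))
  expect_true(step$accepted)
  expect_equal(step$net$weights[[1]][1, 1], 1 / 1.01, tolerance = 1e-12)
  expect_equal(step$state$mu, 0.001)  # accepted: mu * beta
})

test_that("damping grows by 1/beta on a rejected step and caps out", {
  # at the exact optimum Jt e = 0: delta = 0, F unchanged -> rejected
  net <- lmnet(c(1, 1), "linear", seed = 1, bias = FALSE)
  net$weights[[1]][] <- 1
  st <- lm_train_state(mu = 0.01)
  step <- lm_step(net, st, matrix(c(1, 2)), matrix(c(1, 2)))
  expect_false(step$accepted)
  expect_equal(step$state$mu, 0.1)  # rejected: mu / beta with beta = 0.1
  expect_equal(step$net$weights[[1]][1, 1], 1)

  st$mu <- 1e10
  step2 <- lm_step(net, st, matrix(c(1, 2)), matrix(c(1, 2)))
  expect_equal(step2$state$status, "mu_overflow")
})

test_that("training a linear network recovers generating weights (normal-equations oracle)", {
  withr::with_seed(11, {
    X <- matrix(stats::rnorm(60), 20, 3)
    w_true <- c(0.7, -1.2, 0.4); b_true <- 0.3
    t <- X %*% w_true + b_true
  })
  net <- lmnet(c(3, 1), "linear", seed = 5)
  fit <- lm_train(net, X, t, lm_control(max_iter = 100, f_tol = 1e-20, rel_tol = 0))
  expect_equal(as.numeric(fit$net$weights[[1]]), w_true, tolerance = 1e-6)
  expect_equal(fit$net$biases[[1]], b_true, tolerance = 1e-6)
  expect_lte(fit$state$f_history[length(fit$state$f_history)], 1e-10)

  # independent oracle: direct normal-equations solve
  A <- cbind(X, 1)
  beta <- solve(crossprod(A), crossprod(A, t))
  expect_equal(c(as.numeric(fit$net$weights[[1]]), fit$net$biases[[1]]),
               as.numeric(beta), tolerance = 1e-8)
})

test_that("max_iter = 0 returns the initial network unchanged", {
  net <- lmnet(c(2, 2), "sigmoid", seed = 9)
  X <- matrix(stats::runif(8), 4, 2)
  fit <- lm_train(net, X, matrix(0.5, 4, 2), lm_control(max_iter = 0))
  expect_identical(fit$net$weights, net$weights)
  expect_equal(fit$state$iteration, 0L)
})

test_that("accepted-step F history is non-increasing across random problems", {
  for (seed in 1:10) {
    f <- random_small_net(seed)
    k <- f$net$layer_sizes[length(f$net$layer_sizes)]
    targets <- withr::with_seed(seed + 100,
      matrix(stats::runif(nrow(f$X) * k, 0.2, 0.8), nrow(f$X), k))
    fit <- lm_train(f$net, f$X, targets, lm_control(max_iter = 40))
    expect_true(all(diff(fit$state$f_history) <= 0), info = paste("seed", seed))
  }
})

test_that("model JSON round trip predicts bit-identically", {
  net <- lmnet(c(5, 4, 2), c("tanh", "sigmoid"), seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_lmnet(net, path)
  net2 <- read_lmnet(path)
  X <- withr::with_seed(8, matrix(stats::rnorm(20), 4, 5))
  expect_identical(predict(net, X), predict(net2, X))
  expect_identical(net2$activations, net$activations)
})

test_that("tidy and glance expose parameters and fit summary", {
  net <- lmnet(c(2, 2, 1), "sigmoid", seed = 4)
  td <- tidy(net)
  expect_equal(nrow(td), lmscreen:::n_params(net))
  expect_true(all(c("layer", "term", "estimate") %in% names(td)))
  X <- matrix(stats::runif(10), 5, 2)
  fit <- lm_train(net, X, matrix(0.4, 5, 1), lm_control(max_iter = 5))
  g <- glance(fit)
  expect_lte(g$iterations, 5L)
  expect_true(g$f_final <= g$f_initial)
})
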