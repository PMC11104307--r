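test_that("prediction sums active weights and rectifies at zero", {
  expect_equal(predict_us(c(0.8, -0.5), c(1, 1)), 0.3)
  expect_equal(predict_us(c(0.8, -0.5), c(0, 1)), 0)
  expect_equal(predict_us(c(0, 0), c(1, 1)), 0)
  expect_equal(predict_us(-0.5, 1, rectify = FALSE), -0.5)
})

test_that("attention weights are the m-normalized salience gains", {
  att <- attention_weights(c(1, 1), c(1, 1), m = 8)
  expect_equal(att$gnorm, 2^(1 / 8))
  expect_equal(att$a, rep(2^(-1 / 8), 2))
  expect_equal(sum(att$a^8)^(1 / 8), 1)  # unit m-norm over present features

  expect_equal(attention_weights(c(5, 2), c(1, 0), m = 8)$a, c(1, 0))
  expect_equal(attention_weights(c(3, 1), c(1, 1), m = 1)$a, c(0.75, 0.25))
  expect_error(attention_weights(c(1, 1), c(0, 0), m = 8), "no features active")
})

test_that("familiarity learning rate follows the closed form and decreases", {
  expect_equal(familiarity_rate(1, 0.1, 1.5), 0.1 + 0.5 * 2^(-1.5))
  expect_equal(familiarity_rate(3, 0.15, 0.5), 0.4)
  n <- 0:200
  lam <- familiarity_rate(n, 0.1, 1.5)
  expect_true(all(diff(lam) < 0))
  expect_true(all(lam > 0.1 & lam <= 0.1 + 0.5))
  expect_equal(familiarity_rate(1e9, 0.1, 1.5), 0.1, tolerance = 1e-6)
})

test_that("salience update matches a finite-difference gradient oracle", {
  set.seed(11)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    f <- rep(1, k); f[sample(k, 1)] <- sample(0:1, 1)
    if (all(f == 0)) f[1] <- 1
    w <- runif(k, 0.1, 0.9)  # positive weights keep yhat interior (> 0)
    eta <- runif(k, 0.5, 2)
    m <- sample(c(2, 8), 1)
    mu <- runif(1, 0.5, 2)
    y <- 1
    att <- attention_weights(eta, f, m)
    yhat <- predict_us(w, f, a = att$a)
    expect_gt(yhat, 0)
    new_eta <- salience_update(eta, f, w, att$a, att$gnorm, yhat, y, mu, m,
                               floor = 1e-4)
    sqerr <- function(e) {
      at <- attention_weights(e, f, m)
      (y - predict_us(w, f, a = at$a))^2
    }
    grad <- pracma::grad(sqerr, eta)
    expect_equal(new_eta - eta, -mu / 2 * grad, tolerance = 1e-6)
  }
})

test_that("zero prediction error and absent features leave salience alone", {
  eta <- c(1, 2)
  f <- c(1, 1)
  w <- c(0.5, 0.5)
  att <- attention_weights(eta, f, 8)
  yhat <- predict_us(w, f, a = att$a)
  expect_equal(salience_update(eta, f, w, att$a, att$gnorm, yhat, yhat,
                               1.5, 8), eta)
  f2 <- c(1, 0)
  att2 <- attention_weights(eta, f2, 8)
  out <- salience_update(eta, f2, w, att2$a, att2$gnorm, 0.2, 1, 1.5, 8)
  expect_equal(out[2], eta[2])  # absent feature untouched
})

test_that("one step of the basic model reproduces the hand-computed update", {
  basis <- build_basis(stimulus_catalog("CS", "A"))
  st <- init_state(basis)
  out <- learner_step(st, c(CS = 1, A = 1), 1, basis,
                      model_params("basic", lambda = 0.3))
  expect_equal(out$record$yhat, 0)
  expect_equal(out$record$error, 1)
  expect_equal(out$state$w, c(CS = 0.3, A = 0.3))
})

test_that("decay acts on negative weights on featureless steps only", {
  basis <- build_basis(stimulus_catalog("CS", "A"))
  st <- init_state(basis)
  st$w <- c(CS = 0.4, A = -0.5)
  pars <- model_params("decay", rho = 0.002)
  out <- learner_step(st, c(CS = 0, A = 0), 0, basis, pars)
  expect_equal(out$state$w, c(CS = 0.4, A = -0.499))

  # boundary: exactly-zero weight is not decayed
  st$w <- c(CS = 0, A = 0)
  out0 <- learner_step(st, c(CS = 0, A = 0), 0, basis, pars)
  expect_equal(out0$state$w, c(CS = 0, A = 0))
})

test_that("a fully predicted US is a fixed point when no weight is negative", {
  basis <- build_basis(stimulus_catalog("CS", "A"))
  for (v in c("basic", "familiarity")) {
    st <- init_state(basis)
    st$w <- c(CS = 0.7, A = 0.3)
    out <- learner_step(st, c(CS = 1, A = 1), 1, basis, model_params(v))
    expect_equal(out$state$w, st$w)
  }
})

test_that("a lone inhibitor does not extinguish under rectified prediction", {
  basis <- build_basis(stimulus_catalog("X", "A"), include_contexts = FALSE)
  st <- init_state(basis)
  st$w <- c(X = -0.6)
  out <- learner_step(st, c(X = 1, A = 0), 0, basis, model_params("basic"))
  expect_equal(out$record$yhat, 0)
  expect_equal(out$state$w, c(X = -0.6))
  # linear prediction (the historical failure mode): weight creeps up
  out2 <- learner_step(st, c(X = 1, A = 0), 0, basis,
                       model_params("basic", rectify = FALSE))
  expect_equal(out2$record$yhat, -0.6)
  expect_gt(out2$state$w["X"], -0.6)
})

test_that("acquisition approaches the US asymptote", {
  d <- fix_cond_ext(10, 0)
  tr <- run_learner(d, "main", params = model_params("basic", lambda = 0.3))
  final <- tr$yhat[max(which(tr$info$type == "trial"))]
  expect_gt(final, 0.9)
  expect_true(all(tr$yhat >= 0))
  # no stochastic element: repeat runs are identical
  tr2 <- run_learner(d, "main", params = model_params("basic", lambda = 0.3))
  expect_identical(tr$W, tr2$W)
})

test_that("negative weights contract geometrically over a pure delay", {
  basis <- build_basis(stimulus_catalog("CS", "A"))
  st <- init_state(basis)
  st$w <- c(CS = 0.3, A = -0.5)
  tr <- run_learner(fix_delay_only(200), "main", basis = basis,
                    params = model_params("decay", rho = 0.002),
                    initial_state = st)
  expect_equal(tr$final_state$w[["A"]], -0.5 * (1 - 0.002)^200)
  expect_equal(tr$final_state$w[["CS"]], 0.3)  # positive weights immune
})

test_that("rectified prediction is non-negative for every variant", {
  set.seed(21)
  for (v in c("basic", "configural", "decay", "familiarity", "compact")) {
    case <- random_oracle_case(v)
    case$params$rectify <- TRUE
    res <- pkg_run_steps(case$X, case$y, case$basis, case$params)
    expect_true(all(res$yhat >= 0))
  }
})

test_that("compact attention has unit m-norm over present features", {
  p <- build_paradigm("gradual_extinction")
  tr <- run_paradigm(p)$trajectories$Standard
  present <- tr$info$type != "delay"
  norms <- apply(tr$A[present, , drop = FALSE], 1, function(a)
    sum(abs(a)^8)^(1 / 8))
  expect_equal(norms, rep(1, sum(present)))
})

test_that("non-finite state fails fast", {
  basis <- build_basis(stimulus_catalog("CS", "A"))
  st <- init_state(basis)
  st$w[1] <- NaN
  expect_error(learner_step(st, c(CS = 1, A = 1), 1, basis,
                            model_params("basic")), "non-finite")
})

test_that("unknown or out-of-range parameters are rejected", {
  expect_error(model_params("basic", rho = 0.1), "unknown parameter")
  expect_error(model_params("basic", lambda = 1.5))
  expect_error(model_params("compact", m = 0.5))
})
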