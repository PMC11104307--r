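# Naive, loop-by-loop transcription of each learner variant's per-step
# pseudocode. Deliberately independent of the package internals (explicit
# per-feature for-loops, own featurization) so it can serve as an oracle
# for the vectorized implementation.

oracle_featurize <- function(x, basis) {
  f <- numeric(nrow(basis))
  for (j in seq_len(nrow(basis))) {
    if (basis$kind[j] == "elemental") {
      f[j] <- x[[basis$s1[j]]]
    } else {
      f[j] <- x[[basis$s1[j]]] * x[[basis$s2[j]]]
    }
  }
  f
}

oracle_run <- function(variant, X, y, basis, pars) {
  k <- nrow(basis)
  w <- numeric(k); n <- numeric(k); eta <- rep(1, k)
  W <- N <- ETA <- matrix(NA_real_, nrow(X), k)
  YHAT <- numeric(nrow(X))
  for (t in seq_len(nrow(X))) {
    f <- oracle_featurize(X[t, ], basis)
    if (variant %in% c("basic", "configural", "decay", "familiarity")) {
      yhat <- 0
      for (i in 1:k) yhat <- yhat + f[i] * w[i]
      if (pars$rectify) yhat <- max(yhat, 0)
      err <- y[t] - yhat
      if (variant %in% c("basic", "configural")) {
        for (i in 1:k) w[i] <- w[i] + pars$lambda * f[i] * err
      } else if (variant == "decay") {
        for (i in 1:k)
          w[i] <- w[i] + pars$lambda * f[i] * err -
            (if (w[i] < 0) 1 else 0) * pars$rho * w[i]
      } else {
        for (i in 1:k) {
          n[i] <- n[i] + f[i]
          lam <- pars$lambda_min + 0.5 * (n[i] + 1)^(-pars$p)
          w[i] <- w[i] + lam * f[i] * err
        }
      }
    } else { # compact
      if (all(f == 0)) {
        yhat <- 0
        for (i in 1:k)
          if (w[i] < 0) w[i] <- w[i] - pars$rho * w[i]
      } else {
        g <- numeric(k)
        for (i in 1:k) g[i] <- eta[i] * f[i]
        gn <- 0
        for (i in 1:k) gn <- gn + abs(g[i])^pars$m
        gn <- gn^(1 / pars$m)
        a <- numeric(k)
        for (i in 1:k) a[i] <- g[i] / gn
        yhat <- 0
        for (i in 1:k) yhat <- yhat + a[i] * f[i] * w[i]
        if (pars$rectify) yhat <- max(yhat, 0)
        err <- y[t] - yhat
        for (i in 1:k) {
          n[i] <- n[i] + f[i]
          lam <- pars$lambda_min + 0.5 * (n[i] + 1)^(-pars$p)
          eta[i] <- max(eta[i] + pars$mu * f[i] * (1 / gn) * err *
                          (w[i] * f[i] - a[i]^(pars$m - 1) * yhat),
                        pars$eta_floor)
          w[i] <- w[i] + lam * a[i] * f[i] * err -
            (if (w[i] < 0) 1 else 0) * pars$rho * w[i]
        }
      }
    }
    W[t, ] <- w; N[t, ] <- n; ETA[t, ] <- eta; YHAT[t] <- yhat
  }
  list(W = W, N = N, ETA = ETA, yhat = YHAT)
}

# drive the package step function over a raw cue matrix
pkg_run_steps <- function(X, y, basis, params) {
  state <- init_state(basis)
  k <- nrow(basis)
  W <- N <- ETA <- matrix(NA_real_, nrow(X), k)
  YHAT <- numeric(nrow(X))
  for (t in seq_len(nrow(X))) {
    out <- learner_step(state, X[t, ], y[t], basis, params)
    state <- out$state
    W[t, ] <- state$w; N[t, ] <- state$n; ETA[t, ] <- state$eta
    YHAT[t] <- out$record$yhat
  }
  list(W = W, N = N, ETA = ETA, yhat = YHAT)
}

random_oracle_case <- function(variant) {
  n_cs <- sample(1:4, 1)
  catalog <- stimulus_catalog(paste0("S", seq_len(n_cs)), "CTX")
  basis <- build_basis(catalog,
                       include_configural = variant %in% c("configural", "compact"))
  steps <- sample(5:20, 1)
  stim <- stimuli(catalog)
  X <- matrix(rbinom(steps * length(stim), 1, 0.5), steps,
              dimnames = list(NULL, stim))
  X[sample(steps, 2), ] <- 0  # featureless (delay-like) steps included
  y <- rbinom(steps, 1, 0.4)
  params <- switch(variant,
    basic = model_params("basic", lambda = runif(1, 0.05, 0.5)),
    configural = model_params("configural", lambda = runif(1, 0.05, 0.5)),
    decay = model_params("decay", lambda = runif(1, 0.05, 0.5),
                         rho = runif(1, 0.001, 0.05)),
    familiarity = model_params("familiarity", lambda_min = runif(1, 0.05, 0.3),
                               p = runif(1, 0.3, 2)),
    compact = model_params("compact", rho = runif(1, 0.001, 0.05),
                           mu = runif(1, 0.5, 2),
                           lambda_min = runif(1, 0.05, 0.3),
                           m = sample(c(1, 2, 8), 1), p = runif(1, 0.3, 2)))
  params$rectify <- runif(1) < 0.8
  list(X = X, y = y, basis = basis, params = params)
}
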