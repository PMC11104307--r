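VARIANTS <- c("basic", "configural", "decay", "familiarity", "compact")

# figure-caption defaults per variant
variant_defaults <- function(variant) {
  switch(variant,
    basic       = list(lambda = 0.3),
    configural  = list(lambda = 0.2),
    decay       = list(lambda = 0.3, rho = 0.002),
    familiarity = list(lambda_min = 0.1, p = 1.5),
    compact     = list(rho = 0.01, mu = 1.5, lambda_min = 0.15, m = 8, p = 0.5))
}

#' Model parameters
#'
#' Bundles the parameters of one learner variant:
#' \describe{
#'   \item{basic}{delta rule on elemental features; `lambda`.}
#'   \item{configural}{delta rule on elemental plus configural features;
#'     `lambda`.}
#'   \item{decay}{basic plus asymmetric forgetting: negative weights shrink
#'     by a fraction `rho` on every time step; positive weights are stable.}
#'   \item{familiarity}{per-feature learning rate that declines with the
#'     number of observations of the feature,
#'     `lambda_i = lambda_min + 0.5 (n_i + 1)^(-p)`.}
#'   \item{compact}{revised CompAct: configural features, familiarity rates,
#'     decay of inhibition, and competitive attention. Each feature carries a
#'     salience `eta`; attention is the m-norm-normalized salience-gated
#'     activation and rescales both prediction and learning; salience follows
#'     gradient descent on squared prediction error with step size `mu`.}
#' }
#' Prediction is positively rectified by default (`rectify = TRUE`); turning
#' rectification off restores the original linear prediction, under which a
#' lone conditioned inhibitor erroneously extinguishes.
#'
#' Unspecified parameters take the variant's defaults (the hand-tuned values
#' used throughout the simulation battery); unknown names are rejected.
#'
#' @param variant One of basic, configural, decay, familiarity, compact.
#' @param ... Parameter overrides: `lambda`, `rho`, `lambda_min`, `p`, `mu`,
#'   `m`, `rectify`, `eta_floor`.
#' @return An object of class `rw_params`.
#' @examples
#' model_params("decay")               # lambda 0.3, rho 0.002
#' model_params("basic", lambda = 0.1)
#' @export
model_params <- function(variant = VARIANTS, ...) {
  variant <- match.arg(variant)
  p <- variant_defaults(variant)
  p$rectify <- TRUE
  if (variant == "compact") p$eta_floor <- 1e-4
  dots <- list(...)
  unknown <- setdiff(names(dots), c(names(p)))
  if (length(unknown))
    stop("unknown parameter(s) for variant '", variant, "': ",
         paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  if (!is.null(p$lambda)) stopifnot(p$lambda > 0, p$lambda < 1)
  if (!is.null(p$rho)) stopifnot(p$rho >= 0, p$rho < 1)
  if (!is.null(p$lambda_min)) stopifnot(p$lambda_min > 0)
  if (!is.null(p$p)) stopifnot(p$p > 0)
  if (!is.null(p$mu)) stopifnot(p$mu > 0)
  if (!is.null(p$m)) stopifnot(p$m >= 1)
  structure(c(list(variant = variant), p), class = "rw_params")
}

#' @export
print.rw_params <- function(x, ...) {
  vals <- x[setdiff(names(x), "variant")]
  cat("<rw_params> ", x$variant, ": ",
      paste(names(vals), unlist(lapply(vals, format)), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Does the variant use configural features by default?
#' @param params An `rw_params`.
#' @return Logical.
#' @export
uses_configural <- function(params) params$variant %in% c("configural", "compact")

#' Fresh learner state
#'
#' Novel features start with zero association weight (no pre-existing
#' associations), zero observation count, and unit salience.
#'
#' @param basis An [build_basis()] result.
#' @return An object of class `rw_state` with named vectors `w`, `n`, `eta`.
#' @export
init_state <- function(basis) {
  z <- stats::setNames(numeric(nrow(basis)), basis$id)
  structure(list(w = z, n = z, eta = z + 1), class = "rw_state")
}

#' US prediction from current associations
#'
#' The summed associative strength of active features, positively rectified
#' (a predicted US value cannot be negative). For the compact variant,
#' activations are rescaled by attention weights `a`.
#'
#' @param w Weight vector.
#' @param f Feature activation vector.
#' @param rectify Apply `max(., 0)`?
#' @param a Optional attention weights (compact).
#' @return Scalar predicted US value.
#' @examples
#' predict_us(c(0.8, -0.5), c(1, 1))  # 0.3
#' predict_us(c(0.8, -0.5), c(0, 1))  # 0
#' @export
predict_us <- function(w, f, rectify = TRUE, a = NULL) {
  s <- if (is.null(a)) sum(f * w) else sum(a * f * w)
  if (rectify) max(s, 0) else s
}

#' Competitive attention weights
#'
#' Attention gain is salience gated by activation, `g = eta * f`; attention
#' weights are the gain normalized by its m-norm, so the attention vector
#' always has unit m-norm over present features. Lower `m` means stronger
#' competition between features. Undefined when no feature is active.
#'
#' @param eta Salience vector (positive).
#' @param f Feature activation vector.
#' @param m Norm order (>= 1).
#' @return List with `g`, `a`, and `gnorm` (the m-norm of `g`).
#' @examples
#' attention_weights(c(1, 1), c(1, 1), m = 8)$gnorm  # 2^(1/8)
#' @export
attention_weights <- function(eta, f, m) {
  g <- eta * f
  if (all(g == 0)) stop("attention undefined: no features active")
  gnorm <- sum(abs(g)^m)^(1 / m)
  list(g = g, a = g / gnorm, gnorm = gnorm)
}

#' Familiarity-dependent learning rate
#'
#' Attention to a feature declines each time it is observed:
#' `lambda_i = lambda_min + 0.5 (n_i + 1)^(-p)`, falling from
#' `lambda_min + 0.5` toward the asymptote `lambda_min`. `n_i` is the count
#' *after* the current observation has been tallied.
#'
#' @param n Observation count(s).
#' @param lambda_min Asymptotic minimum learning rate.
#' @param p Decline exponent (> 0).
#' @return Learning rate(s), same shape as `n`.
#' @examples
#' familiarity_rate(1, 0.1, 1.5)  # 0.1 + 0.5 * 2^-1.5
#' @export
familiarity_rate <- function(n, lambda_min, p) lambda_min + 0.5 * (n + 1)^(-p)

#' Salience update (gradient descent on squared prediction error)
#'
#' Moves each active feature's salience along the negative gradient of the
#' squared prediction error, so features that predict the US accurately gain
#' salience at the expense of the rest:
#' `eta_i <- eta_i + mu * f_i * |g|_m^-1 * (y - yhat) * (w_i f_i - a_i^(m-1) yhat)`.
#' Absent features are untouched. The result is clipped from below at
#' `floor` (salience must stay positive for the m-norm to be defined).
#'
#' @param eta,f,w Current salience, activations, weights.
#' @param a,gnorm Attention weights and gain norm from [attention_weights()].
#' @param yhat,y Predicted and observed US value for the step.
#' @param mu Salience step size.
#' @param m Norm order.
#' @param floor Lower clip for salience.
#' @return Updated salience vector.
#' @export
salience_update <- function(eta, f, w, a, gnorm, yhat, y, mu, m, floor = 1e-4) {
  pmax(eta + mu * f / gnorm * (y - yhat) * (w * f - a^(m - 1) * yhat), floor)
}

#' Execute one time step of a learner
#'
#' Runs the selected variant's per-step program: featurize, (compact)
#' attention, predict, (familiarity/compact) tally observations and compute
#' per-feature rates, (compact) salience update, then the weight update.
#' All updates use the step's pre-update prediction. Decay of inhibition
#' applies to every negative weight on every step, gated neither by feature
#' activation nor by trial type — a delay is simply a long run of
#' featureless steps during which inhibition fades.
#'
#' @param state An `rw_state`.
#' @param x Named cue-presence vector over catalog stimuli.
#' @param y Observed US value (0/1).
#' @param basis Feature basis the state is dimensioned over.
#' @param params An [model_params()].
#' @return List with `record` (yhat, error, and per-feature `lambda_i`/`a`
#'   where the variant defines them) and `state` (updated).
#' @export
learner_step <- function(state, x, y, basis, params) {
  if (any(!is.finite(state$w)) || any(!is.finite(state$eta)))
    stop("non-finite learner state")
  f <- featurize(x, basis)
  step_core(state, f, y, params)
}

# shared per-step kernel operating directly on feature activations
step_core <- function(state, f, y, params) {
  w <- state$w
  variant <- params$variant
  rec <- list(yhat = NA_real_, error = NA_real_, lambda_i = NULL, a = NULL)

  if (variant == "compact") {
    if (!any(f > 0)) {
      # delay step: attention undefined, nothing to learn; inhibition decays
      rec$yhat <- 0
      rec$error <- y - 0
      state$w <- w - (w < 0) * params$rho * w
      return(list(record = rec, state = state))
    }
    att <- attention_weights(state$eta, f, params$m)
    yhat <- predict_us(w, f, params$rectify, a = att$a)
    err <- y - yhat
    state$n <- state$n + f
    lam <- familiarity_rate(state$n, params$lambda_min, params$p)
    state$eta <- salience_update(state$eta, f, w, att$a, att$gnorm, yhat, y,
                                 params$mu, params$m, params$eta_floor)
    state$w <- w + lam * att$a * f * err - (w < 0) * params$rho * w
    rec$yhat <- yhat; rec$error <- err; rec$lambda_i <- lam; rec$a <- att$a
    return(list(record = rec, state = state))
  }

  yhat <- predict_us(w, f, params$rectify)
  err <- y - yhat
  if (variant %in% c("basic", "configural")) {
    state$w <- w + params$lambda * f * err
  } else if (variant == "decay") {
    state$w <- w + params$lambda * f * err - (w < 0) * params$rho * w
  } else if (variant == "familiarity") {
    state$n <- state$n + f
    lam <- familiarity_rate(state$n, params$lambda_min, params$p)
    state$w <- w + lam * f * err
    rec$lambda_i <- lam
  }
  rec$yhat <- yhat; rec$error <- err
  list(record = rec, state = state)
}

#' Run a learner over a design group
#'
#' Expands the design for one group and applies [learner_step()] to every
#' time step, recording the full learner state after each step. The run is
#' deterministic: there is no stochastic element anywhere in the models.
#'
#' @param design A valid `rw_design` (or an already expanded `rw_timesteps`).
#' @param group Group label (ignored if `design` is already expanded).
#' @param basis Feature basis; defaults to the variant's canonical basis
#'   over the design's catalog.
#' @param params An [model_params()].
#' @param initial_state Optional starting `rw_state` (default: fresh zeros).
#' @return An object of class `rw_trajectory`: list with `info`, `y`,
#'   `yhat`, `error`, state-history matrices `W`, `N`, `ETA` (steps by
#'   features, state *after* each step), per-step `A` and `LAMBDA` where
#'   defined, `basis`, `params`, and `final_state`.
#' @examples
#' d <- design(stimulus_catalog("CS", "A"),
#'             trial_spec("CS+", "CS", 1),
#'             groups = list(g = list(stage("cond", "A", rep("CS+", 10)))))
#' tr <- run_learner(d, "g", params = model_params("basic"))
#' tail(tr$yhat[tr$info$type == "trial"], 1)  # near asymptote 1
#' @export
run_learner <- function(design, group = NULL, basis = NULL, params,
                        initial_state = NULL) {
  if (inherits(design, "rw_timesteps")) {
    ts <- design
    if (is.null(basis)) stop("basis required when passing an expanded sequence")
  } else {
    ts <- expand_design(design, group)
    if (is.null(basis))
      basis <- build_basis(design$catalog, include_configural = uses_configural(params))
  }
  state <- if (is.null(initial_state)) init_state(basis) else initial_state
  nstep <- nrow(ts$x)
  nf <- nrow(basis)
  F <- featurize(ts$x, basis)
  yhat <- err <- numeric(nstep)
  W <- N <- ETA <- matrix(NA_real_, nstep, nf, dimnames = list(NULL, basis$id))
  A <- LAM <- NULL
  if (params$variant == "compact") A <- W
  if (params$variant %in% c("familiarity", "compact")) LAM <- W
  for (i in seq_len(nstep)) {
    out <- step_core(state, F[i, ], ts$y[i], params)
    state <- out$state
    yhat[i] <- out$record$yhat
    err[i] <- out$record$error
    W[i, ] <- state$w; N[i, ] <- state$n; ETA[i, ] <- state$eta
    if (!is.null(A) && !is.null(out$record$a)) A[i, ] <- out$record$a
    if (!is.null(LAM) && !is.null(out$record$lambda_i)) LAM[i, ] <- out$record$lambda_i
  }
  structure(list(info = ts$info, y = ts$y, yhat = yhat, error = err,
                 W = W, N = N, ETA = ETA, A = A, LAMBDA = LAM,
                 basis = basis, params = params, final_state = state),
            class = "rw_trajectory")
}

#' @export
print.rw_trajectory <- function(x, ...) {
  cat("<rw_trajectory> ", length(x$yhat), " steps, variant ",
      x$params$variant, "\n  final w: ", sep = "")
  cat(paste(names(x$final_state$w), round(x$final_state$w, 3), sep = "="),
      sep = ", ")
  cat("\n")
  invisible(x)
}

#' Long-format trajectory export
#'
#' One row per step and feature, suitable for CSV export and plotting.
#'
#' @param x An `rw_trajectory`.
#' @param ... Unused.
#' @return Data frame with columns `step`, `stage`, `is_trial`, `y`,
#'   `y_hat`, `feature`, `w`, `n`, `eta`, `a`, `lambda_i`.
#' @export
as.data.frame.rw_trajectory <- function(x, ...) {
  nf <- nrow(x$basis); ns <- length(x$yhat)
  data.frame(
    step = rep(x$info$step, each = nf),
    stage = rep(x$info$stage, each = nf),
    is_trial = rep(as.integer(x$info$type == "trial"), each = nf),
    y = rep(x$y, each = nf),
    y_hat = rep(x$yhat, each = nf),
    feature = rep(x$basis$id, ns),
    w = as.vector(t(x$W)),
    n = as.vector(t(x$N)),
    eta = as.vector(t(x$ETA)),
    a = if (is.null(x$A)) NA_real_ else as.vector(t(x$A)),
    lambda_i = if (is.null(x$LAMBDA)) NA_real_ else as.vector(t(x$LAMBDA)),
    stringsAsFactors = FALSE)
}

#' Write a trajectory to CSV
#' @param traj An `rw_trajectory`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
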