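#' Training configuration for iterative classifiers
#'
#' @param max_iterations iteration cap shared by all trainers (default
#'   200).
#' @param learning_rate,momentum full-batch gradient-descent parameters;
#'   the gradient is averaged over training rows.
#' @param sigma0 scaled-conjugate-gradient finite-difference step scale.
#' @param lambda0 initial scale (Levenberg-Marquardt style regularizer) of
#'   the scaled conjugate gradient.
#' @param weight_decay L2 penalty coefficient added to the cross-entropy
#'   error (0 disables it).
#' @param rng_seed seed for weight initialization.
#' @param tol_error,tol_param convergence tolerances on the error decrease
#'   and parameter change.
#' @return A `train_config` list.
#' @export
train_config <- function(max_iterations = 200L, learning_rate = 0.1,
                         momentum = 0, sigma0 = 1e-4, lambda0 = 1e-6,
                         weight_decay = 0, rng_seed = 1L,
                         tol_error = 1e-8, tol_param = 1e-8) {
  if (max_iterations < 1L) config_error("max_iterations must be >= 1")
  structure(list(max_iterations = as.integer(max_iterations),
                 learning_rate = learning_rate, momentum = momentum,
                 sigma0 = sigma0, lambda0 = lambda0,
                 weight_decay = weight_decay,
                 rng_seed = as.integer(rng_seed),
                 tol_error = tol_error, tol_param = tol_param),
            class = "train_config")
}

## Scaled conjugate gradient (Moller 1993): conjugate directions with an
## adaptively scaled Levenberg-Marquardt term, no line search. `fn`/`gr`
## take and return the flat parameter vector. Returns accepted-error trace
## (non-increasing) and the iteration count (never above the cap).
scg_optimize <- function(w, fn, gr, config = train_config()) {
  sigma0 <- config$sigma0
  lambda <- config$lambda0
  lambda_min <- 1e-15; lambda_max <- 1e100
  f_old <- fn(w)
  if (!is.finite(f_old)) numeric_error("non-finite error at the initial point")
  grad_new <- gr(w)
  grad_old <- grad_new
  d <- -grad_new
  success <- TRUE
  n_success <- 0L
  trace <- f_old
  mu <- 0; kappa <- 0; theta <- 0
  iterations <- 0L
  for (j in seq_len(config$max_iterations)) {
    iterations <- j
    if (success) {
      mu <- sum(d * grad_new)
      if (mu >= 0) {
        d <- -grad_new
        mu <- sum(d * grad_new)
      }
      kappa <- sum(d * d)
      if (kappa < .Machine$double.eps) break
      sigma <- sigma0 / sqrt(kappa)
      g_plus <- gr(w + sigma * d)
      theta <- sum(d * (g_plus - grad_new)) / sigma
    }
    delta <- theta + lambda * kappa
    if (delta <= 0) {
      delta <- lambda * kappa
      lambda <- lambda - theta / kappa
    }
    alpha <- -mu / delta
    w_new <- w + alpha * d
    f_new <- fn(w_new)
    if (!is.finite(f_new)) numeric_error("non-finite error during scg training")
    comparison <- 2 * delta * (f_old - f_new) / mu^2   # Moller's Delta
    if (comparison >= 0) {
      success <- TRUE
      n_success <- n_success + 1L
      param_change <- sqrt(sum((alpha * d)^2))
      error_change <- f_old - f_new
      w <- w_new
      trace <- c(trace, f_new)
      f_old <- f_new
      grad_old <- grad_new
      grad_new <- gr(w)
      if (param_change < config$tol_param && error_change < config$tol_error)
        break
      if (sum(grad_new^2) == 0) break
    } else {
      success <- FALSE
    }
    if (comparison < 0.25) lambda <- min(4 * lambda, lambda_max)
    if (comparison > 0.75) lambda <- max(lambda / 2, lambda_min)
    if (n_success == length(w)) {      # restart with steepest descent
      d <- -grad_new
      n_success <- 0L
    } else if (success) {
      gamma <- sum((grad_old - grad_new) * grad_new) / mu
      d <- gamma * d - grad_new
    }
  }
  list(w = w, value = f_old, trace = trace, iterations = iterations)
}

## Full-batch gradient descent with optional momentum; the gradient is
## divided by n_rows so the learning rate is per-sample.
gd_optimize <- function(w, fn, gr, n_rows, config = train_config()) {
  v <- numeric(length(w))
  f_prev <- fn(w)
  trace <- f_prev
  iterations <- 0L
  for (j in seq_len(config$max_iterations)) {
    iterations <- j
    g <- gr(w) / n_rows
    v <- config$momentum * v - config$learning_rate * g
    w <- w + v
    f <- fn(w)
    if (!is.finite(f)) numeric_error("non-finite error during gradient-descent training")
    trace <- c(trace, f)
    converged <- abs(f_prev - f) < config$tol_error &&
      sqrt(sum(v^2)) < config$tol_param
    f_prev <- f
    if (converged) break
  }
  list(w = w, value = f_prev, trace = trace, iterations = iterations)
}
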