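## The four model/trainer combinations compared by the toolkit: pooled-
## covariance LDA; softmax/logistic GLM trained by IRLS or scaled conjugate
## gradient; MLP trained by full-batch gradient descent or scaled conjugate
## gradient. All error functions are cross-entropies matched to the output
## function (multinomial for softmax, sum of Bernoulli terms for logistic),
## summed over training rows, plus an optional L2 penalty.

#' Fit a pooled-covariance linear discriminant classifier
#'
#' Classic LDA: per-class means, a covariance matrix pooled over classes,
#' and linear discriminant scores
#' `x' S^-1 m_c - m_c' S^-1 m_c / 2 + log pi_c`. The pooled covariance is
#' regularized by adding `reg * trace(S)/p` to the diagonal to guard
#' against singular fits on degenerate data.
#'
#' @param x numeric feature matrix `[n x p]`.
#' @param class_index integer class labels (any coding; levels are taken
#'   from `sort(unique(class_index))`).
#' @param priors prior class probabilities (defaults to the empirical
#'   class frequencies); must sum to 1.
#' @param reg relative diagonal regularization of the pooled covariance.
#' @return An `emg_lda` model with fields `class_means`,
#'   `pooled_covariance`, `priors`, `class_levels`.
#' @export
fit_lda <- function(x, class_index, priors = NULL, reg = 1e-8) {
  x <- as.matrix(x)
  levels <- sort(unique(class_index))
  if (length(levels) < 2L) config_error("need at least 2 classes")
  counts <- vapply(levels, function(l) sum(class_index == l), integer(1L))
  if (any(counts < 2L)) config_error("every class needs at least 2 samples")
  p <- ncol(x)
  means <- t(vapply(levels, function(l)
    colMeans(x[class_index == l, , drop = FALSE]), numeric(p)))
  pooled <- matrix(0, p, p)
  for (i in seq_along(levels)) {
    xc <- sweep(x[class_index == levels[i], , drop = FALSE], 2L, means[i, ])
    pooled <- pooled + crossprod(xc)
  }
  pooled <- pooled / (nrow(x) - length(levels))
  pooled <- (pooled + t(pooled)) / 2
  diag(pooled) <- diag(pooled) + reg * sum(diag(pooled)) / p
  if (is.null(priors)) priors <- counts / sum(counts)
  if (abs(sum(priors) - 1) > 1e-8) config_error("priors must sum to 1")
  sinv <- tryCatch(solve(pooled), error = function(e)
    numeric_error("pooled covariance is singular after regularization"))
  structure(list(class_means = means, pooled_covariance = pooled,
                 priors = priors, class_levels = levels, sinv = sinv),
            class = "emg_lda")
}

#' Linear discriminant scores
#'
#' @param object an [fit_lda()] model.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return Score matrix `[n x n_classes]`; the row argmax is the
#'   predicted class (see `class_levels`).
#' @export
predict.emg_lda <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  l <- object$class_means %*% object$sinv          # [C x p]
  offs <- -0.5 * rowSums(l * object$class_means) + log(object$priors)
  scores <- x %*% t(l)
  sweep(scores, 2L, offs, "+")
}

## ---- GLM --------------------------------------------------------------

glm_forward <- function(z, w, output_function) {
  a <- z %*% w
  y <- if (output_function == "softmax") softmax_rows(a) else sigmoid(a)
  list(a = a, y = y)
}

glm_objective <- function(z, targets, output_function, decay) {
  ce <- if (output_function == "softmax") cross_entropy_softmax
        else cross_entropy_logistic
  p <- ncol(z); m <- ncol(targets)
  list(
    fn = function(wv) {
      w <- matrix(wv, p, m)
      ce(z %*% w, targets) + 0.5 * decay * sum(w^2)
    },
    gr = function(wv) {
      w <- matrix(wv, p, m)
      fwd <- glm_forward(z, w, output_function)
      as.vector(crossprod(z, fwd$y - targets) + decay * w)
    })
}

#' Train a generalized linear classifier
#'
#' A single-layer network with a bias unit and a softmax (multinomial) or
#' logistic (independent Bernoulli) output, trained by iteratively
#' reweighted least squares (Fisher scoring with a step-halving safeguard
#' so the training cross-entropy never increases) or by scaled conjugate
#' gradient. The two trainers optimize the same convex objective and reach
#' the same optimum.
#'
#' @param x feature matrix `[n x p]`.
#' @param targets 0/1 target matrix (one-hot rows for softmax; any binary
#'   rows for logistic), see [encode_targets()].
#' @param algorithm `"irls"` or `"scg"`.
#' @param output_function `"softmax"` or `"logistic"`.
#' @param config a [train_config()].
#' @return An `emg_glm` model with the `(p+1) x n_outputs` weight matrix
#'   (bias row first), the output function, trainer provenance, the
#'   accepted-error trace and the final training cross-entropy.
#' @export
train_glm <- function(x, targets, algorithm = c("irls", "scg"),
                      output_function = c("softmax", "logistic"),
                      config = train_config()) {
  algorithm <- match.arg(algorithm)
  output_function <- match.arg(output_function)
  x <- as.matrix(x); targets <- as.matrix(targets)
  if (output_function == "softmax" &&
      any(abs(rowSums(targets) - 1) > 1e-8))
    config_error("softmax output requires one-hot target rows")
  z <- cbind(1, x)
  p <- ncol(z); m <- ncol(targets)
  obj <- glm_objective(z, targets, output_function, config$weight_decay)
  w0 <- numeric(p * m)
  res <- if (algorithm == "scg") scg_optimize(w0, obj$fn, obj$gr, config)
         else glm_irls(z, targets, output_function, obj$fn, config)
  w <- matrix(res$w, p, m)
  if (!all(is.finite(w))) numeric_error("diverging GLM weights")
  structure(list(weights = w, output_function = output_function,
                 trainer = algorithm, error_trace = res$trace,
                 final_error = res$value, iterations = res$iterations),
            class = "emg_glm")
}

## IRLS / Fisher scoring: Newton steps on the cross-entropy, safeguarded
## by halving the step until the total error does not increase. For the
## logistic output the outputs are independent and the per-output weighted
## least squares (working weights y(1-y)) is the exact Newton step; for
## softmax the full multinomial Fisher information (blocks
## Z' diag(y_j (delta_jj' - y_j')) Z) is assembled and solved, giving the
## usual quadratic convergence to the unique optimum of the convex
## objective.
glm_irls <- function(z, targets, output_function, fn, config) {
  p <- ncol(z); m <- ncol(targets)
  w <- matrix(0, p, m)
  decay <- config$weight_decay
  err <- fn(as.vector(w))
  trace <- err
  iterations <- 0L
  for (it in seq_len(config$max_iterations)) {
    iterations <- it
    fwd <- glm_forward(z, w, output_function)
    w_new <- w
    if (output_function == "logistic") {
      for (j in seq_len(m)) {
        wt <- pmax(fwd$y[, j] * (1 - fwd$y[, j]), 1e-10)
        gj <- crossprod(z, fwd$y[, j] - targets[, j]) + decay * w[, j]
        h <- crossprod(z * wt, z)
        diag(h) <- diag(h) + decay + 1e-10
        step <- tryCatch(solve(h, gj), error = function(e)
          numeric_error("singular IRLS system"))
        w_new[, j] <- w[, j] - step
      }
    } else {
      g <- as.vector(crossprod(z, fwd$y - targets) + decay * w)
      h <- matrix(0, p * m, p * m)
      for (j in seq_len(m)) for (jj in j:m) {
        wt <- if (j == jj) fwd$y[, j] * (1 - fwd$y[, j])
              else -fwd$y[, j] * fwd$y[, jj]
        block <- crossprod(z * wt, z)
        rows <- (j - 1L) * p + seq_len(p)
        cols <- (jj - 1L) * p + seq_len(p)
        h[rows, cols] <- block
        if (j != jj) h[cols, rows] <- t(block)
      }
      diag(h) <- diag(h) + decay + 1e-8 * max(diag(h))
      step <- tryCatch(solve(h, g), error = function(e)
        numeric_error("singular IRLS system"))
      w_new <- w - matrix(step, p, m)
    }
    eta <- 1
    repeat {
      w_try <- w + eta * (w_new - w)
      err_try <- fn(as.vector(w_try))
      if (is.finite(err_try) && err_try <= err + 1e-12) break
      eta <- eta / 2
      if (eta < 1e-4) break
    }
    if (!is.finite(err_try) || err_try > err + 1e-12) break  # no progress
    improvement <- err - err_try
    w <- w_try
    err <- err_try
    trace <- c(trace, err)
    if (improvement < config$tol_error) break
  }
  list(w = as.vector(w), value = err, trace = trace, iterations = iterations)
}

#' GLM outputs
#'
#' @param object an [train_glm()] model.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return Output matrix: softmax rows sum to 1; logistic outputs lie in
#'   (0, 1) elementwise.
#' @export
predict.emg_glm <- function(object, newdata, ...) {
  z <- cbind(1, as.matrix(newdata))
  glm_forward(z, object$weights, object$output_function)$y
}

## ---- MLP --------------------------------------------------------------

mlp_shapes <- function(layer_sizes) {
  ## list of (W, b) dims per connection
  lapply(seq_len(length(layer_sizes) - 1L), function(l)
    list(w = c(layer_sizes[l], layer_sizes[l + 1L]), b = layer_sizes[l + 1L]))
}

mlp_unflatten <- function(wv, shapes) {
  pos <- 0L
  lapply(shapes, function(s) {
    nw <- prod(s$w)
    w <- matrix(wv[pos + seq_len(nw)], s$w[1L], s$w[2L])
    pos <<- pos + nw
    b <- wv[pos + seq_len(s$b)]
    pos <<- pos + s$b
    list(w = w, b = b)
  })
}

mlp_forward <- function(layers, x, output_function) {
  h <- x
  nl <- length(layers)
  acts <- vector("list", nl)
  for (l in seq_len(nl)) {
    a <- sweep(h %*% layers[[l]]$w, 2L, layers[[l]]$b, "+")
    if (l < nl) {
      h <- sigmoid(a)                  # logistic hidden activation
      acts[[l]] <- h
    } else {
      acts[[l]] <- a                   # output pre-activation
    }
  }
  y <- if (output_function == "softmax") softmax_rows(acts[[nl]])
       else sigmoid(acts[[nl]])
  list(acts = acts, a_out = acts[[nl]], y = y)
}

## error + gradient of the flat parameter vector (backpropagation)
mlp_objective <- function(x, targets, layer_sizes, output_function, decay) {
  shapes <- mlp_shapes(layer_sizes)
  ce <- if (output_function == "softmax") cross_entropy_softmax
        else cross_entropy_logistic
  list(
    fn = function(wv) {
      layers <- mlp_unflatten(wv, shapes)
      fwd <- mlp_forward(layers, x, output_function)
      ce(fwd$a_out, targets) + 0.5 * decay * sum(wv^2)
    },
    gr = function(wv) {
      layers <- mlp_unflatten(wv, shapes)
      fwd <- mlp_forward(layers, x, output_function)
      nl <- length(layers)
      grads <- vector("list", nl)
      delta <- fwd$y - targets         # canonical-link output delta
      for (l in rev(seq_len(nl))) {
        h_in <- if (l == 1L) x else fwd$acts[[l - 1L]]
        grads[[l]] <- list(w = crossprod(h_in, delta) + decay * layers[[l]]$w,
                           b = colSums(delta) + decay * layers[[l]]$b)
        if (l > 1L) {
          h <- fwd$acts[[l - 1L]]
          delta <- (delta %*% t(layers[[l]]$w)) * h * (1 - h)
        }
      }
      unlist(lapply(grads, function(g) c(as.vector(g$w), g$b)))
    })
}

#' Train a feed-forward multi-layer perceptron
#'
#' Logistic hidden units (one or two hidden layers) and a softmax or
#' logistic output layer, trained full-batch either by backpropagation
#' with gradient descent or by scaled conjugate gradient, both capped at
#' `config$max_iterations` (default 200). Weights are initialized
#' reproducibly from `config$rng_seed` with scale `1/sqrt(fan_in)`.
#'
#' @param x feature matrix `[n x p]`.
#' @param targets 0/1 target matrix, see [encode_targets()].
#' @param hidden hidden layer sizes (length 1 or 2).
#' @param trainer `"scg"` or `"gradient_descent"`.
#' @param output_function `"softmax"` or `"logistic"`.
#' @param config a [train_config()].
#' @return An `emg_mlp` model with `layer_sizes`, the per-layer weights
#'   and biases, output function, trainer provenance, accepted-error
#'   trace, final training cross-entropy and iteration count.
#' @export
train_mlp <- function(x, targets, hidden = 32L,
                      trainer = c("scg", "gradient_descent"),
                      output_function = c("softmax", "logistic"),
                      config = train_config()) {
  trainer <- match.arg(trainer)
  output_function <- match.arg(output_function)
  x <- as.matrix(x); targets <- as.matrix(targets)
  if (!length(hidden) %in% 1:2)
    config_error("hidden must give 1 or 2 hidden layer sizes")
  layer_sizes <- c(ncol(x), as.integer(hidden), ncol(targets))
  shapes <- mlp_shapes(layer_sizes)
  w0 <- withr::with_seed(config$rng_seed, {
    unlist(lapply(shapes, function(s)
      c(rnorm(prod(s$w), sd = 1 / sqrt(s$w[1L])), numeric(s$b))))
  })
  obj <- mlp_objective(x, targets, layer_sizes, output_function,
                       config$weight_decay)
  res <- if (trainer == "scg") scg_optimize(w0, obj$fn, obj$gr, config)
         else gd_optimize(w0, obj$fn, obj$gr, nrow(x), config)
  layers <- mlp_unflatten(res$w, shapes)
  if (!all(vapply(layers, function(l) all(is.finite(l$w), is.finite(l$b)),
                  logical(1L))))
    numeric_error("non-finite MLP parameters after training")
  structure(list(layer_sizes = layer_sizes, layers = layers,
                 hidden_activation = "logistic",
                 output_function = output_function, trainer = trainer,
                 error_trace = res$trace, final_error = res$value,
                 iterations = res$iterations),
            class = "emg_mlp")
}

#' MLP outputs
#'
#' @param object an [train_mlp()] model.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return Output matrix (softmax rows sum to 1; logistic outputs in
#'   (0, 1)).
#' @export
predict.emg_mlp <- function(object, newdata, ...) {
  mlp_forward(object$layers, as.matrix(newdata), object$output_function)$y
}

#' @export
print.emg_lda <- function(x, ...) {
  cat(sprintf("<emg_lda> %d classes, %d features\n",
              length(x$class_levels), ncol(x$class_means)))
  invisible(x)
}

#' @export
print.emg_glm <- function(x, ...) {
  cat(sprintf("<emg_glm> %s output, trained by %s (%d iterations, final CE %.4g)\n",
              x$output_function, x$trainer, x$iterations, x$final_error))
  invisible(x)
}

#' @export
print.emg_mlp <- function(x, ...) {
  cat(sprintf("<emg_mlp> layers %s, %s output, trained by %s (%d iterations, final CE %.4g)\n",
              paste(x$layer_sizes, collapse = "-"), x$output_function,
              x$trainer, x$iterations, x$final_error))
  invisible(x)
}
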