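test_that("LDA matches the closed-form discriminant for two Gaussians", {
  withr::with_seed(10, {
    n <- 200; p <- 5
    x0 <- matrix(rnorm(n * p), ncol = p)
    x1 <- matrix(rnorm(n * p), ncol = p) + rep(c(1.5, -1, 0.5, 0, 2), each = n)
    x <- rbind(x0, x1); y <- rep(0:1, each = n)
  })
  model <- fit_lda(x, y)
  ## closed form from the sample moments, computed independently
  mu0 <- colMeans(x0); mu1 <- colMeans(x1)
  s <- (crossprod(sweep(x0, 2, mu0)) + crossprod(sweep(x1, 2, mu1))) / (2 * n - 2)
  w_closed <- solve(s, mu1 - mu0)
  ## the model's boundary normal is the difference of discriminant
  ## coefficient vectors
  l <- model$class_means %*% model$sinv
  w_model <- l[2, ] - l[1, ]
  expect_lt(max(abs(w_model - w_closed)) / max(abs(w_closed)), 1e-6)
  ## pooled covariance symmetric, priors sum to 1
  expect_lt(max(abs(model$pooled_covariance - t(model$pooled_covariance))), 1e-10)
  expect_equal(sum(model$priors), 1)
})

test_that("LDA agrees with an independent reference implementation", {
  withr::with_seed(11, {
    x <- matrix(rnorm(300 * 4), ncol = 4) +
      rep(c(0, 1.2, -1.2), each = 100) %o% c(1, 0.5, -0.5, 0.2)
    y <- rep(0:2, each = 100)
    xt <- matrix(rnorm(150 * 4), ncol = 4)
  })
  model <- fit_lda(x, y)
  pred <- model$class_levels[decode_single(predict(model, xt)) + 1L]
  ref <- MASS::lda(x, grouping = y)
  pred_ref <- as.integer(as.character(predict(ref, xt)$class))
  ## identical up to the tiny diagonal regularization at the boundary
  expect_gte(mean(pred == pred_ref), 0.99)
})

test_that("LDA on identical class means performs at chance", {
  withr::with_seed(12, {
    x <- matrix(rnorm(400 * 6), ncol = 6)
    y <- rep(0:3, each = 100)
    model <- fit_lda(x, y, priors = rep(0.25, 4))
    xt <- matrix(rnorm(1200 * 6), ncol = 6)
    yt <- sample(0:3, 1200, replace = TRUE)
  })
  acc <- mean(model$class_levels[decode_single(predict(model, xt)) + 1L] == yt)
  expect_lt(abs(acc - 0.25), 3 * sqrt(0.25 * 0.75 / 1200))
})

test_that("softmax GLM outputs sum to one and logistic outputs stay in (0,1)", {
  withr::with_seed(13, {
    x <- matrix(rnorm(60 * 3), ncol = 3)
    y <- sample(0:2, 60, replace = TRUE)
  })
  lt <- data.frame(class_index = 0:2, name = c("a", "b", "c"))
  t1 <- encode_targets(y, "single", lt)
  g <- train_glm(x, t1, "irls", "softmax")
  out <- predict(g, x)
  expect_lt(max(abs(rowSums(out) - 1)), 1e-12)
  g2 <- train_glm(x, (t1[, 1:2] > 0) * 1, "scg", "logistic")
  out2 <- predict(g2, x)
  expect_true(all(out2 > 0 & out2 < 1))
})

test_that("intercept-only GLM recovers the class frequencies", {
  withr::with_seed(14, {
    y <- sample(0:2, 500, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  })
  lt <- data.frame(class_index = 0:2, name = c("a", "b", "c"))
  targets <- encode_targets(y, "single", lt)
  g <- train_glm(matrix(0, 500, 0), targets, "irls", "softmax")
  probs <- predict(g, matrix(0, 1, 0))[1, ]
  freq <- as.vector(table(factor(y, 0:2))) / 500
  expect_equal(unname(probs), freq, tolerance = 1e-4)
})

test_that("IRLS error trace is non-increasing (step-halving safeguard)", {
  withr::with_seed(15, {
    x <- matrix(rnorm(80 * 4), ncol = 4)
    y <- (x[, 1] + 0.5 * x[, 2] + rnorm(80, sd = 0.5) > 0) * 1L
  })
  lt <- data.frame(class_index = 0:1, name = c("a", "b"))
  g <- train_glm(x, encode_targets(y, "single", lt), "irls", "softmax",
                 config = train_config(weight_decay = 0.01))
  expect_true(all(diff(g$error_trace) <= 1e-10))
})

test_that("backprop gradient matches central finite differences", {
  withr::with_seed(16, {
    x <- matrix(rnorm(12 * 3), ncol = 3)
    t_soft <- diag(2)[sample(1:2, 12, replace = TRUE), ]
    for (outfun in c("softmax", "logistic")) {
      obj <- emgpr:::mlp_objective(x, t_soft, c(3L, 4L, 2L), outfun,
                                   decay = 0.01)
      w <- rnorm(3 * 4 + 4 + 4 * 2 + 2, sd = 0.5)
      g <- obj$gr(w)
      eps <- 1e-5
      g_fd <- vapply(seq_along(w), function(j) {
        e <- numeric(length(w)); e[j] <- eps
        (obj$fn(w + e) - obj$fn(w - e)) / (2 * eps)
      }, numeric(1))
      expect_lt(max(abs(g - g_fd)) / max(abs(g)), 1e-6)
    }
  })
})

test_that("scg solves XOR with a 2-4-1 logistic net (best of 10 seeds)", {
  withr::with_seed(17, {
    x <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
    x <- x[rep(1:4, each = 10), ] + matrix(rnorm(80, sd = 0.02), ncol = 2)
    tt <- matrix(rep(c(0, 1, 1, 0), each = 10), ncol = 1)
  })
  best <- 0
  for (seed in 1:10) {
    net <- train_mlp(x, tt, hidden = 4L, trainer = "scg",
                     output_function = "logistic",
                     config = train_config(rng_seed = seed))
    acc <- mean((predict(net, x) > 0.5) == tt)
    best <- max(best, acc)
    if (best == 1) break
  }
  expect_equal(best, 1)
})

test_that("training respects the 200-iteration cap and is seed-reproducible", {
  fm <- tiny_fm()
  idx <- which(fm$class_index %in% 0:3)
  x <- fm$values[idx, ]; y <- fm$class_index[idx]
  lt <- fm$labels
  targets <- encode_targets(y, "single", lt)[, 1:27]
  norm <- fit_normalization(x, "zscore")
  xn <- apply_normalization(x, norm)
  for (tr in c("scg", "gradient_descent")) {
    net <- train_mlp(xn, targets, hidden = 8L, trainer = tr,
                     output_function = "softmax",
                     config = train_config(rng_seed = 3L))
    expect_lte(net$iterations, 200L)
    net2 <- train_mlp(xn, targets, hidden = 8L, trainer = tr,
                      output_function = "softmax",
                      config = train_config(rng_seed = 3L))
    expect_identical(net$layers, net2$layers)
  }
  ## scg accepted-error trace is non-increasing
  net <- train_mlp(xn, targets, hidden = 8L, trainer = "scg",
                   output_function = "softmax",
                   config = train_config(rng_seed = 4L))
  expect_true(all(diff(net$error_trace) <= 1e-10))
})

test_that("per-DoF ensembles have 4 outputs per DoF and handle rest-only data", {
  fm <- tiny_fm()
  norm <- fit_normalization(fm$values, "zscore")
  xn <- apply_normalization(fm$values, norm)
  ens <- fit_per_dof_ensemble(xn, fm$class_index, fm$labels, base = "lda")
  expect_length(ens$models, 3)
  out <- predict(ens, xn[1:5, ])
  expect_equal(ncol(out), 12)
  for (m in ens$models) expect_equal(nrow(m$class_means), 4)
  ## degenerate: only rest windows -> constant rest prediction
  rest_rows <- fm$class_index == 0L
  ens0 <- fit_per_dof_ensemble(xn[rest_rows, ], fm$class_index[rest_rows],
                               fm$labels, base = "lda")
  pred <- decode_per_dof(predict(ens0, xn[1:10, ]), fm$labels)
  expect_true(all(pred == 0L))
})

test_that("model serialization round-trips predictions exactly", {
  fm <- tiny_fm()
  ec <- tiny_eval_config()
  sp <- emgpr:::make_splits(fm$class_index, ec)
  tr <- sp$splits[[1]]$train
  norm <- fit_normalization(fm$values[tr, ], "zscore")
  xtr <- apply_normalization(fm$values[tr, ], norm)
  xte <- apply_normalization(fm$values[-tr, ], norm)
  for (m in list(parse_method("lda"),
                 parse_method("glm-irls", output_type = "multiple"),
                 parse_method("mlp-scg", hidden = 8L))) {
    fit <- emgpr:::fit_method(m, xtr, fm$class_index[tr], fm$labels)
    f <- withr::local_tempfile(fileext = ".json")
    write_model(fit, f, normalization = norm)
    fit2 <- read_model(f)
    expect_equal(classify(fit2, xte), classify(fit, xte))
    expect_equal(attr(fit2, "normalization")$location,
                 unname(norm$location), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})
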