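#' Evaluation configuration
#'
#' Repeated stratified random splits: per movement class,
#' `train_per_movement` windows are drawn for training and
#' `test_per_movement` for testing (disjoint), the normalization is
#' fitted on the training partition only, the model is trained and
#' scored, and the whole procedure repeats `n_repetitions` times with
#' fresh splits. Defaults follow common practice for this protocol
#' (72/49 windows, 100 repetitions, alpha 0.05).
#'
#' @param n_repetitions number of random splits.
#' @param train_per_movement training windows drawn per movement class.
#' @param test_per_movement test windows per movement class; `NULL` means
#'   all remaining windows.
#' @param normalization `"zscore"` or `"midrange0range2"`.
#' @param alpha significance level for paired comparisons.
#' @param rng_seed master seed; splits and model initializations derive
#'   from it, so equal seeds give identical results.
#' @return An `eval_config` list.
#' @export
eval_config <- function(n_repetitions = 100L, train_per_movement = 72L,
                        test_per_movement = 49L,
                        normalization = c("zscore", "midrange0range2"),
                        alpha = 0.05, rng_seed = 1L) {
  if (alpha <= 0 || alpha >= 1) config_error("alpha must be in (0, 1)")
  if (n_repetitions < 1L) config_error("n_repetitions must be >= 1")
  structure(list(n_repetitions = as.integer(n_repetitions),
                 train_per_movement = as.integer(train_per_movement),
                 test_per_movement =
                   if (is.null(test_per_movement)) NULL
                   else as.integer(test_per_movement),
                 normalization = match.arg(normalization),
                 alpha = alpha, rng_seed = as.integer(rng_seed)),
            class = "eval_config")
}

## Pre-generate the stratified splits for all repetitions from the master
## seed. Depending only on the feature labels and the config, the split
## sequence is shared between methods evaluated under the same config
## (common random numbers), so paired differences reflect the method.
make_splits <- function(class_index, config) {
  classes <- sort(unique(class_index))
  counts <- vapply(classes, function(cl) sum(class_index == cl), integer(1L))
  n_test <- config$test_per_movement %||% (min(counts) - config$train_per_movement)
  if (config$train_per_movement + n_test > min(counts))
    config_error(sprintf(
      "insufficient windows: %d train + %d test requested, smallest class has %d",
      config$train_per_movement, n_test, min(counts)))
  if (n_test < 1L) config_error("no test windows left after the training draw")
  withr::with_seed(config$rng_seed, {
    model_seeds <- sample.int(.Machine$integer.max - 1L, config$n_repetitions)
    splits <- lapply(seq_len(config$n_repetitions), function(r) {
      train <- integer(0); test <- integer(0)
      for (cl in classes) {
        idx <- which(class_index == cl)
        pick <- sample(idx, config$train_per_movement + n_test)
        train <- c(train, pick[seq_len(config$train_per_movement)])
        test <- c(test, pick[config$train_per_movement + seq_len(n_test)])
      }
      list(train = train, test = test)
    })
    list(splits = splits, model_seeds = model_seeds, n_test = n_test)
  })
}

#' Repeated stratified-split evaluation of one method
#'
#' @param features a [feature_matrix()].
#' @param method a [method_spec()] or shorthand string (see
#'   [parse_method()]).
#' @param config an [eval_config()].
#' @return An `emg_eval` with the per-repetition accuracy vector, mean
#'   accuracy `acc`, its standard deviation `sd` over repetitions, the
#'   summed confusion matrix, and mean training time per repetition in
#'   seconds (informational).
#' @export
repeated_split_evaluate <- function(features, method, config = eval_config()) {
  spec <- parse_method(method)
  sp <- make_splits(features$class_index, config)
  n_rep <- config$n_repetitions
  n_class <- nrow(features$labels)
  accuracies <- numeric(n_rep)
  confusion <- matrix(0L, n_class, n_class,
                      dimnames = list(true = features$labels$name,
                                      predicted = features$labels$name))
  t_train <- 0
  for (r in seq_len(n_rep)) {
    tr <- sp$splits[[r]]$train
    te <- sp$splits[[r]]$test
    norm <- fit_normalization(features$values[tr, , drop = FALSE],
                              config$normalization)
    xtr <- apply_normalization(features$values[tr, , drop = FALSE], norm)
    xte <- apply_normalization(features$values[te, , drop = FALSE], norm)
    spec_r <- spec
    spec_r$train$rng_seed <- sp$model_seeds[r]
    t0 <- proc.time()[["elapsed"]]
    fit <- fit_method(spec_r, xtr, features$class_index[tr], features$labels)
    t_train <- t_train + (proc.time()[["elapsed"]] - t0)
    pred <- classify(fit, xte)
    truth <- features$class_index[te]
    accuracies[r] <- mean(pred == truth)
    ti <- match(truth, features$labels$class_index)
    pi <- match(pred, features$labels$class_index)
    for (j in seq_along(ti))
      confusion[ti[j], pi[j]] <- confusion[ti[j], pi[j]] + 1L
  }
  structure(list(method = spec, accuracies = accuracies,
                 acc = mean(accuracies), sd = sd(accuracies),
                 confusion = confusion, n_test = sp$n_test,
                 train_time = t_train / n_rep, config = config),
            class = "emg_eval")
}

#' @export
print.emg_eval <- function(x, ...) {
  cat(sprintf("<emg_eval> %s-%s (%s output): Acc %.3f, SD %.3f over %d repetitions\n",
              x$method$method, x$method$trainer, x$method$output_type,
              x$acc, if (is.na(x$sd)) 0 else x$sd, length(x$accuracies)))
  invisible(x)
}

#' Wilcoxon signed-rank test for paired accuracies
#'
#' Two-sided paired test. Zero differences are dropped; with no remaining
#' differences the test returns p = 1 with `no_evidence = TRUE`. For up to
#' 25 tie-free differences the exact signed-rank null distribution is
#' used; otherwise a normal approximation with tie correction and
#' continuity correction.
#'
#' @param a,b equal-length paired accuracy vectors.
#' @param alpha significance level reported alongside the decision.
#' @return List with `p_value`, `statistic` (V, the positive-rank sum),
#'   `direction` (+1 if `a` tends larger, -1 if `b`, 0 if balanced),
#'   `significant`, `no_evidence`, `method` (`"exact"` or `"normal"`).
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4, 5, 6, 7), c(1, 1, 1, 1, 1, 1))$p_value
#' # 0.03125
#' @export
wilcoxon_signed_rank <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) config_error("paired vectors must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(p_value = 1, statistic = NA_real_, direction = 0,
                significant = FALSE, no_evidence = TRUE, method = "none"))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- any(duplicated(abs(d)))
  if (n <= 25L && !ties) {
    p_low <- psignrank(v, n)                 # P(V <= v)
    p_high <- psignrank(v - 1, n, lower.tail = FALSE)  # P(V >= v)
    p <- min(1, 2 * min(p_low, p_high))
    method <- "exact"
  } else {
    tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(p_value = p, statistic = v, direction = sign(v - mu),
       significant = p < alpha, no_evidence = FALSE, method = method)
}

#' Hidden-unit sweep for the scg-trained MLP
#'
#' Trains `nets_per_hu` networks per candidate hidden-layer size, each on
#' a fresh stratified split, and applies the stopping rule: find the
#' best-scoring size, then select the smallest size whose accuracies are
#' not significantly worse than the best's under a paired Wilcoxon
#' signed-rank test at `config$alpha`. Splits are shared across sizes
#' (common random numbers) so comparisons are paired.
#'
#' @param features a [feature_matrix()].
#' @param output_type `"single"` or `"multiple"`.
#' @param hidden_range candidate hidden-unit counts.
#' @param nets_per_hu networks trained per count.
#' @param config an [eval_config()]; `n_repetitions` is overridden by
#'   `nets_per_hu`.
#' @param train a [train_config()] for the individual networks.
#' @return A `sweep_result` with the accuracy matrix
#'   `[nets_per_hu x n_sizes]`, mean accuracy per size, the selected
#'   size, and the p-value of each size against the best.
#' @export
hidden_unit_sweep <- function(features, output_type = "single",
                              hidden_range = 1:100, nets_per_hu = 10L,
                              config = eval_config(), train = train_config()) {
  if (!length(hidden_range)) config_error("hidden_range must be non-empty")
  config$n_repetitions <- as.integer(nets_per_hu)
  accs <- matrix(NA_real_, nets_per_hu, length(hidden_range),
                 dimnames = list(NULL, as.character(hidden_range)))
  for (i in seq_along(hidden_range)) {
    spec <- method_spec("mlp", "scg", output_type = output_type,
                        hidden = hidden_range[i], train = train)
    accs[, i] <- repeated_split_evaluate(features, spec, config)$accuracies
  }
  mean_acc <- colMeans(accs)
  best <- which.max(mean_acc)
  p_vs_best <- vapply(seq_along(hidden_range), function(i) {
    if (i == best) return(1)
    wilcoxon_signed_rank(accs[, i], accs[, best])$p_value
  }, numeric(1L))
  ## significantly worse than best: significant AND lower mean
  worse <- p_vs_best < config$alpha & mean_acc < mean_acc[best]
  selected <- hidden_range[min(which(!worse))]
  structure(list(hidden_range = hidden_range, accuracies = accs,
                 mean_acc = mean_acc, selected = selected,
                 best = hidden_range[best], p_vs_best = p_vs_best,
                 nets_per_hu = nets_per_hu, alpha = config$alpha),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> hidden units %s; best %d, selected %d\n",
              paste(range(x$hidden_range), collapse = "-"), x$best, x$selected))
  invisible(x)
}

#' Compare several methods on one feature matrix
#'
#' Evaluates each method with [repeated_split_evaluate()] under the same
#' configuration, so all methods see the same split sequence and the
#' per-repetition accuracies are paired. Reports mean accuracy, SD,
#' training time, and the matrix of pairwise two-sided Wilcoxon
#' signed-rank p-values.
#'
#' @param features a [feature_matrix()].
#' @param methods character vector of shorthand names (see
#'   [parse_method()]) or a list of [method_spec()]s; names are used as
#'   row labels.
#' @param config an [eval_config()].
#' @param output_type output type applied to shorthand names.
#' @return An `emg_comparison`: `table` (data.frame with method, output
#'   type, acc, sd, train time), `p_values` (pairwise matrix), `results`
#'   (the individual `emg_eval`s).
#' @export
compare_methods <- function(features,
                            methods = c("lda", "glm-irls", "glm-scg",
                                        "mlp-gd", "mlp-scg"),
                            config = eval_config(),
                            output_type = "single") {
  if (is.character(methods))
    methods <- setNames(lapply(methods, parse_method,
                               output_type = output_type), methods)
  if (is.null(names(methods)))
    names(methods) <- vapply(methods, function(s)
      paste0(s$method, if (s$trainer != "none") paste0("-", s$trainer)),
      character(1L))
  results <- lapply(methods, function(spec)
    repeated_split_evaluate(features, spec, config))
  tab <- data.frame(
    method = names(methods),
    output_type = vapply(methods, `[[`, character(1L), "output_type"),
    acc = vapply(results, `[[`, numeric(1L), "acc"),
    sd = vapply(results, `[[`, numeric(1L), "sd"),
    train_time_s = vapply(results, `[[`, numeric(1L), "train_time"),
    row.names = NULL)
  m <- length(methods)
  p_values <- matrix(NA_real_, m, m,
                     dimnames = list(names(methods), names(methods)))
  if (m > 1L && config$n_repetitions >= 2L)
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      p <- wilcoxon_signed_rank(results[[i]]$accuracies,
                                results[[j]]$accuracies,
                                alpha = config$alpha)$p_value
      p_values[i, j] <- p_values[j, i] <- p
    }
  structure(list(table = tab, p_values = p_values, results = results,
                 config = config),
            class = "emg_comparison")
}

#' @export
print.emg_comparison <- function(x, ...) {
  cat("<emg_comparison>\n")
  tab <- x$table
  tab$acc <- sprintf("%.3f", tab$acc)
  tab$sd <- sprintf("%.3f", tab$sd)
  tab$train_time_s <- sprintf("%.2f", tab$train_time_s)
  print(tab, row.names = FALSE)
  invisible(x)
}
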