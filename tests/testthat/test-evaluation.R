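test_that("stratified splits use exact per-class counts and are disjoint", {
  fm <- tiny_fm()
  cfg <- eval_config(n_repetitions = 5, train_per_movement = 12,
                     test_per_movement = 8, rng_seed = 9)
  sp <- emgpr:::make_splits(fm$class_index, cfg)
  for (s in sp$splits) {
    expect_length(intersect(s$train, s$test), 0)
    for (cl in unique(fm$class_index)) {
      expect_equal(sum(fm$class_index[s$train] == cl), 12)
      expect_equal(sum(fm$class_index[s$test] == cl), 8)
    }
  }
  ## too greedy a split is refused
  expect_error(
    emgpr:::make_splits(fm$class_index,
                        eval_config(train_per_movement = 20,
                                    test_per_movement = 10)),
    class = "emgpr_config_error")
})

test_that("a perfectly separable task evaluates to Acc 1, SD 0", {
  fm <- separable_fm()
  res <- repeated_split_evaluate(fm, "lda",
                                 eval_config(n_repetitions = 4,
                                             train_per_movement = 15,
                                             test_per_movement = 10,
                                             rng_seed = 2))
  expect_equal(res$acc, 1)
  expect_equal(res$sd, 0)
  expect_equal(sum(res$confusion), 4 * 10 * 4)
  expect_equal(sum(diag(res$confusion)), sum(res$confusion))
})

test_that("label-randomized features score at chance level", {
  withr::with_seed(30, {
    lt <- enumerate_labels(3)
    cls <- rep(lt$class_index, each = 40)
    x <- matrix(rnorm(length(cls) * 8), ncol = 8)
    fm <- feature_matrix(x, cls, lt)
  })
  res <- repeated_split_evaluate(fm, "lda",
                                 eval_config(n_repetitions = 2,
                                             train_per_movement = 25,
                                             test_per_movement = 15,
                                             rng_seed = 3))
  n_cls <- 27
  se <- sqrt((1 / n_cls) * (1 - 1 / n_cls) / (15 * n_cls * 2))
  expect_lt(abs(res$acc - 1 / n_cls), 3 * se)
})

test_that("evaluation is deterministic given the seed", {
  fm <- tiny_fm()
  cfg <- tiny_eval_config(n_rep = 3, seed = 77)
  r1 <- repeated_split_evaluate(fm, "glm-irls", cfg)
  r2 <- repeated_split_evaluate(fm, "glm-irls", cfg)
  expect_identical(r1$accuracies, r2$accuracies)
  expect_identical(r1$confusion, r2$confusion)
})

test_that("Wilcoxon signed-rank handles the canonical cases", {
  ## identical vectors: no evidence, p = 1
  w <- wilcoxon_signed_rank(1:6, 1:6)
  expect_equal(w$p_value, 1)
  expect_true(w$no_evidence)
  ## n = 6 all-positive distinct differences: exact p = 2/64
  w2 <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6, 7), rep(1, 6))
  expect_equal(w2$p_value, 2 / 64)
  expect_equal(w2$direction, 1)
  expect_true(w2$significant)
  expect_identical(w2$method, "exact")
})

test_that("exact Wilcoxon path agrees with brute-force enumeration", {
  withr::with_seed(31, {
    for (n in 5:12) {
      for (rep in 1:3) {
        a <- rnorm(n)
        b <- rnorm(n)
        while (any(duplicated(abs(a - b))) || any(a == b)) b <- rnorm(n)
        ours <- wilcoxon_signed_rank(a, b)
        expect_equal(ours$p_value, wilcoxon_enum_oracle(a, b),
                     info = sprintf("n = %d", n))
        ## and with the reference implementation
        expect_equal(ours$p_value,
                     stats::wilcox.test(a, b, paired = TRUE,
                                        exact = TRUE)$p.value)
      }
    }
  })
})

test_that("tied or long samples fall back to a sane normal approximation", {
  a <- c(1, 2, 3, 4, 5, 6, 7, 8)
  b <- c(2, 1, 4, 3, 7, 5, 5, 6)   # tied |differences|
  w <- wilcoxon_signed_rank(a, b)
  expect_identical(w$method, "normal")
  expect_true(w$p_value > 0 && w$p_value <= 1)
  withr::with_seed(32, {
    a <- rnorm(40, mean = 0.5); b <- rnorm(40)
    w2 <- wilcoxon_signed_rank(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, correct = TRUE)$p.value
    expect_equal(w2$p_value, ref, tolerance = 0.05)
    expect_equal(w2$direction, 1)
  })
})

test_that("hidden-unit sweep selects the smallest sufficient size", {
  ## trivially separable task: accuracy saturates at every size
  fm <- separable_fm(n_classes = 2, per_class = 24, noise = 0.05)
  cfg <- eval_config(train_per_movement = 14, test_per_movement = 10,
                     rng_seed = 4)
  sw <- hidden_unit_sweep(fm, hidden_range = c(1L, 2L, 4L),
                          nets_per_hu = 10L, config = cfg,
                          train = train_config(max_iterations = 100))
  expect_equal(dim(sw$accuracies), c(10, 3))   # 10 nets per size recorded
  expect_equal(sw$selected, 1L)
  ## XOR-style task: one hidden unit is not enough
  fmx <- xor_fm()
  cfgx <- eval_config(train_per_movement = 40, test_per_movement = 20,
                      rng_seed = 5)
  swx <- hidden_unit_sweep(fmx, hidden_range = c(1L, 4L, 8L),
                           nets_per_hu = 10L, config = cfgx,
                           train = train_config(max_iterations = 150))
  expect_gt(swx$selected, 1L)
})

test_that("method comparison pairs accuracies under shared splits", {
  fm <- tiny_fm()
  cfg <- tiny_eval_config(n_rep = 3, seed = 6)
  cmp <- compare_methods(fm, c("lda", "glm-irls"), cfg)
  expect_equal(nrow(cmp$table), 2)
  expect_equal(cmp$p_values["lda", "glm-irls"],
               wilcoxon_signed_rank(cmp$results$lda$accuracies,
                                    cmp$results$`glm-irls`$accuracies)$p_value)
  ## a single method yields a one-row table and no p-values
  cmp1 <- compare_methods(fm, "lda", cfg)
  expect_equal(nrow(cmp1$table), 1)
  expect_true(all(is.na(cmp1$p_values)))
  ## shared split sequence: re-evaluating a method alone reproduces its
  ## accuracy vector exactly
  solo <- repeated_split_evaluate(fm, "lda", cfg)
  expect_identical(solo$accuracies, cmp$results$lda$accuracies)
})
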