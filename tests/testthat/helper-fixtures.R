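## Shared fixtures, built in code at load time (no stored binaries).

## A small, fast session: full 27-label structure but short recordings.
tiny_synth_config <- function(seed = 7L, snr = 10, ...) {
  synth_config(sampling_rate = 500, contraction_time = 1,
               n_repetitions = 2L, band = c(20, 200), snr = snr,
               rng_seed = seed, ...)
}

tiny_session <- function(seed = 7L, snr = 10, ...) {
  generate_session(tiny_synth_config(seed, snr, ...))
}

## cached once per test run: 22 windows per movement, 32 features
tiny_fm <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- extract_features(tiny_session())
    cache
  }
})

tiny_eval_config <- function(n_rep = 3L, seed = 5L, ...) {
  eval_config(n_repetitions = n_rep, train_per_movement = 12L,
              test_per_movement = NULL, rng_seed = seed, ...)
}

## "desk-scale" session: the standard protocol (3 x 3 s repetitions,
## 8 channels, 200 ms / 50 ms windows -> 117 windows per movement) at a
## 1 kHz sampling rate.
desk_synth_config <- function(seed = 1L, snr = 3) {
  synth_config(sampling_rate = 1000, snr = snr, rng_seed = seed)
}

## brute-force window-count oracle: place windows until they no longer fit
count_windows_oracle <- function(L, w, i) {
  count <- 0L; s <- 1L
  while (s + w - 1L <= L) { count <- count + 1L; s <- s + i }
  count
}

## brute-force time-domain feature oracle (explicit loops)
td_oracle <- function(x, zc_thr = 0, ssc_thr = 0) {
  n <- length(x)
  mav <- sum(abs(x)) / n
  wl <- 0; zc <- 0; ssc <- 0
  for (k in seq_len(n - 1L)) {
    wl <- wl + abs(x[k + 1L] - x[k])
    if (x[k] * x[k + 1L] < 0 && abs(x[k + 1L] - x[k]) > zc_thr) zc <- zc + 1L
  }
  for (k in 2:(n - 1L)) {
    d1 <- x[k] - x[k - 1L]; d2 <- x[k] - x[k + 1L]
    if (d1 * d2 > 0 && abs(d1) > ssc_thr && abs(d2) > ssc_thr) ssc <- ssc + 1L
  }
  c(mav = mav, wl = wl, zc = zc, ssc = ssc)
}

## exhaustive-enumeration Wilcoxon signed-rank oracle (two-sided)
wilcoxon_enum_oracle <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  vs <- apply(signs, 1L, function(s) sum(r[s]))
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}

## a linearly separable toy feature matrix with arbitrary class count
separable_fm <- function(n_classes = 4L, per_class = 30L, noise = 0.05,
                         seed = 42L) {
  labels <- data.frame(class_index = seq_len(n_classes) - 1L,
                       name = paste0("c", seq_len(n_classes) - 1L))
  withr::with_seed(seed, {
    cls <- rep(labels$class_index, each = per_class)
    x <- matrix(rnorm(length(cls) * n_classes, sd = noise),
                ncol = n_classes)
    x[cbind(seq_along(cls), cls + 1L)] <-
      x[cbind(seq_along(cls), cls + 1L)] + 1
    feature_matrix(x, cls, labels)
  })
}

## XOR-style task: not linearly separable, solvable with >= 2 hidden units
xor_fm <- function(per_cluster = 30L, noise = 0.15, seed = 11L) {
  labels <- data.frame(class_index = 0:1, name = c("a", "b"))
  withr::with_seed(seed, {
    centers <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
    cls <- rep(c(0L, 0L, 1L, 1L), each = per_cluster)
    x <- centers[rep(1:4, each = per_cluster), ] +
      matrix(rnorm(8L * per_cluster, sd = noise), ncol = 2L)
    feature_matrix(x, cls, labels)
  })
}
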