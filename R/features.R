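#' Sliding-window specification
#'
#' Defaults follow the usual myoelectric-control analysis settings: 200 ms
#' windows advanced by 50 ms, after removing the first and last 15 % of
#' each repetition so that only the isotonic part of the contraction
#' remains.
#'
#' @param window_length window length in seconds.
#' @param increment window increment (hop) in seconds; `0 < increment <=
#'   window_length`.
#' @param trim_fraction fraction of each repetition removed at both ends,
#'   in `[0, 0.5)`.
#' @return A `window_spec` list.
#' @export
window_spec <- function(window_length = 0.2, increment = 0.05,
                        trim_fraction = 0.15) {
  if (window_length <= 0) config_error("window_length must be positive")
  if (increment <= 0 || increment > window_length)
    config_error("increment must satisfy 0 < increment <= window_length")
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    config_error("trim_fraction must be in [0, 0.5)")
  structure(list(window_length = window_length, increment = increment,
                 trim_fraction = trim_fraction), class = "window_spec")
}

#' Trim the ends of a repetition
#'
#' Removes the first and last `trim_fraction` of the samples (boundaries
#' rounded down), keeping the central portion of the contraction.
#'
#' @param x numeric vector, or matrix with time along rows.
#' @param trim_fraction fraction removed at each end, in `[0, 0.5)`.
#' @return The trimmed vector/matrix.
#' @examples
#' length(trim_recording(rnorm(1000), 0.15))  # 700
#' @export
trim_recording <- function(x, trim_fraction = 0.15) {
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    config_error("trim_fraction must be in [0, 0.5)")
  n <- if (is.matrix(x)) nrow(x) else length(x)
  cut <- floor(trim_fraction * n)
  keep <- (cut + 1L):(n - cut)
  if (length(keep) < 1L)
    config_error("trimming removed all samples")
  if (is.matrix(x)) x[keep, , drop = FALSE] else x[keep]
}

## number of windows in a contiguous segment of L samples
n_windows <- function(L, w, i) {
  if (L < w) 0L else as.integer(floor((L - w) / i) + 1L)
}

#' Slice fixed sliding windows from a contiguous segment
#'
#' Windows are half-open sample intervals `[start, start + w)` and never
#' span segment (repetition) boundaries; slice each repetition separately.
#' The window count is `floor((L - w) / i) + 1` for a segment of `L`
#' samples with window `w` and increment `i` samples.
#'
#' @param x numeric matrix `[time x channels]` (a vector is treated as one
#'   channel).
#' @param spec a [window_spec()].
#' @param sampling_rate sampling frequency in Hz.
#' @return Array `[window_samples x channels x n_windows]`.
#' @export
slice_windows <- function(x, spec = window_spec(), sampling_rate) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  w <- round(spec$window_length * sampling_rate)
  i <- round(spec$increment * sampling_rate)
  if (w < 1L || i < 1L)
    config_error("window and increment must be at least one sample long")
  L <- nrow(x)
  if (L < w)
    config_error(sprintf("segment of %d samples is shorter than the %d-sample window",
                         L, w))
  nw <- n_windows(L, w, i)
  starts <- (seq_len(nw) - 1L) * i + 1L
  out <- array(NA_real_, c(w, ncol(x), nw))
  for (k in seq_len(nw))
    out[, , k] <- x[starts[k]:(starts[k] + w - 1L), , drop = FALSE]
  out
}

#' Time-domain EMG features of one window
#'
#' The four classic time-domain features per channel:
#' mean absolute value (MAV), waveform length (WL, the summed absolute
#' sample-to-sample difference), zero crossings (ZC, sign changes between
#' consecutive samples whose amplitude step exceeds `zc_threshold`), and
#' slope sign changes (SSC, interior samples where the slope changes sign
#' with both adjacent steps exceeding `ssc_threshold`). Thresholds default
#' to 0 (no deadband); small positive deadbands are common in acquisition
#' software and can be set here.
#'
#' @param window numeric vector (one channel) or matrix
#'   `[samples x channels]`; at least 3 samples.
#' @param zc_threshold amplitude deadband for ZC.
#' @param ssc_threshold amplitude deadband for SSC.
#' @return For a vector, the named numeric `c(mav, wl, zc, ssc)`; for a
#'   matrix, the channel-major concatenation (4 values per channel).
#' @examples
#' extract_td_features(c(1, -1, 1, -1))  # mav 1, wl 6, zc 3, ssc 2
#' @export
extract_td_features <- function(window, zc_threshold = 0, ssc_threshold = 0) {
  if (is.matrix(window)) {
    vals <- lapply(seq_len(ncol(window)), function(ch)
      extract_td_features(window[, ch], zc_threshold, ssc_threshold))
    out <- unlist(vals)
    names(out) <- as.vector(outer(c("mav", "wl", "zc", "ssc"),
                                  seq_len(ncol(window)),
                                  function(f, ch) sprintf("ch%d_%s", ch, f)))
    return(out)
  }
  n <- length(window)
  if (n < 3L) data_error("window must contain at least 3 samples")
  d <- diff(window)
  mav <- mean(abs(window))
  wl <- sum(abs(d))
  sign_change <- window[-n] * window[-1L] < 0
  zc <- sum(sign_change & abs(d) > zc_threshold)
  d1 <- d[-length(d)]          # step into the interior point
  d2 <- d[-1L]                 # step out of it
  ssc <- sum(d1 * d2 < 0 & abs(d1) > ssc_threshold & abs(d2) > ssc_threshold)
  c(mav = mav, wl = wl, zc = as.numeric(zc), ssc = as.numeric(ssc))
}

## Fast path: all windows of one multi-channel segment at once, via
## cumulative sums of per-sample contributions. Agrees with the per-window
## extract_td_features() (property-tested).
td_features_segment <- function(x, w, i, zc_threshold = 0, ssc_threshold = 0) {
  L <- nrow(x); nc <- ncol(x)
  nw <- n_windows(L, w, i)
  starts <- (seq_len(nw) - 1L) * i + 1L
  out <- matrix(NA_real_, nw, 4L * nc)
  for (ch in seq_len(nc)) {
    v <- x[, ch]
    d <- diff(v)
    ca <- c(0, cumsum(abs(v)))
    cd <- c(0, cumsum(abs(d)))
    zci <- c(0, cumsum((v[-L] * v[-1L] < 0) & (abs(d) > zc_threshold)))
    d1 <- d[-(L - 1L)]; d2 <- d[-1L]
    ssci <- c(0, cumsum(d1 * d2 < 0 & abs(d1) > ssc_threshold &
                          abs(d2) > ssc_threshold))
    mav <- (ca[starts + w] - ca[starts]) / w
    wl <- cd[starts + w - 1L] - cd[starts]
    zc <- zci[starts + w - 1L] - zci[starts]
    ssc <- ssci[starts + w - 2L] - ssci[starts]
    out[, (ch - 1L) * 4L + 1:4] <- cbind(mav, wl, zc, ssc)
  }
  colnames(out) <- as.vector(outer(c("mav", "wl", "zc", "ssc"), seq_len(nc),
                                   function(f, ch) sprintf("ch%d_%s", ch, f)))
  out
}

#' Windowed feature matrix of a whole session
#'
#' Trims each repetition, slices sliding windows (never spanning a
#' repetition boundary), and extracts the four time-domain features per
#' channel, yielding `channels x 4` feature columns per window.
#'
#' @param session a [recording_session()].
#' @param spec a [window_spec()].
#' @param zc_threshold,ssc_threshold deadbands, see
#'   [extract_td_features()].
#' @return A `feature_matrix` object: list with `values`
#'   (`n_windows x features`), `class_index` (0-based movement class per
#'   window, in session movement order), `labels` (label table, see
#'   [enumerate_labels()]), `feature_names` and `subject_id`.
#' @export
extract_features <- function(session, spec = window_spec(),
                             zc_threshold = 0, ssc_threshold = 0) {
  validate_session(session)
  fs <- session$sampling_rate
  w <- round(spec$window_length * fs)
  i <- round(spec$increment * fs)
  ranges <- repetition_ranges(session)
  n_mov <- length(session$movement_names)
  vals <- vector("list", n_mov)
  for (m in seq_len(n_mov)) {
    x <- session$samples[, , m, drop = FALSE]
    dim(x) <- dim(session$samples)[1:2]
    segs <- lapply(ranges, function(idx) {
      seg <- trim_recording(x[idx, , drop = FALSE], spec$trim_fraction)
      if (nrow(seg) < w)
        config_error("trimmed repetition is shorter than one window")
      td_features_segment(seg, w, i, zc_threshold, ssc_threshold)
    })
    vals[[m]] <- do.call(rbind, segs)
  }
  values <- do.call(rbind, vals)
  class_index <- rep(seq_len(n_mov) - 1L, vapply(vals, nrow, integer(1L)))
  if (!all(is.finite(values))) data_error("non-finite feature values")
  k <- round(log(n_mov, 3))
  labels <- if (3^k == n_mov) {
    lt <- enumerate_labels(k)
    lt$name <- session$movement_names
    lt
  } else {
    data.frame(class_index = seq_len(n_mov) - 1L,
               name = session$movement_names)
  }
  feature_matrix(values, class_index, labels, session$subject_id)
}

#' Construct a feature matrix object
#'
#' Usually produced by [extract_features()]; the constructor is exported so
#' that feature data from other sources (or simulations) can enter the
#' evaluation machinery.
#'
#' @param values numeric matrix `[n_windows x n_features]`.
#' @param class_index integer vector of 0-based class indices per row.
#' @param labels label table (see [enumerate_labels()]); minimally columns
#'   `class_index` and `name`.
#' @param subject_id opaque identifier.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(values, class_index, labels, subject_id = "unknown") {
  values <- as.matrix(values)
  if (nrow(values) != length(class_index))
    structural_error("one class index per feature row required")
  if (!all(class_index %in% labels$class_index))
    data_error("class_index values outside the label table")
  structure(list(values = values,
                 class_index = as.integer(class_index),
                 labels = labels,
                 feature_names = colnames(values),
                 subject_id = subject_id),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d windows x %d features, %d classes (subject '%s')\n",
              nrow(x$values), ncol(x$values), nrow(x$labels), x$subject_id))
  invisible(x)
}

#' Fit a column normalization on training features
#'
#' Two linear normalizations: `"zscore"` (column mean 0, sample SD 1) and
#' `"midrange0range2"` (column minimum mapped to -1, maximum to +1).
#' Parameters should be fitted on the training partition only and then
#' applied unchanged to the test partition, so no test information leaks
#' into training.
#'
#' @param x numeric matrix with at least 2 rows.
#' @param kind `"zscore"` or `"midrange0range2"`.
#' @return A `normalization_spec` with per-column `location` and `scale`.
#'   Degenerate (zero-spread) columns get scale 1 with a warning.
#' @export
fit_normalization <- function(x, kind = c("zscore", "midrange0range2")) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  if (nrow(x) < 2L) config_error("need at least 2 rows to fit a normalization")
  if (kind == "zscore") {
    location <- colMeans(x)
    scale <- apply(x, 2L, sd)
  } else {
    lo <- apply(x, 2L, min); hi <- apply(x, 2L, max)
    location <- (lo + hi) / 2
    scale <- (hi - lo) / 2
  }
  degenerate <- !is.finite(scale) | scale <= 0
  if (any(degenerate)) {
    warning(sprintf("%d zero-spread column(s); scale set to 1", sum(degenerate)))
    scale[degenerate] <- 1
  }
  structure(list(kind = kind, location = location, scale = scale),
            class = "normalization_spec")
}

#' Apply a fitted normalization
#'
#' @param x numeric matrix with the same columns the spec was fitted on.
#' @param spec a [fit_normalization()] result.
#' @return The transformed matrix.
#' @export
apply_normalization <- function(x, spec) {
  x <- as.matrix(x)
  if (ncol(x) != length(spec$location))
    structural_error("column count differs from the fitted normalization")
  sweep(sweep(x, 2L, spec$location, "-"), 2L, spec$scale, "/")
}
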