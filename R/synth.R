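#' Default activation matrix for the synthetic EMG generator
#'
#' Six rows (one per individual movement: hand open/close, hand
#' flex/extend, wrist pronation/supination), eight columns (channels of a
#' circular forearm electrode array). Each movement dominates 2-3
#' channels with partially overlapping supports, and the agonist and
#' antagonist of each degree of freedom load different channels, the way
#' antagonist muscle groups sit on different sides of the forearm.
#'
#' @return A 6 x 8 matrix with entries in `[0, 1]`.
#' @export
default_activation_matrix <- function() {
  a <- rbind(
    c(1.0, 0.7, 0.2, 0.0, 0.0, 0.0, 0.0, 0.3),  # hand open
    c(0.2, 0.3, 1.0, 0.8, 0.0, 0.0, 0.0, 0.0),  # hand close
    c(0.0, 0.2, 0.3, 1.0, 0.7, 0.0, 0.0, 0.0),  # hand flex
    c(0.0, 0.0, 0.0, 0.2, 0.3, 1.0, 0.8, 0.0),  # hand extend
    c(0.0, 0.0, 0.3, 0.0, 0.7, 0.9, 0.2, 0.0),  # pronation
    c(0.7, 0.0, 0.0, 0.0, 0.0, 0.2, 0.3, 1.0))  # supination
  rownames(a) <- c("hand_open", "hand_close", "hand_flex", "hand_extend",
                   "pronation", "supination")
  a
}

#' Configuration of the synthetic EMG generator
#'
#' The generator emulates a surface-EMG recording protocol: a fixed
#' number of repetitions of a sustained contraction per movement, all 27
#' labels of 3 degrees of freedom (6 individual movements, their
#' simultaneous combinations, and rest). Each channel carries
#' band-limited Gaussian noise whose amplitude is raised on the channels
#' a movement activates:
#' `signal = (1 + activation * sqrt(snr)) * bandpass(white noise)`,
#' so `snr` is the power ratio contributed by a fully active channel
#' relative to baseline; `snr = 0` makes all movements statistically
#' identical and large `snr` makes them separable by construction.
#'
#' @param channel_count number of electrode channels.
#' @param sampling_rate Hz.
#' @param contraction_time seconds per repetition.
#' @param n_repetitions repetitions per movement.
#' @param activation_matrix `[6 x channels]` per-movement channel
#'   activations in `[0, 1]`; see [default_activation_matrix()].
#' @param combination `"max"` (co-contraction saturates; default) or
#'   `"sum"` (clipped at 1) for simultaneous movements.
#' @param band band-pass edges in Hz for the noise carrier.
#' @param filter_order Butterworth order of the (zero-phase) band-pass.
#' @param snr activation-to-baseline power ratio (>= 0).
#' @param rng_seed seed; the session is fully reproducible from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(channel_count = 8L, sampling_rate = 2000,
                         contraction_time = 3, n_repetitions = 3L,
                         activation_matrix = default_activation_matrix(),
                         combination = c("max", "sum"),
                         band = c(20, 450), filter_order = 4L,
                         snr = 10, rng_seed = 1L) {
  combination <- match.arg(combination)
  if (snr < 0) config_error("snr must be >= 0")
  if (any(activation_matrix < 0 | activation_matrix > 1))
    config_error("activation_matrix entries must lie in [0, 1]")
  if (ncol(activation_matrix) != channel_count)
    config_error("activation_matrix must have one column per channel")
  if (nrow(activation_matrix) != 6L)
    config_error("activation_matrix must have 6 rows (individual movements)")
  if (band[2L] >= sampling_rate / 2)
    config_error("band upper edge must be below the Nyquist frequency")
  structure(list(channel_count = as.integer(channel_count),
                 sampling_rate = sampling_rate,
                 contraction_time = contraction_time,
                 n_repetitions = as.integer(n_repetitions),
                 activation_matrix = activation_matrix,
                 combination = combination, band = band,
                 filter_order = as.integer(filter_order),
                 snr = snr, rng_seed = as.integer(rng_seed)),
            class = "synth_config")
}

#' Generate a synthetic EMG recording session
#'
#' For each of the 27 movement labels, every channel's signal is
#' band-limited Gaussian noise scaled by `1 + a * sqrt(snr)`, where `a`
#' is the channel activation of that label: 0 for rest, the activation
#' row for an individual movement, and the row-wise `max` (or clipped
#' sum) of the active movements' rows for simultaneous movements.
#' Movements appear in the canonical label order of
#' [enumerate_labels()], so the session is ready for the downstream
#' coding schemes.
#'
#' @param config a [synth_config()].
#' @return A [recording_session()].
#' @examples
#' s <- generate_session(synth_config(sampling_rate = 500,
#'                                    contraction_time = 1,
#'                                    n_repetitions = 2))
#' s
#' @export
generate_session <- function(config = synth_config()) {
  labels <- enumerate_labels(3L)
  states <- label_states(labels)
  n_mov <- nrow(labels)
  n_t <- round(config$sampling_rate * config$contraction_time *
                 config$n_repetitions)
  bf <- signal::butter(config$filter_order,
                       config$band / (config$sampling_rate / 2),
                       type = "pass")
  gains <- t(vapply(seq_len(n_mov), function(m) {
    act <- movement_activation(states[m, ], config)
    1 + act * sqrt(config$snr)
  }, numeric(config$channel_count)))
  samples <- withr::with_seed(config$rng_seed, {
    out <- array(NA_real_, c(n_t, config$channel_count, n_mov))
    for (m in seq_len(n_mov)) for (ch in seq_len(config$channel_count)) {
      noise <- signal::filtfilt(bf, rnorm(n_t))
      out[, ch, m] <- gains[m, ch] * noise
    }
    out
  })
  recording_session(samples,
                    sampling_rate = config$sampling_rate,
                    contraction_time = config$contraction_time,
                    n_repetitions = config$n_repetitions,
                    movement_names = labels$name,
                    subject_id = sprintf("synthetic-seed%d", config$rng_seed))
}

## channel activation vector of one label state (length = channels)
movement_activation <- function(state, config) {
  act <- numeric(config$channel_count)
  rows <- integer(0)
  for (d in seq_along(state)) {
    if (state[d] > 0L) rows <- c(rows, 2L * d - 1L)
    if (state[d] < 0L) rows <- c(rows, 2L * d)
  }
  if (length(rows)) {
    block <- config$activation_matrix[rows, , drop = FALSE]
    act <- if (config$combination == "max") apply(block, 2L, max)
           else pmin(colSums(block), 1)
  }
  act
}
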