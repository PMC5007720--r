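#' EMG recording session container
#'
#' Holds a multi-channel surface-EMG recording: one concatenated block of
#' repetitions per movement, with sampling and timing metadata. The order of
#' `movement_names` is the canonical class order used by every downstream
#' step (feature labels, target encodings, report rows).
#'
#' @param samples numeric array `[time x channels x movements]`; repetitions
#'   of each movement are concatenated along the time axis.
#' @param sampling_rate sampling frequency in Hz (positive).
#' @param contraction_time duration of one repetition in seconds.
#' @param n_repetitions number of repetitions per movement.
#' @param movement_names character vector naming the movements, in class
#'   order (individual, combined, rest).
#' @param subject_id opaque subject identifier.
#' @param rep_boundaries integer vector of first-sample indices of each
#'   repetition (1-based). Defaults to an equal split of the time axis into
#'   `n_repetitions` blocks.
#' @return An object of class `recording_session`.
#' @examples
#' s <- recording_session(array(rnorm(400 * 2 * 3), c(400, 2, 3)),
#'                        sampling_rate = 100, contraction_time = 2,
#'                        n_repetitions = 2,
#'                        movement_names = c("a", "b", "rest"))
#' s
#' @export
recording_session <- function(samples, sampling_rate, contraction_time,
                              n_repetitions, movement_names,
                              subject_id = "unknown",
                              rep_boundaries = NULL) {
  if (length(dim(samples)) != 3L)
    structural_error("samples must be a 3-d array [time x channels x movements]")
  n_time <- dim(samples)[1L]
  if (is.null(rep_boundaries)) {
    per_rep <- n_time %/% n_repetitions
    rep_boundaries <- as.integer((seq_len(n_repetitions) - 1L) * per_rep + 1L)
  }
  s <- structure(list(
    samples          = samples,
    sampling_rate    = as.numeric(sampling_rate),
    contraction_time = as.numeric(contraction_time),
    n_repetitions    = as.integer(n_repetitions),
    channel_count    = dim(samples)[2L],
    movement_names   = as.character(movement_names),
    subject_id       = as.character(subject_id),
    rep_boundaries   = as.integer(rep_boundaries)
  ), class = "recording_session")
  validate_session(s)
}

#' Validate a recording session
#'
#' Checks the structural invariants: finite samples, tensor dimensions
#' consistent with the channel count and movement list, and enough samples
#' to hold `n_repetitions` repetitions of `contraction_time` seconds.
#'
#' @param session a [recording_session()].
#' @return The session, invisibly usable, if valid; otherwise an error of
#'   class `emgpr_structural_error` or `emgpr_data_error`.
#' @export
validate_session <- function(session) {
  required <- c("samples", "sampling_rate", "contraction_time",
                "n_repetitions", "channel_count", "movement_names",
                "subject_id", "rep_boundaries")
  for (f in required)
    if (is.null(session[[f]]))
      structural_error(sprintf("session is missing required field '%s'", f))
  d <- dim(session$samples)
  if (length(d) != 3L)
    structural_error("samples must be a 3-d array [time x channels x movements]")
  if (session$sampling_rate <= 0)
    structural_error("sampling_rate must be positive")
  if (length(session$movement_names) == 0L)
    structural_error("movement_names must be non-empty")
  if (d[2L] != session$channel_count)
    data_error(sprintf("channel dimension (%d) disagrees with channel_count (%d)",
                       d[2L], session$channel_count))
  if (d[3L] != length(session$movement_names))
    data_error(sprintf("movement dimension (%d) disagrees with movement_names (%d)",
                       d[3L], length(session$movement_names)))
  if (!all(is.finite(session$samples)))
    data_error("samples contain non-finite values")
  need <- session$sampling_rate * session$contraction_time * session$n_repetitions
  if (need > d[1L] + 1e-9)
    data_error(sprintf(
      "time axis too short: %d samples < %g s x %d reps at %g Hz",
      d[1L], session$contraction_time, session$n_repetitions,
      session$sampling_rate))
  if (length(session$rep_boundaries) != session$n_repetitions ||
      is.unsorted(session$rep_boundaries) ||
      session$rep_boundaries[1L] < 1L ||
      session$rep_boundaries[session$n_repetitions] > d[1L])
    structural_error("rep_boundaries must be sorted start indices within the time axis")
  session
}

#' @export
print.recording_session <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<recording_session> subject '%s'\n", x$subject_id))
  cat(sprintf("  %d movements x %d channels, %d samples @ %g Hz\n",
              d[3L], d[2L], d[1L], x$sampling_rate))
  cat(sprintf("  %d repetitions of %g s per movement\n",
              x$n_repetitions, x$contraction_time))
  invisible(x)
}

## sample ranges of each repetition (list of index vectors), per movement
repetition_ranges <- function(session) {
  d1 <- dim(session$samples)[1L]
  b <- session$rep_boundaries
  ends <- c(b[-1L] - 1L, d1)
  Map(function(s, e) s:e, b, ends)
}

#' Default field map for MAT session containers
#'
#' Maps session fields to the variable names used inside the MAT-file v5
#' struct. Field names of historical Matlab session structs vary across
#' releases, so the map is configurable rather than hard-coded: pass a
#' modified copy to [read_session()]/[write_session()] to match a
#' particular release.
#'
#' @return Named character vector mapping session fields to struct fields.
#' @export
mat_field_map <- function() {
  c(sampling_rate    = "sF",
    contraction_time = "cT",
    n_repetitions    = "nR",
    channel_count    = "nCh",
    movement_names   = "mvnts",
    samples          = "tdata",
    subject_id       = "sbj",
    rep_boundaries   = "repB")
}

#' Read an EMG recording session
#'
#' Two dialects are supported: `"fixture"`, a portable directory of
#' delimited-text channel files plus a JSON metadata file (bit-exact
#' round-trip, no binary dependency), and `"mat"`, a MAT-file v5 container
#' holding one struct whose fields follow `field_map`.
#'
#' @param path file (mat) or directory (fixture) to read.
#' @param dialect `"fixture"` or `"mat"`.
#' @param field_map for the mat dialect, the struct field naming; see
#'   [mat_field_map()].
#' @param varname for the mat dialect, the struct variable name; if `NULL`
#'   the first struct in the file is used.
#' @return A validated [recording_session()].
#' @export
read_session <- function(path, dialect = c("fixture", "mat"),
                         field_map = mat_field_map(), varname = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "fixture") read_session_fixture(path)
  else read_session_mat(path, field_map, varname)
}

#' Write an EMG recording session
#'
#' @param session a valid [recording_session()].
#' @param path output directory (fixture) or file (mat).
#' @inheritParams read_session
#' @param varname struct variable name for the mat dialect.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, dialect = c("fixture", "mat"),
                          field_map = mat_field_map(),
                          varname = "recSession") {
  dialect <- match.arg(dialect)
  validate_session(session)
  if (dialect == "fixture") write_session_fixture(session, path)
  else write_session_mat(session, path, field_map, varname)
  invisible(path)
}

## ---- fixture dialect --------------------------------------------------

fmt17 <- function(x) sprintf("%.17g", x)

write_session_fixture <- function(session, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  meta <- list(
    format           = "emgpr-session-fixture",
    version          = 1L,
    sampling_rate    = fmt17(session$sampling_rate),
    contraction_time = fmt17(session$contraction_time),
    n_repetitions    = session$n_repetitions,
    channel_count    = session$channel_count,
    movement_names   = session$movement_names,
    subject_id       = session$subject_id,
    rep_boundaries   = session$rep_boundaries,
    n_samples        = dim(session$samples)[1L]
  )
  jsonlite::write_json(meta, file.path(path, "session.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  header <- paste0("ch", seq_len(session$channel_count), collapse = ",")
  for (m in seq_along(session$movement_names)) {
    x <- session$samples[, , m, drop = FALSE]
    dim(x) <- dim(session$samples)[1:2]
    lines <- c(header,
               apply(matrix(fmt17(x), nrow = nrow(x)), 1L, paste, collapse = ","))
    writeLines(lines, file.path(path, sprintf("movement_%03d.csv", m)))
  }
}

read_session_fixture <- function(path) {
  mf <- file.path(path, "session.json")
  if (!file.exists(mf))
    structural_error(sprintf("fixture metadata not found: %s", mf))
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  for (f in c("sampling_rate", "contraction_time", "n_repetitions",
              "channel_count", "movement_names", "n_samples"))
    if (is.null(meta[[f]]))
      structural_error(sprintf("fixture metadata is missing field '%s'", f))
  n_mov <- length(meta$movement_names)
  n_ch <- as.integer(meta$channel_count)
  n_t <- as.integer(meta$n_samples)
  samples <- array(NA_real_, c(n_t, n_ch, n_mov))
  for (m in seq_len(n_mov)) {
    f <- file.path(path, sprintf("movement_%03d.csv", m))
    if (!file.exists(f))
      structural_error(sprintf("fixture channel file not found: %s", f))
    x <- as.matrix(data.table::fread(f))
    if (nrow(x) != n_t || ncol(x) != n_ch)
      data_error(sprintf("%s: expected %d x %d samples, found %d x %d",
                         f, n_t, n_ch, nrow(x), ncol(x)))
    samples[, , m] <- x
  }
  recording_session(samples,
                    sampling_rate    = as.numeric(meta$sampling_rate),
                    contraction_time = as.numeric(meta$contraction_time),
                    n_repetitions    = as.integer(meta$n_repetitions),
                    movement_names   = meta$movement_names,
                    subject_id       = meta$subject_id %||% "unknown",
                    rep_boundaries   = meta$rep_boundaries)
}

## ---- mat dialect ------------------------------------------------------

write_session_mat <- function(session, path, field_map, varname) {
  s <- list()
  s[[field_map[["sampling_rate"]]]]    <- session$sampling_rate
  s[[field_map[["contraction_time"]]]] <- session$contraction_time
  s[[field_map[["n_repetitions"]]]]    <- as.numeric(session$n_repetitions)
  s[[field_map[["channel_count"]]]]    <- as.numeric(session$channel_count)
  s[[field_map[["movement_names"]]]]   <- mat_cellstr(session$movement_names)
  s[[field_map[["samples"]]]]          <- session$samples
  s[[field_map[["subject_id"]]]]       <- session$subject_id
  s[[field_map[["rep_boundaries"]]]]   <- as.numeric(session$rep_boundaries)
  vars <- setNames(list(s), varname)
  write_mat5(vars, path)
}

read_session_mat <- function(path, field_map, varname) {
  if (!file.exists(path))
    structural_error(sprintf("file not found: %s", path))
  vars <- read_mat5(path)
  s <- if (!is.null(varname)) vars[[varname]] else {
    hit <- which(vapply(vars, function(v)
      is.list(v) && !is.null(names(v)), logical(1L)))[1L]
    if (is.na(hit)) structural_error("no session struct found in MAT file")
    vars[[hit]]
  }
  if (is.null(s)) structural_error("requested variable not found in MAT file")
  need <- c("sampling_rate", "contraction_time", "n_repetitions",
            "channel_count", "movement_names", "samples")
  for (f in need)
    if (is.null(s[[field_map[[f]]]]))
      structural_error(sprintf("MAT session struct is missing field '%s' ('%s')",
                               field_map[[f]], f))
  samples <- s[[field_map[["samples"]]]]
  if (length(dim(samples)) == 2L) dim(samples) <- c(dim(samples), 1L)
  rb <- s[[field_map[["rep_boundaries"]]]]
  recording_session(samples,
                    sampling_rate    = as.numeric(s[[field_map[["sampling_rate"]]]]),
                    contraction_time = as.numeric(s[[field_map[["contraction_time"]]]]),
                    n_repetitions    = as.integer(s[[field_map[["n_repetitions"]]]]),
                    movement_names   = unlist(s[[field_map[["movement_names"]]]]),
                    subject_id       = s[[field_map[["subject_id"]]]] %||% "unknown",
                    rep_boundaries   = if (!is.null(rb)) as.integer(rb) else NULL)
}
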