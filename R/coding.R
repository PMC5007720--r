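#' Enumerate movement labels for k degrees of freedom
#'
#' Each degree of freedom (DoF) is in one of three states: +1 (agonist
#' direction), -1 (antagonist direction) or 0 (inactive), giving `3^k`
#' labels; the all-zero state is the rest / no-movement label. With the
#' default 3 DoF (hand open/close, hand flex/extend, wrist
#' pronation/supination) this yields 27 labels: 6 individual movements,
#' 20 simultaneous combinations and rest.
#'
#' The canonical order is mixed-radix with DoF 1 least significant and
#' digit order (0, +1, -1), so class index 0 is rest and the index is a
#' bijection with the state vector.
#'
#' @param n_dof number of degrees of freedom (k).
#' @param movement_names optional length-`2k` character vector naming the
#'   agonist/antagonist direction of each DoF, in DoF order.
#' @return A data.frame label table: `class_index` (0-based), `name`, and
#'   state columns `s1..sk`.
#' @examples
#' nrow(enumerate_labels(3))  # 27
#' @export
enumerate_labels <- function(n_dof = 3L, movement_names = NULL) {
  stopifnot(n_dof >= 1L)
  if (is.null(movement_names)) {
    movement_names <- if (n_dof == 3L)
      c("hand_open", "hand_close", "hand_flex", "hand_extend",
        "pronation", "supination")
    else as.vector(t(outer(seq_len(n_dof), c("pos", "neg"),
                           function(d, s) sprintf("dof%d_%s", d, s))))
  }
  if (length(movement_names) != 2L * n_dof)
    config_error("movement_names must have 2 entries per DoF")
  n <- 3L^n_dof
  digit_state <- c(0L, 1L, -1L)          # digit 0/1/2 -> state 0/+1/-1
  states <- matrix(0L, n, n_dof)
  for (d in seq_len(n_dof)) {
    digits <- (seq_len(n) - 1L) %/% 3L^(d - 1L) %% 3L
    states[, d] <- digit_state[digits + 1L]
  }
  name_of <- function(s) {
    act <- which(s != 0L)
    if (!length(act)) return("rest")
    paste(vapply(act, function(d)
      movement_names[2L * (d - 1L) + if (s[d] > 0L) 1L else 2L],
      character(1L)), collapse = "+")
  }
  data.frame(class_index = seq_len(n) - 1L,
             name = apply(states, 1L, name_of),
             setNames(as.data.frame(states), paste0("s", seq_len(n_dof))),
             stringsAsFactors = FALSE)
}

label_states <- function(labels) {
  scols <- grep("^s[0-9]+$", names(labels), value = TRUE)
  if (!length(scols))
    config_error("label table has no DoF state columns; only the single output scheme is available")
  as.matrix(labels[scols])
}

## state matrix [n x k] -> 0-based class index (mixed radix, digit 0/1/2)
state_to_index <- function(states) {
  states <- rbind(states)
  k <- ncol(states)
  digits <- ifelse(states == 0L, 0L, ifelse(states > 0L, 1L, 2L))
  as.integer(digits %*% 3L^(seq_len(k) - 1L))
}

#' Build classifier target encodings
#'
#' Three schemes: `"single"` — one-hot over all classes (one unit per
#' label, simultaneous combinations included); `"multiple"` — one unit per
#' individual movement (2 per DoF), simultaneous movements activate
#' several units; `"per_dof"` — one block of 4 units per DoF (agonist,
#' antagonist, other movement, rest), as used by per-DoF ensembles of
#' linear classifiers.
#'
#' @param class_index integer vector of 0-based class indices.
#' @param scheme `"single"`, `"multiple"` or `"per_dof"`.
#' @param labels label table from [enumerate_labels()]; needed to resolve
#'   DoF states (schemes other than `"single"`).
#' @return Numeric 0/1 target matrix with one row per element of
#'   `class_index`.
#' @export
encode_targets <- function(class_index, scheme = c("single", "multiple", "per_dof"),
                           labels) {
  scheme <- match.arg(scheme)
  n <- length(class_index)
  row <- match(class_index, labels$class_index)
  if (anyNA(row)) data_error("class_index outside the label table")
  if (scheme == "single") {
    t <- matrix(0, n, nrow(labels))
    t[cbind(seq_len(n), row)] <- 1
    return(t)
  }
  states <- label_states(labels)[row, , drop = FALSE]
  k <- ncol(states)
  if (scheme == "multiple") {
    t <- matrix(0, n, 2L * k)
    for (d in seq_len(k)) {
      t[states[, d] > 0L, 2L * d - 1L] <- 1
      t[states[, d] < 0L, 2L * d] <- 1
    }
    return(t)
  }
  ## per_dof: blocks of (agonist, antagonist, other, rest)
  t <- matrix(0, n, 4L * k)
  cls <- per_dof_classes(states)
  for (d in seq_len(k))
    t[cbind(seq_len(n), 4L * (d - 1L) + cls[, d])] <- 1
  t
}

## per-DoF 4-class membership: 1 agonist, 2 antagonist, 3 other, 4 rest.
## A window counts as "other" for DoF d when d is inactive but some other
## DoF is active; it goes to agonist/antagonist whenever d itself is
## active, regardless of co-active DoF.
per_dof_classes <- function(states) {
  states <- rbind(states)
  k <- ncol(states)
  any_active <- rowSums(states != 0L) > 0L
  out <- matrix(4L, nrow(states), k)
  for (d in seq_len(k)) {
    out[states[, d] > 0L, d] <- 1L
    out[states[, d] < 0L, d] <- 2L
    out[states[, d] == 0L & any_active, d] <- 3L
  }
  out
}

#' Decode single-output activations to class indices
#'
#' Argmax over output units, with a deterministic lowest-index tie-break.
#'
#' @param outputs numeric vector (one window) or matrix
#'   `[n_windows x n_classes]`.
#' @return Integer vector of 0-based class indices.
#' @export
decode_single <- function(outputs) {
  outputs <- rbind(outputs)
  as.integer(apply(outputs, 1L, which.max) - 1L)
}

#' Decode multiple-output (per-movement unit) activations
#'
#' A unit is active when its output exceeds `threshold`; when both units
#' of one DoF are active, the larger output wins; a row with no active
#' unit decodes to rest.
#'
#' @param outputs numeric vector or matrix `[n_windows x 2k]`, units
#'   ordered (agonist, antagonist) per DoF.
#' @param labels label table from [enumerate_labels()].
#' @param threshold activation threshold.
#' @return Integer vector of 0-based class indices.
#' @export
decode_multiple <- function(outputs, labels, threshold = 0.5) {
  outputs <- rbind(outputs)
  k <- ncol(outputs) / 2L
  states <- matrix(0L, nrow(outputs), k)
  for (d in seq_len(k)) {
    ag <- outputs[, 2L * d - 1L]
    an <- outputs[, 2L * d]
    a_on <- ag > threshold
    n_on <- an > threshold
    states[a_on & (!n_on | ag >= an), d] <- 1L
    states[n_on & (!a_on | an > ag), d] <- -1L
  }
  idx <- state_to_index(states)
  if (!all(idx %in% labels$class_index))
    data_error("decoded state outside the label table")
  idx
}

#' Decode per-DoF ensemble outputs
#'
#' Each DoF contributes a block of 4 scores (agonist, antagonist, other,
#' rest); the block argmax maps to the DoF state (+1, -1, 0, 0) and the
#' states combine into a movement label, with all-"other" equivalent to
#' rest.
#'
#' @param outputs numeric vector or matrix `[n_windows x 4k]`.
#' @param labels label table from [enumerate_labels()].
#' @return Integer vector of 0-based class indices.
#' @export
decode_per_dof <- function(outputs, labels) {
  outputs <- rbind(outputs)
  k <- ncol(outputs) / 4L
  state_of <- c(1L, -1L, 0L, 0L)
  states <- matrix(0L, nrow(outputs), k)
  for (d in seq_len(k)) {
    block <- outputs[, 4L * (d - 1L) + 1:4, drop = FALSE]
    states[, d] <- state_of[apply(block, 1L, which.max)]
  }
  idx <- state_to_index(states)
  if (!all(idx %in% labels$class_index))
    data_error("decoded state outside the label table")
  idx
}

#' Export a label table as delimited text
#'
#' @param labels label table from [enumerate_labels()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_label_table <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
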