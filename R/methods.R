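#' Describe a classification method
#'
#' Binds a model family, trainer and output type into a unit the
#' evaluation machinery can fit and score:
#' \itemize{
#'   \item `lda` — single output: one pooled-covariance LDA over all
#'     classes; multiple output: a per-DoF ensemble of 4-class LDAs
#'     (agonist / antagonist / other / rest).
#'   \item `glm` — single output: softmax GLM over all classes; multiple
#'     output: per-DoF ensemble of 4-class softmax GLMs. Trainer `"irls"`
#'     or `"scg"`.
#'   \item `mlp` — single output: one-hot targets over all classes;
#'     multiple output: one logistic unit per individual movement (2 per
#'     DoF), decoded by thresholding. Trainer `"scg"` or
#'     `"gradient_descent"`. The default output function is softmax for
#'     scg-trained single-output nets and logistic otherwise.
#' }
#'
#' Shorthand strings are accepted by the evaluation functions:
#' `"lda"`, `"glm-irls"`, `"glm-scg"`, `"mlp-gd"`, `"mlp-scg"`.
#'
#' @param method `"lda"`, `"glm"` or `"mlp"`.
#' @param trainer `"irls"`/`"scg"` for glm; `"gradient_descent"`/`"scg"`
#'   for mlp; ignored for lda.
#' @param output_type `"single"` or `"multiple"`.
#' @param hidden hidden layer sizes for mlp.
#' @param output_function optional override of the output nonlinearity.
#' @param train a [train_config()].
#' @return A `method_spec` object.
#' @export
method_spec <- function(method = c("lda", "glm", "mlp"), trainer = NULL,
                        output_type = c("single", "multiple"),
                        hidden = 32L, output_function = NULL,
                        train = train_config()) {
  method <- match.arg(method)
  output_type <- match.arg(output_type)
  trainer <- switch(method,
    lda = "none",
    glm = match.arg(trainer %||% "irls", c("irls", "scg")),
    mlp = match.arg(trainer %||% "scg", c("scg", "gradient_descent", "gd")))
  if (identical(trainer, "gd")) trainer <- "gradient_descent"
  if (is.null(output_function))
    output_function <- if (method == "mlp" && output_type == "multiple") "logistic"
      else if (method == "mlp" && trainer == "gradient_descent") "logistic"
      else "softmax"
  structure(list(method = method, trainer = trainer,
                 output_type = output_type, hidden = hidden,
                 output_function = output_function, train = train),
            class = "method_spec")
}

#' Parse a method shorthand string
#'
#' @param x one of `"lda"`, `"glm-irls"`, `"glm-scg"`, `"mlp-gd"`,
#'   `"mlp-scg"` (or a ready [method_spec()]).
#' @param output_type `"single"` or `"multiple"`.
#' @param ... passed on to [method_spec()].
#' @return A [method_spec()].
#' @export
parse_method <- function(x, output_type = "single", ...) {
  if (inherits(x, "method_spec")) return(x)
  known <- c("lda", "glm-irls", "glm-scg", "mlp-gd", "mlp-scg")
  if (!x %in% known)
    config_error(sprintf("unknown method '%s' (known: %s)", x,
                         paste(known, collapse = ", ")))
  parts <- strsplit(x, "-", fixed = TRUE)[[1L]]
  method_spec(parts[1L], if (length(parts) > 1L) parts[2L] else NULL,
              output_type = output_type, ...)
}

#' Fit a per-DoF ensemble of 4-class linear models
#'
#' One 4-class model (agonist / antagonist / other movement / rest) per
#' degree of freedom; predictions from the k models are combined by
#' [decode_per_dof()] into a full movement label. This is how linear
#' classifiers, which cannot emit multiple active outputs from a single
#' model, handle simultaneous movements.
#'
#' @param x feature matrix.
#' @param class_index 0-based class index per row.
#' @param labels label table with DoF state columns.
#' @param base `"lda"` or `"glm"`.
#' @param trainer GLM trainer (ignored for lda).
#' @param config a [train_config()].
#' @return An `emg_per_dof` list of k fitted models.
#' @export
fit_per_dof_ensemble <- function(x, class_index, labels,
                                 base = c("lda", "glm"), trainer = "irls",
                                 config = train_config()) {
  base <- match.arg(base)
  states <- label_states(labels)[match(class_index, labels$class_index), ,
                                 drop = FALSE]
  cls <- per_dof_classes(states)
  k <- ncol(cls)
  models <- lapply(seq_len(k), function(d) {
    present <- sort(unique(cls[, d]))
    if (length(present) == 1L) {
      structure(list(constant = present), class = "emg_constant4")
    } else if (base == "lda") {
      fit_lda(x, cls[, d])
    } else {
      t4 <- matrix(0, nrow(x), 4L)
      t4[cbind(seq_len(nrow(x)), cls[, d])] <- 1
      train_glm(x, t4, algorithm = trainer, output_function = "softmax",
                config = config)
    }
  })
  structure(list(models = models, base = base, n_dof = k), class = "emg_per_dof")
}

#' @export
predict.emg_per_dof <- function(object, newdata, ...) {
  blocks <- lapply(object$models, function(m) {
    if (inherits(m, "emg_constant4")) {
      out <- matrix(0, nrow(as.matrix(newdata)), 4L)
      out[, m$constant] <- 1
      out
    } else {
      scores <- predict(m, newdata)
      if (inherits(m, "emg_lda")) {
        ## expand to the 4 canonical columns in case a class was absent
        full <- matrix(-Inf, nrow(scores), 4L)
        full[, m$class_levels] <- scores
        full
      } else scores
    }
  })
  do.call(cbind, blocks)
}

## ---- fit/classify dispatch used by the evaluation machinery -----------

fit_method <- function(spec, x, class_index, labels) {
  single <- spec$output_type == "single"
  model <- if (spec$method == "lda") {
    if (single) fit_lda(x, class_index)
    else fit_per_dof_ensemble(x, class_index, labels, base = "lda")
  } else if (spec$method == "glm") {
    if (single) {
      targets <- encode_targets(class_index, "single", labels)
      train_glm(x, targets, algorithm = spec$trainer,
                output_function = "softmax", config = spec$train)
    } else {
      fit_per_dof_ensemble(x, class_index, labels, base = "glm",
                           trainer = spec$trainer, config = spec$train)
    }
  } else {
    scheme <- if (single) "single" else "multiple"
    targets <- encode_targets(class_index, scheme, labels)
    outfun <- if (single) spec$output_function else "logistic"
    train_mlp(x, targets, hidden = spec$hidden, trainer = spec$trainer,
              output_function = outfun, config = spec$train)
  }
  structure(list(spec = spec, model = model, labels = labels),
            class = "emg_fit")
}

#' Classify feature windows with a fitted method
#'
#' Runs the model forward and decodes its outputs with the decoder
#' matching the method's output type.
#'
#' @param fit an `emg_fit` (from the evaluation machinery) or a bare
#'   model plus explicit decoding arguments.
#' @param newdata feature matrix.
#' @return Integer vector of predicted 0-based class indices.
#' @export
classify <- function(fit, newdata) {
  stopifnot(inherits(fit, "emg_fit"))
  out <- predict(fit$model, newdata)
  spec <- fit$spec
  if (spec$output_type == "single") {
    if (inherits(fit$model, "emg_lda"))
      fit$model$class_levels[decode_single(out) + 1L]
    else fit$labels$class_index[decode_single(out) + 1L]
  } else if (inherits(fit$model, "emg_per_dof")) {
    decode_per_dof(out, fit$labels)
  } else {
    decode_multiple(out, fit$labels)
  }
}

## ---- serialization ----------------------------------------------------

#' Serialize a fitted model to a portable JSON document
#'
#' The document records the model family, architecture, weights, output
#' function, the label table and (optionally) the normalization spec, so
#' that a trained pipeline is a single portable text file.
#'
#' @param fit an `emg_fit`, or any of the bare model classes.
#' @param path output file.
#' @param normalization optional [fit_normalization()] spec to embed.
#' @return `path`, invisibly.
#' @export
write_model <- function(fit, path, normalization = NULL) {
  ser <- serialize_model(fit)
  if (!is.null(normalization))
    ser$normalization <- list(kind = normalization$kind,
                              location = normalization$location,
                              scale = normalization$scale)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

serialize_model <- function(fit) {
  if (inherits(fit, "emg_fit")) {
    return(list(container = "emg_fit",
                spec = fit$spec[c("method", "trainer", "output_type",
                                  "hidden", "output_function")],
                labels = as.list(fit$labels),
                model = serialize_model(fit$model)))
  }
  if (inherits(fit, "emg_lda"))
    list(type = "lda", class_means = fit$class_means,
         pooled_covariance = fit$pooled_covariance, priors = fit$priors,
         class_levels = fit$class_levels)
  else if (inherits(fit, "emg_glm"))
    list(type = "glm", weights = fit$weights,
         output_function = fit$output_function, trainer = fit$trainer)
  else if (inherits(fit, "emg_mlp"))
    list(type = "mlp", layer_sizes = fit$layer_sizes,
         layers = lapply(fit$layers, function(l) list(w = l$w, b = l$b)),
         output_function = fit$output_function, trainer = fit$trainer)
  else if (inherits(fit, "emg_per_dof"))
    list(type = "per_dof", base = fit$base, n_dof = fit$n_dof,
         models = lapply(fit$models, serialize_model))
  else if (inherits(fit, "emg_constant4"))
    list(type = "constant4", constant = fit$constant)
  else structural_error("cannot serialize this model class")
}

#' Read a serialized model
#'
#' @param path JSON file written by [write_model()].
#' @return The model object (an `emg_fit` if one was written); any
#'   embedded normalization is attached as attribute `"normalization"`.
#' @export
read_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  obj <- deserialize_model(doc)
  if (!is.null(doc$normalization))
    attr(obj, "normalization") <- structure(
      list(kind = doc$normalization$kind,
           location = unlist(doc$normalization$location),
           scale = unlist(doc$normalization$scale)),
      class = "normalization_spec")
  obj
}

deserialize_model <- function(doc) {
  if (identical(doc$container, "emg_fit")) {
    spec <- method_spec(doc$spec$method,
                        if (doc$spec$trainer %in% c("irls", "scg", "gradient_descent"))
                          doc$spec$trainer else NULL,
                        output_type = doc$spec$output_type,
                        hidden = unlist(doc$spec$hidden),
                        output_function = doc$spec$output_function)
    return(structure(list(spec = spec,
                          model = deserialize_model(doc$model),
                          labels = as.data.frame(lapply(doc$labels, unlist))),
                     class = "emg_fit"))
  }
  switch(doc$type,
    lda = {
      m <- as.matrix(doc$pooled_covariance)
      structure(list(class_means = as.matrix(doc$class_means),
                     pooled_covariance = m,
                     priors = unlist(doc$priors),
                     class_levels = unlist(doc$class_levels),
                     sinv = solve(m)),
                class = "emg_lda")
    },
    glm = structure(list(weights = as.matrix(doc$weights),
                         output_function = doc$output_function,
                         trainer = doc$trainer),
                    class = "emg_glm"),
    mlp = structure(list(layer_sizes = unlist(doc$layer_sizes),
                         layers = lapply(doc$layers, function(l)
                           list(w = as.matrix(l$w), b = unlist(l$b))),
                         hidden_activation = "logistic",
                         output_function = doc$output_function,
                         trainer = doc$trainer),
                    class = "emg_mlp"),
    per_dof = structure(list(models = lapply(doc$models, deserialize_model),
                             base = doc$base, n_dof = doc$n_dof),
                        class = "emg_per_dof"),
    constant4 = structure(list(constant = doc$constant),
                          class = "emg_constant4"),
    structural_error("unknown serialized model type"))
}
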