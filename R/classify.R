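#' Train a linear large-margin classifier on selected markers
#'
#' Fits a soft-margin linear support-vector classifier with the cost
#' parameter fixed to 1 on the standardized delta-Ct submatrix restricted to
#' `markers`. Each marker is z-standardized (centered and scaled) with
#' parameters estimated on the training samples only; the parameters are
#' stored in the model so predictions are self-contained and invariant to
#' positive rescaling of any input column. The solver configuration is
#' deterministic, so identical inputs yield identical weights.
#'
#' @param ds a labeled [delta_ct_dataset()] with samples of the two
#'   diagnostic classes only.
#' @param markers marker names to use (non-empty, all present in `ds`).
#' @param cost soft-margin cost parameter; fixed to 1 by design, exposed
#'   for completeness.
#' @return An object of class `ct_svm`: markers, weights (one per marker),
#'   bias, per-marker standardization (center, scale), and the two class
#'   labels. The decision value of a sample x is
#'   `sum(weights * (x - center) / scale) + bias`; positive decision values
#'   are called `positive_class`, and a sample exactly on the hyperplane
#'   (decision value 0) is called `negative_class` -- the documented benign
#'   tie convention.
#' @export
train_svm <- function(ds, markers, cost = 1) {
  stopifnot(inherits(ds, "delta_ct_dataset"))
  if (is.null(ds$labels)) stop("dataset has no labels")
  if (length(markers) == 0) stop("empty marker list")
  missing <- setdiff(markers, rownames(ds$dct))
  if (length(missing) > 0)
    stop("unknown marker(s): ", paste(missing, collapse = ", "))
  two_class_check(ds, min_per_class = 1)

  x <- t(ds$dct[markers, , drop = FALSE])
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1   # constant marker: center only
  z <- scale(x, center = center, scale = scale)

  y <- factor(ds$labels, levels = c(ds$positive_class, ds$negative_class))
  fit <- e1071::svm(z, y, type = "C-classification", kernel = "linear",
                    cost = cost, scale = FALSE, tolerance = 1e-6,
                    shrinking = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients decision values toward whichever class it encountered
  # first; re-orient so that a positive decision value means positive class,
  # calibrating against the solver's own fitted labels.
  dv <- drop(z %*% w) + b
  agree <- mean((dv > 0) == (fit$fitted == ds$positive_class))
  if (agree < 0.5) {
    w <- -w
    b <- -b
  }
  structure(list(markers = markers,
                 weights = stats::setNames(as.numeric(w), markers),
                 bias = as.numeric(b),
                 center = stats::setNames(as.numeric(center), markers),
                 scale = stats::setNames(as.numeric(scale), markers),
                 positive_class = ds$positive_class,
                 negative_class = ds$negative_class,
                 cost = cost),
            class = "ct_svm")
}

#' @export
print.ct_svm <- function(x, ...) {
  cat("<ct_svm> linear classifier, ", length(x$markers), " marker(s), cost ",
      x$cost, "; ", x$positive_class, " if decision > 0 else ",
      x$negative_class, "\n", sep = "")
  invisible(x)
}

#' Decision values of a linear marker classifier
#'
#' @param model a [train_svm()] model.
#' @param ds a [delta_ct_dataset()] containing all model markers.
#' @return Named numeric vector of signed distances (in weight units) from
#'   the decision hyperplane, one per sample.
#' @export
decision_values <- function(model, ds) {
  stopifnot(inherits(model, "ct_svm"), inherits(ds, "delta_ct_dataset"))
  missing <- setdiff(model$markers, rownames(ds$dct))
  if (length(missing) > 0)
    stop("dataset lacks model marker(s): ", paste(missing, collapse = ", "))
  x <- t(ds$dct[model$markers, , drop = FALSE])
  z <- scale(x, center = model$center, scale = model$scale)
  drop(z %*% model$weights) + model$bias
}

#' Predict diagnosis labels
#'
#' A sample is called `positive_class` iff its decision value is strictly
#' positive; a decision value of exactly 0 is called `negative_class`.
#' Every sample receives exactly one call (no reject option).
#'
#' @param object a `ct_svm` model.
#' @param ds a [delta_ct_dataset()] containing all model markers.
#' @param ... unused.
#' @return Named character vector of predicted labels.
#' @export
predict.ct_svm <- function(object, ds, ...) {
  dv <- decision_values(object, ds)
  stats::setNames(ifelse(dv > 0, object$positive_class,
                         object$negative_class), names(dv))
}

#' Rank-then-train: the top-k classifier strategy
#'
#' Composes [rank_markers()] on the given (training) data with
#' [train_svm()] on the `k` best markers; the selected marker list is part
#' of the trained artifact. This is the unit that cross-validation refits
#' on every training fold.
#'
#' @param ds a labeled [delta_ct_dataset()].
#' @param k number of top-ranked markers to keep (`1 <= k <= nrow(ds$dct)`).
#' @return A `ct_svm` model using exactly `k` markers.
#' @export
train_topk <- function(ds, k) {
  stopifnot(inherits(ds, "delta_ct_dataset"))
  m <- nrow(ds$dct)
  if (k < 1 || k > m)
    stop("k must be between 1 and the number of markers (", m, ")")
  two_class_check(ds, min_per_class = 2)
  train_svm(ds, top_markers(ds, k))
}

#' Serialize / deserialize a classifier as JSON
#'
#' The JSON document carries the selected markers, weights, bias,
#' standardization parameters, class labels and optional metadata, so a
#' stored model can be applied to new delta-Ct tables without refitting.
#'
#' @param model a `ct_svm` model.
#' @param path file path.
#' @param metadata optional named list stored verbatim (e.g. selection
#'   provenance such as the chosen top-list size).
#' @return `write_model`: `path` invisibly; `read_model`: a `ct_svm`.
#' @export
write_model <- function(model, path, metadata = NULL) {
  stopifnot(inherits(model, "ct_svm"))
  doc <- list(format = "ctpanel-linear-model", version = 1L,
              markers = model$markers,
              weights = unname(model$weights),
              bias = model$bias,
              center = unname(model$center),
              scale = unname(model$scale),
              positive_class = model$positive_class,
              negative_class = model$negative_class,
              cost = model$cost,
              metadata = metadata)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "ctpanel-linear-model"))
    stop("not a ctpanel model file: ", path)
  structure(list(markers = doc$markers,
                 weights = stats::setNames(doc$weights, doc$markers),
                 bias = doc$bias,
                 center = stats::setNames(doc$center, doc$markers),
                 scale = stats::setNames(doc$scale, doc$markers),
                 positive_class = doc$positive_class,
                 negative_class = doc$negative_class,
                 cost = doc$cost,
                 metadata = doc$metadata),
            class = "ct_svm")
}
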