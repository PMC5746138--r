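#' Univariate single-threshold marker scores (TNoM family)
#'
#' `tnom_cw_score()` scores one marker by the best achievable balanced
#' performance of a single-threshold classifier: every candidate threshold
#' (midpoints between consecutive distinct sorted values, plus one cut below
#' the minimum and one above the maximum) is evaluated under both
#' orientations, and the maximum of `(sensitivity + specificity) / 2` is
#' returned. `tnom_score()` is the plain variant whose objective is overall
#' accuracy (the pooled correct fraction); the two coincide on balanced
#' classes.
#'
#' Ties in the objective are resolved toward the smaller threshold, and at
#' equal threshold toward the `positive_above` orientation, so scores,
#' thresholds and orientations are deterministic.
#'
#' @param values numeric vector of delta-Ct values for one marker (finite).
#' @param labels vector of class labels aligned with `values`.
#' @param positive_class label of the positive (malignant) class; default
#'   the first of the two distinct labels in sorted order is *not* assumed
#'   -- it must be present among `labels`.
#' @return An object of class `threshold_score`: a list with `score`,
#'   `threshold`, `orientation` (`"positive_above"` or `"positive_below"`),
#'   `sensitivity_at_opt` and `specificity_at_opt`. For the class-wise
#'   variant `score == (sensitivity_at_opt + specificity_at_opt) / 2` and
#'   the orientation search guarantees `score >= 0.5`.
#' @examples
#' tnom_cw_score(c(1, 2, 5, 6), c("CP", "CP", "PDAC", "PDAC"), "PDAC")
#' @export
tnom_cw_score <- function(values, labels, positive_class = "PDAC") {
  threshold_scan(values, labels, positive_class, objective = "balanced")
}

#' @rdname tnom_cw_score
#' @export
tnom_score <- function(values, labels, positive_class = "PDAC") {
  threshold_scan(values, labels, positive_class, objective = "accuracy")
}

# Shared scan engine. For a cut placed after sorted position i
# (i in 0..n, restricted to boundaries between distinct values), with
# pb = positives at or below the cut and nb = negatives at or below:
#   positive_below: sens = pb/P,     spec = (N - nb)/N
#   positive_above: sens = (P-pb)/P, spec = nb/N
# so the two orientations' objectives are complementary (obj_above =
# 1 - obj_below), for the balanced and the pooled objective alike.
threshold_scan <- function(values, labels, positive_class,
                           objective = c("balanced", "accuracy")) {
  objective <- match.arg(objective)
  if (any(!is.finite(values))) stop("non-finite marker value")
  labels <- as.character(labels)
  pos <- labels == positive_class
  P <- sum(pos); N <- sum(!pos)
  if (P == 0 || N == 0)
    stop("both classes must be non-empty (positives: ", P,
         ", negatives: ", N, ")")
  n <- length(values)
  ord <- order(values)
  v <- values[ord]
  y <- pos[ord]

  cuts <- c(0L, which(diff(v) > 0), n)          # valid cut positions i
  pb <- c(0, cumsum(y))[cuts + 1L]              # positives at/below cut
  nb <- cuts - pb
  thr <- c(v[1] - 1,
           if (length(cuts) > 2) (v[cuts[-c(1, length(cuts))]] +
                                  v[cuts[-c(1, length(cuts))] + 1L]) / 2,
           v[n] + 1)

  sens_b <- pb / P
  spec_b <- (N - nb) / N
  obj_b <- if (objective == "balanced") (sens_b + spec_b) / 2
           else (pb + (N - nb)) / n
  obj_a <- 1 - obj_b

  # precedence: increasing threshold, positive_above before positive_below
  obj <- c(rbind(obj_a, obj_b))
  best <- which.max(obj)                        # first maximum wins
  i <- ceiling(best / 2)
  above <- best %% 2 == 1L
  res <- list(
    score = obj[best],
    threshold = thr[i],
    orientation = if (above) "positive_above" else "positive_below",
    sensitivity_at_opt = if (above) 1 - sens_b[i] else sens_b[i],
    specificity_at_opt = if (above) 1 - spec_b[i] else spec_b[i],
    objective = objective)
  class(res) <- "threshold_score"
  res
}

#' @export
print.threshold_score <- function(x, ...) {
  cat(sprintf(
    "<threshold_score> score %.4f at threshold %.4g (%s); sens %.3f spec %.3f\n",
    x$score, x$threshold, x$orientation,
    x$sensitivity_at_opt, x$specificity_at_opt))
  invisible(x)
}

# Class-wise scores for every row of a matrix, vectorized over thresholds.
# Returns the numeric score vector only (used inside cross-validation where
# thresholds and orientations are not needed).
tnom_cw_scores <- function(dct, pos) {
  P <- sum(pos); N <- sum(!pos)
  apply(dct, 1, function(v) {
    ord <- order(v)
    y <- pos[ord]
    vv <- v[ord]
    cuts <- c(0L, which(diff(vv) > 0), length(vv))
    pb <- c(0, cumsum(y))[cuts + 1L]
    nb <- cuts - pb
    obj <- (pb / P + (N - nb) / N) / 2
    max(obj, 1 - obj)
  })
}

#' Rank markers by class-wise threshold score
#'
#' Computes the class-wise threshold score of every marker on the given
#' (training) samples and orders markers by score, breaking ties by panel
#' position (the dataset's row order), so rankings are reproducible across
#' runs and platforms. Inside cross-validation this is recomputed on every
#' training fold -- never on the full dataset -- so that marker selection
#' cannot leak test information.
#'
#' @param ds a labeled [delta_ct_dataset()] restricted to the two
#'   diagnostic classes.
#' @return An object of class `marker_ranking`: a data.frame with columns
#'   `rank`, `marker`, `score`, `threshold`, `orientation`,
#'   `sensitivity`, `specificity`, ordered by (score desc, panel position
#'   asc).
#' @export
rank_markers <- function(ds) {
  stopifnot(inherits(ds, "delta_ct_dataset"))
  if (is.null(ds$labels)) stop("dataset has no labels")
  two_class_check(ds, min_per_class = 2)
  scores <- lapply(rownames(ds$dct), function(mk)
    tnom_cw_score(ds$dct[mk, ], ds$labels, ds$positive_class))
  out <- data.frame(
    marker = rownames(ds$dct),
    score = vapply(scores, `[[`, numeric(1), "score"),
    threshold = vapply(scores, `[[`, numeric(1), "threshold"),
    orientation = vapply(scores, `[[`, character(1), "orientation"),
    sensitivity = vapply(scores, `[[`, numeric(1), "sensitivity_at_opt"),
    specificity = vapply(scores, `[[`, numeric(1), "specificity_at_opt"),
    stringsAsFactors = FALSE)
  ord <- order(-out$score, seq_len(nrow(out)))
  out <- out[ord, ]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  structure(out, class = c("marker_ranking", "data.frame"),
            tie_break = "score desc, panel position asc")
}

# Fast path used inside CV: top-k marker names only.
top_markers <- function(ds, k) {
  pos <- ds$labels == ds$positive_class
  sc <- tnom_cw_scores(ds$dct, pos)
  rownames(ds$dct)[order(-sc, seq_along(sc))[seq_len(k)]]
}

two_class_check <- function(ds, min_per_class = 1) {
  tab <- table(factor(ds$labels,
                      levels = c(ds$positive_class, ds$negative_class)))
  extra <- setdiff(unique(ds$labels),
                   c(ds$positive_class, ds$negative_class))
  if (length(extra) > 0)
    stop("labels outside the two diagnostic classes: ",
         paste(extra, collapse = ", "))
  if (any(tab < min_per_class))
    stop("need at least ", min_per_class, " sample(s) per class (",
         paste(names(tab), tab, sep = "=", collapse = ", "), ")")
  invisible(tab)
}
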