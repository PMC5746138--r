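#' Retrain the final classifier on the whole two-class cohort
#'
#' After the top-list sweep has picked an optimal size k, the deployable
#' model is obtained by refitting the top-k strategy (ranking plus linear
#' classifier) on every available sample of the two diagnostic classes.
#' This is [train_topk()] on the full cohort -- no special-cased code path.
#' If k exceeds the number of available markers it is capped with a
#' warning.
#'
#' @param ds_pdac_cp a labeled [delta_ct_dataset()] restricted to the
#'   positive and negative diagnostic classes.
#' @param k top-list size (default 77, the size class of the combined-panel
#'   optimum; pass the sweep's `argmax_k` in practice).
#' @return A `ct_svm` model using `min(k, markers)` markers.
#' @export
retrain_final <- function(ds_pdac_cp, k = 77) {
  stopifnot(inherits(ds_pdac_cp, "delta_ct_dataset"))
  m <- nrow(ds_pdac_cp$dct)
  if (k < 1) stop("k must be >= 1")
  if (k > m) {
    warning("k = ", k, " exceeds the ", m,
            " available markers; capping at ", m)
    k <- m
  }
  train_topk(ds_pdac_cp, k)
}

#' Apply the final classifier to additional lesion classes
#'
#' Every sample of the additional-lesion dataset is assigned to the
#' malignant (positive) or benign (negative) class by [predict.ct_svm()]
#' -- a binary forced choice with no abstention -- and per-diagnosis-group
#' tallies are returned. Groups with zero samples are dropped with a
#' warning.
#'
#' @param model a `ct_svm` model (typically from [retrain_final()]).
#' @param ds_other a [delta_ct_dataset()] of non-PDAC/CP samples
#'   containing all model markers.
#' @param groups named character vector, sample id -> diagnosis group
#'   (default the dataset's own labels).
#' @return An object of class `lesion_call_table`: a data.frame with one
#'   row per group (`group`, `n`, `assigned_positive`,
#'   `assigned_negative`); the two assignment columns sum to `n` in every
#'   row.
#' @export
classify_lesions <- function(model, ds_other, groups = ds_other$labels) {
  stopifnot(inherits(model, "ct_svm"), inherits(ds_other, "delta_ct_dataset"))
  if (ncol(ds_other$dct) == 0) {
    res <- data.frame(group = character(0), n = integer(0),
                      assigned_positive = integer(0),
                      assigned_negative = integer(0),
                      stringsAsFactors = FALSE)
    return(structure(res, class = c("lesion_call_table", "data.frame"),
                     positive_class = model$positive_class,
                     negative_class = model$negative_class))
  }
  if (is.null(groups)) stop("no diagnosis groups supplied")
  groups <- groups[colnames(ds_other$dct)]
  if (anyNA(groups))
    stop("group missing for sample(s): ",
         paste(colnames(ds_other$dct)[is.na(groups)], collapse = ", "))
  if (is.factor(groups)) {
    unused <- setdiff(levels(groups), unique(as.character(groups)))
    if (length(unused) > 0)
      warning("dropping group(s) with zero samples: ",
              paste(unused, collapse = ", "))
    groups <- as.character(groups)
    names(groups) <- colnames(ds_other$dct)
  }
  calls <- predict(model, ds_other)
  rows <- lapply(unique(groups), function(g) {
    in_g <- groups == g
    data.frame(group = g, n = sum(in_g),
               assigned_positive = sum(calls[in_g] == model$positive_class),
               assigned_negative = sum(calls[in_g] == model$negative_class),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  structure(res, class = c("lesion_call_table", "data.frame"),
            positive_class = model$positive_class,
            negative_class = model$negative_class)
}

#' Uncentered Pearson correlation between matrix columns
#'
#' `sim(x, y) = sum(x * y) / sqrt(sum(x^2) * sum(y^2))`: the cosine of the
#' angle between the raw vectors, computed without mean-centering, so it is
#' sensitive to shared sign and magnitude. A zero column has no defined
#' direction and is a hard error.
#'
#' @param m numeric matrix; correlation is computed between columns.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
uncentered_cor <- function(m) {
  m <- as.matrix(m)
  norms <- sqrt(colSums(m^2))
  if (any(norms == 0)) {
    off <- if (!is.null(colnames(m))) colnames(m)[norms == 0]
           else which(norms == 0)
    stop("zero vector(s), uncentered correlation undefined: ",
         paste(off, collapse = ", "))
  }
  crossprod(m) / tcrossprod(norms)
}

#' Two-way hierarchical clustering of an expression matrix
#'
#' Clusters both the samples and the markers by complete-linkage
#' agglomeration on the dissimilarity `1 - uncentered Pearson correlation`
#' (range `[0, 2]`). Because delta-Ct is inversely related to expression
#' and the uncentered correlation is sign-sensitive, the matrix is negated
#' first so that clustering operates on relative expression (high values =
#' high expression); the returned reordered matrix uses the same
#' orientation. Complete linkage guarantees monotone merge heights, and
#' the agglomeration and leaf orders are deterministic functions of the
#' input order (ties merge in input index order).
#'
#' @param ds a [delta_ct_dataset()] with >= 2 samples and >= 2 markers,
#'   all values finite.
#' @return A list of class `ct_clustering`: `sample_hclust` and
#'   `marker_hclust` (objects of class [stats::hclust]), and `matrix`
#'   (the expression-oriented matrix, rows and columns reordered by the
#'   two dendrograms).
#' @export
cluster_heatmap <- function(ds) {
  stopifnot(inherits(ds, "delta_ct_dataset"))
  if (nrow(ds$dct) < 2 || ncol(ds$dct) < 2)
    stop("need at least 2 markers and 2 samples")
  expr <- -ds$dct                       # high value = high expression
  d_samples <- stats::as.dist(1 - uncentered_cor(expr))
  d_markers <- stats::as.dist(1 - uncentered_cor(t(expr)))
  hc_s <- stats::hclust(d_samples, method = "complete")
  hc_m <- stats::hclust(d_markers, method = "complete")
  structure(list(sample_hclust = hc_s,
                 marker_hclust = hc_m,
                 matrix = expr[hc_m$order, hc_s$order]),
            class = "ct_clustering")
}

#' @export
print.ct_clustering <- function(x, ...) {
  cat("<ct_clustering> ", nrow(x$matrix), " markers x ", ncol(x$matrix),
      " samples, complete linkage on 1 - uncentered correlation\n",
      sep = "")
  invisible(x)
}
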