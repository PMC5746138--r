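#' Cross-validation specification
#'
#' Describes a repeated k-fold cross-validation: `folds` subsets of
#' approximately equal size, the whole procedure repeated over `runs`
#' independent permutations of the cohort (the default 10 x 10 design
#' yields 100 train/test splits). One global seed expands deterministically
#' into per-run permutation seeds.
#'
#' @param folds number of folds (>= 2; default 10).
#' @param runs number of repetitions (>= 1; default 10).
#' @param stratified keep per-class proportions within +/- 1 sample per
#'   fold (default `TRUE`). With unbalanced cohorts unstratified splits can
#'   strand a training set without one class, which is a hard error.
#' @param seed integer seed.
#' @return An object of class `cv_spec`.
#' @export
cv_spec <- function(folds = 10, runs = 10, stratified = TRUE, seed = 1L) {
  if (folds < 2) stop("folds must be >= 2")
  if (runs < 1) stop("runs must be >= 1")
  structure(list(folds = as.integer(folds), runs = as.integer(runs),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "cv_spec")
}

#' Build the train/test splits of a repeated k-fold cross-validation
#'
#' Per run, a fresh seeded permutation of the samples is dealt into
#' `folds` groups of size `floor(n/folds)` or `ceiling(n/folds)`; with
#' stratification the dealing keeps each class's fold counts within one
#' sample of each other. Each fold in turn is the test set, all other
#' folds the training set.
#'
#' @param labels named character vector (sample id -> class).
#' @param spec a [cv_spec()].
#' @return List of `folds * runs` splits, each a list with `run`, `fold`,
#'   `train` and `test` sample ids. Within a run the test sets are disjoint
#'   and exhaustive.
#' @export
make_splits <- function(labels, spec) {
  stopifnot(inherits(spec, "cv_spec"))
  n <- length(labels)
  if (n < spec$folds) stop("fewer samples than folds")
  ids <- names(labels)
  if (is.null(ids)) stop("labels must be named by sample id")
  classes <- unique(labels)
  splits <- vector("list", spec$folds * spec$runs)
  out <- 1L
  for (run in seq_len(spec$runs)) {
    set.seed(derive_seed(spec$seed, run))
    fold_of <- integer(n)
    names(fold_of) <- ids
    if (spec$stratified) {
      offset <- 0L
      for (cl in classes) {
        members <- ids[labels == cl]
        members <- sample(members)
        fold_of[members] <- ((offset + seq_along(members) - 1L) %%
                               spec$folds) + 1L
        offset <- (offset + length(members)) %% spec$folds
      }
    } else {
      perm <- sample(ids)
      fold_of[perm] <- ((seq_len(n) - 1L) %% spec$folds) + 1L
    }
    for (fold in seq_len(spec$folds)) {
      test <- ids[fold_of[ids] == fold]
      train <- ids[fold_of[ids] != fold]
      if (!all(classes %in% labels[train]))
        stop("training set of run ", run, ", fold ", fold,
             " is missing a class; use stratified splits")
      splits[[out]] <- list(run = run, fold = fold,
                            train = train, test = test)
      out <- out + 1L
    }
  }
  splits
}

#' Confusion counts of diagnostic calls against the gold standard
#'
#' @param calls predicted labels.
#' @param truth true labels, aligned with `calls`.
#' @param positive_class,negative_class the two diagnostic classes.
#' @return An object of class `confusion_counts` with fields `TP`, `FN`,
#'   `TN`, `FP` (`TP + FN + TN + FP == length(calls)`).
#' @export
confusion <- function(calls, truth, positive_class = "PDAC",
                      negative_class = "CP") {
  if (length(calls) != length(truth))
    stop("calls and truth lengths differ")
  both <- c(calls, truth)
  bad <- setdiff(unique(both), c(positive_class, negative_class))
  if (length(bad) > 0)
    stop("label(s) outside the two classes: ", paste(bad, collapse = ", "))
  structure(list(
    TP = sum(calls == positive_class & truth == positive_class),
    FN = sum(calls == negative_class & truth == positive_class),
    TN = sum(calls == negative_class & truth == negative_class),
    FP = sum(calls == positive_class & truth == negative_class)),
    class = "confusion_counts")
}

#' Sensitivity, specificity and diagnostic accuracy
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `accuracy = (TP + TN) / (TP + FN + TN + FP)`. A metric whose denominator
#' is zero is flagged as undefined (value `NA`) rather than propagated as
#' `NaN`.
#'
#' @param counts a [confusion()] result.
#' @return List with `sensitivity`, `specificity`, `accuracy` and
#'   `undefined` (character vector naming any undefined metric).
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  res <- list(
    sensitivity = ratio(counts$TP, counts$TP + counts$FN),
    specificity = ratio(counts$TN, counts$TN + counts$FP),
    accuracy = ratio(counts$TP + counts$TN,
                     counts$TP + counts$FN + counts$TN + counts$FP))
  res$undefined <- names(res)[vapply(res, is.na, logical(1))]
  res
}

#' Classifier-building strategies for cross-validation
#'
#' A strategy is the full training recipe refit on every training fold:
#' `fixed_subset_strategy()` trains the linear classifier on a given marker
#' set; `topk_strategy()` first ranks all markers by the class-wise
#' threshold score on the training fold and keeps the `k` best (nested
#' selection -- test samples never influence the ranking).
#'
#' @param markers marker names (fixed-subset strategy).
#' @param k top-list size (top-k strategy).
#' @return An object of class `cv_strategy`.
#' @export
fixed_subset_strategy <- function(markers) {
  if (length(markers) == 0) stop("empty marker list")
  structure(list(type = "fixed", markers = markers), class = "cv_strategy")
}

#' @rdname fixed_subset_strategy
#' @export
topk_strategy <- function(k) {
  if (k < 1) stop("k must be >= 1")
  structure(list(type = "topk", k = as.integer(k)), class = "cv_strategy")
}

fit_strategy <- function(strategy, train_ds) {
  switch(strategy$type,
         fixed = train_svm(train_ds, strategy$markers),
         topk = train_svm(train_ds, top_markers(train_ds, strategy$k)),
         stop("unknown strategy type: ", strategy$type))
}

#' Repeated cross-validated evaluation of a classifier strategy
#'
#' For each of the `folds x runs` splits the full strategy -- including any
#' marker ranking -- is refit on the training folds only, and the held-out
#' fold is predicted. Per-run sensitivity, specificity and accuracy are
#' computed from the run's pooled confusion counts (all of the run's
#' held-out calls), and their means over runs are reported.
#'
#' @param ds a labeled two-class [delta_ct_dataset()].
#' @param strategy a [fixed_subset_strategy()] or [topk_strategy()].
#' @param spec a [cv_spec()].
#' @return An object of class `cv_outcome`: `splits`, `predictions` (one
#'   held-out call per sample per run: columns `run`, `fold`, `sample`,
#'   `call`, `truth`), `per_run` (per-run metrics), and
#'   `mean_sensitivity`, `mean_specificity`, `mean_accuracy`.
#' @export
cross_validate <- function(ds, strategy, spec) {
  stopifnot(inherits(ds, "delta_ct_dataset"),
            inherits(strategy, "cv_strategy"), inherits(spec, "cv_spec"))
  if (is.null(ds$labels)) stop("dataset has no labels")
  two_class_check(ds, min_per_class = 1)
  splits <- make_splits(ds$labels, spec)
  preds <- vector("list", length(splits))
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    model <- tryCatch(
      fit_strategy(strategy, subset_dataset(ds, samples = sp$train)),
      error = function(e) stop("training failed in run ", sp$run, ", fold ",
                               sp$fold, ": ", conditionMessage(e)))
    calls <- predict(model, subset_dataset(ds, samples = sp$test))
    preds[[i]] <- data.frame(run = sp$run, fold = sp$fold,
                             sample = sp$test, call = unname(calls),
                             truth = unname(ds$labels[sp$test]),
                             stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  per_run <- do.call(rbind, lapply(seq_len(spec$runs), function(r) {
    p <- predictions[predictions$run == r, ]
    m <- classification_metrics(confusion(p$call, p$truth,
                                          ds$positive_class,
                                          ds$negative_class))
    data.frame(run = r, sensitivity = m$sensitivity,
               specificity = m$specificity, accuracy = m$accuracy)
  }))
  structure(list(splits = splits, predictions = predictions,
                 per_run = per_run,
                 mean_sensitivity = mean(per_run$sensitivity),
                 mean_specificity = mean(per_run$specificity),
                 mean_accuracy = mean(per_run$accuracy),
                 strategy = strategy, spec = spec),
            class = "cv_outcome")
}

#' @export
print.cv_outcome <- function(x, ...) {
  cat(sprintf(paste0(
    "<cv_outcome> %d x %d-fold CV: %d splits, %d held-out calls\n",
    "  mean sensitivity %.3f, specificity %.3f, accuracy %.3f\n"),
    x$spec$runs, x$spec$folds, length(x$splits), nrow(x$predictions),
    x$mean_sensitivity, x$mean_specificity, x$mean_accuracy))
  invisible(x)
}

#' Exhaustive cross-validated search over marker subsets
#'
#' Evaluates every non-empty subset of the candidate markers (`2^m - 1`
#' subsets) with [cross_validate()] under the fixed-subset strategy and
#' returns the results sorted by mean accuracy, descending. Each subset's
#' cross-validation uses a seed derived from the subset's identity (its
#' bitmask), so results do not depend on evaluation order and the search
#' is trivially parallelizable.
#'
#' `exhaustive_mirna_search()` is the panel-level entry point: it restricts
#' the dataset to the panel's miRNA markers (a hard error if any is
#' absent) before searching -- the miRNA-only screen of all
#' `2^9 - 1 = 511` combinations.
#'
#' @param ds a labeled two-class [delta_ct_dataset()].
#' @param spec a [cv_spec()]; its seed is the search's master seed.
#' @param markers candidate markers (default: all markers in `ds`).
#' @return A data.frame with one row per subset (`subset_id`, `markers`,
#'   `size`, `mean_sensitivity`, `mean_specificity`, `mean_accuracy`),
#'   sorted by accuracy descending (ties: smaller subset id first).
#' @export
exhaustive_subset_search <- function(ds, spec, markers = rownames(ds$dct)) {
  stopifnot(inherits(ds, "delta_ct_dataset"), inherits(spec, "cv_spec"))
  m <- length(markers)
  if (m < 1) stop("no candidate markers")
  if (m > 20) stop("refusing exhaustive search over 2^", m, " - 1 subsets")
  n_subsets <- 2L^m - 1L
  rows <- vector("list", n_subsets)
  for (id in seq_len(n_subsets)) {
    members <- markers[bitwAnd(id, 2L^(seq_len(m) - 1L)) != 0L]
    sub_spec <- cv_spec(spec$folds, spec$runs, spec$stratified,
                        seed = derive_seed(spec$seed, id))
    out <- cross_validate(subset_dataset(ds, markers = members),
                          fixed_subset_strategy(members), sub_spec)
    rows[[id]] <- data.frame(subset_id = id,
                             markers = paste(members, collapse = ";"),
                             size = length(members),
                             mean_sensitivity = out$mean_sensitivity,
                             mean_specificity = out$mean_specificity,
                             mean_accuracy = out$mean_accuracy,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res <- res[order(-res$mean_accuracy, res$subset_id), ]
  rownames(res) <- NULL
  res
}

#' @rdname exhaustive_subset_search
#' @param panel a [marker_panel()] defining the miRNA marker roster
#'   (default the packaged panel).
#' @export
exhaustive_mirna_search <- function(ds, spec, panel = default_panel()) {
  mirna <- panel_markers(panel, chemistry = "miRNA")
  missing <- setdiff(mirna, rownames(ds$dct))
  if (length(missing) > 0)
    stop("dataset lacks panel miRNA marker(s): ",
         paste(missing, collapse = ", "))
  exhaustive_subset_search(subset_dataset(ds, markers = mirna), spec,
                           markers = mirna)
}

#' Number of non-empty marker subsets
#'
#' `2^m - 1`, returned as a double so that panel-scale counts (for the
#' full 88-marker panel about 3.09e26 combinations, far beyond exhaustive
#' search) do not overflow.
#'
#' @param m number of candidate markers.
#' @return `2^m - 1`.
#' @export
subset_count <- function(m) 2^m - 1

#' Cross-validated sweep over top-list sizes
#'
#' Runs the top-k strategy through [cross_validate()] for every
#' `k in 1..k_max` under the same cross-validation specification (all
#' sizes see identical splits, so results are directly comparable), and
#' tabulates mean accuracy, sensitivity and specificity per size.
#' Internally the per-split marker ranking is computed once and reused for
#' every k, which is arithmetically identical to calling
#' [cross_validate()] per k with the same spec.
#'
#' @param ds a labeled two-class [delta_ct_dataset()].
#' @param spec a [cv_spec()].
#' @param k_max largest top-list size (default: all markers).
#' @param flag_accuracy accuracy level flagged in the output table
#'   (default 0.90).
#' @return A data.frame with one row per k (`k`, `mean_sensitivity`,
#'   `mean_specificity`, `mean_accuracy`, `high_accuracy`), with attribute
#'   `argmax_k` (smallest k attaining the maximum mean accuracy).
#' @export
topk_sweep <- function(ds, spec, k_max = nrow(ds$dct),
                       flag_accuracy = 0.90) {
  stopifnot(inherits(ds, "delta_ct_dataset"), inherits(spec, "cv_spec"))
  if (is.null(ds$labels)) stop("dataset has no labels")
  m <- nrow(ds$dct)
  if (k_max < 1 || k_max > m)
    stop("k_max must be between 1 and the number of markers (", m, ")")
  two_class_check(ds, min_per_class = 2)
  splits <- make_splits(ds$labels, spec)
  pos <- ds$labels == ds$positive_class

  # one held-out call per sample per run and per k
  calls <- array(NA_character_, dim = c(k_max, spec$runs, ncol(ds$dct)),
                 dimnames = list(NULL, NULL, colnames(ds$dct)))
  for (sp in splits) {
    train_ds <- subset_dataset(ds, samples = sp$train)
    test_ds <- subset_dataset(ds, samples = sp$test)
    sc <- tnom_cw_scores(train_ds$dct, pos[sp$train])
    ranked <- rownames(train_ds$dct)[order(-sc, seq_along(sc))]
    for (k in seq_len(k_max)) {
      model <- train_svm(train_ds, ranked[seq_len(k)])
      calls[k, sp$run, sp$test] <- predict(model, test_ds)
    }
  }
  rows <- lapply(seq_len(k_max), function(k) {
    per_run <- vapply(seq_len(spec$runs), function(r) {
      m_ <- classification_metrics(confusion(calls[k, r, ],
                                             unname(ds$labels),
                                             ds$positive_class,
                                             ds$negative_class))
      c(m_$sensitivity, m_$specificity, m_$accuracy)
    }, numeric(3))
    data.frame(k = k,
               mean_sensitivity = mean(per_run[1, ]),
               mean_specificity = mean(per_run[2, ]),
               mean_accuracy = mean(per_run[3, ]))
  })
  res <- do.call(rbind, rows)
  res$high_accuracy <- res$mean_accuracy >= flag_accuracy
  attr(res, "argmax_k") <- res$k[which.max(res$mean_accuracy)]
  res
}
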