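#' Simulation configuration for synthetic qPCR cohorts
#'
#' Describes a synthetic fine-needle-aspiration cohort with the statistical
#' structure the downstream analysis assumes: per-marker baseline Ct levels,
#' an additive class-dependent Ct shift on an informative marker subset,
#' stable reference genes, Gaussian per-well technical noise, and censoring
#' of late wells as "Undetermined".
#'
#' @param n_per_class named integer vector, diagnosis label -> sample count.
#'   The default is the two-class study cohort: 41 PDAC and 33 CP.
#' @param informative_markers either marker names, or a count of markers to
#'   sample from the panel (default 10).
#' @param effect_size mean Ct shift (cycles) of informative markers in
#'   classes carrying the malignant signature (default 2.0).
#' @param effect_sign `-1` (marker upregulated in the positive class, lower
#'   Ct), `+1` (downregulated), or a vector recycled over the informative
#'   markers. The default alternates signs, mimicking a panel of both up-
#'   and downregulated markers.
#' @param noise_sd per-well technical noise SD in cycles (default 0.75).
#' @param baseline_ct_range interval for per-marker baseline mean Ct
#'   (default `c(22, 34)`).
#' @param reference_ct optional named vector of reference-assay mean Ct;
#'   defaults to values evenly spaced in `[15, 26]` over the panel's
#'   reference assays. The internal control, if present, is simulated as a
#'   highly abundant stable transcript (mean Ct 12).
#' @param reference_sd reference-assay noise SD in cycles (default 0.25).
#' @param censor_beyond cycle cap: draws beyond it become "Undetermined"
#'   (default 40).
#' @param class_shift_fraction named vector, label -> fraction of the
#'   informative markers on which that class carries the positive-class
#'   shift. The positive class is implicitly 1 and the negative class 0;
#'   defaults for additional lesion classes come from
#'   [default_shift_fractions()] (1.0 for carcinoma-like, 0.5 for
#'   cyst-like lesions).
#' @param positive_class,negative_class diagnosis labels (defaults
#'   `"PDAC"`, `"CP"`).
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_per_class = c(PDAC = 41, CP = 33),
                              informative_markers = 10,
                              effect_size = 2.0,
                              effect_sign = c(-1, 1),
                              noise_sd = 0.75,
                              baseline_ct_range = c(22, 34),
                              reference_ct = NULL,
                              reference_sd = 0.25,
                              censor_beyond = 40,
                              class_shift_fraction = NULL,
                              positive_class = "PDAC",
                              negative_class = "CP",
                              seed = 1L) {
  if (is.null(names(n_per_class)) || any(n_per_class <= 0))
    stop("n_per_class must be a named vector of positive counts")
  if (noise_sd <= 0 || reference_sd <= 0)
    stop("noise_sd and reference_sd must be positive")
  structure(list(n_per_class = n_per_class,
                 informative_markers = informative_markers,
                 effect_size = effect_size,
                 effect_sign = effect_sign,
                 noise_sd = noise_sd,
                 baseline_ct_range = baseline_ct_range,
                 reference_ct = reference_ct,
                 reference_sd = reference_sd,
                 censor_beyond = censor_beyond,
                 class_shift_fraction = class_shift_fraction,
                 positive_class = positive_class,
                 negative_class = negative_class,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default per-class signature fractions for additional lesion classes
#'
#' Carcinoma-like lesions (ampullary, acinar cell and biliary tract
#' carcinomas) carry the full malignant Ct signature; cyst-like lesions
#' (cystadenoma, IPMN, solid pseudopapillary tumor) carry it on half of the
#' informative markers, which makes their classification ambiguous by
#' construction.
#'
#' @return Named numeric vector of signature fractions.
#' @export
default_shift_fractions <- function() {
  c(PDAC = 1, CP = 0,
    AmpullaryCA = 1, AcinarCellCA = 1, BiliaryTractCA = 1,
    Cystadenoma = 0.5, IPMN = 0.5, SPT = 0.5)
}

#' Default additional-lesion class sizes
#'
#' A 39-sample extension cohort of non-PDAC/CP lesions: 3 ampullary, 3
#' acinar cell and 5 biliary tract carcinomas plus 10 cystadenomas, 15
#' IPMNs and 3 solid pseudopapillary tumors.
#'
#' @return Named integer vector of class sizes (sums to 39).
#' @export
lesion_class_counts <- function() {
  c(AmpullaryCA = 3L, AcinarCellCA = 3L, BiliaryTractCA = 5L,
    Cystadenoma = 10L, IPMN = 15L, SPT = 3L)
}

#' Simulate a raw Ct cohort
#'
#' Draws, per sample of class y and assay g,
#' `Ct = baseline(g) + effect(g) * fraction(y, g) + Normal(0, noise_sd^2)`;
#' reference assays (and the internal control) use their own stable means
#' with `reference_sd` noise and no class effect. Draws beyond
#' `censor_beyond` are emitted as undetermined wells (censoring is applied
#' after noise, so "Undetermined" lands exactly where true signal is
#' weakest). Fully reproducible from `cfg$seed`.
#'
#' @param panel a [marker_panel()].
#' @param cfg a [simulation_config()].
#' @return A list with components `ct` (a [ct_matrix()] with censoring
#'   mask), `labels` (named character vector), and `informative`
#'   (the informative marker names, the simulation's ground truth).
#' @export
simulate_cohort <- function(panel, cfg) {
  stopifnot(inherits(panel, "marker_panel"),
            inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  markers <- panel_markers(panel)

  informative <- cfg$informative_markers
  if (is.numeric(informative)) {
    if (informative > length(markers))
      stop("more informative markers requested than panel markers")
    informative <- sort(sample.int(length(markers), informative))
    informative <- markers[informative]
  } else {
    bad <- setdiff(informative, markers)
    if (length(bad) > 0)
      stop("informative marker(s) not in panel: ", paste(bad, collapse = ", "))
  }
  signs <- stats::setNames(rep_len(cfg$effect_sign, length(informative)),
                           informative)

  # per-assay generative means
  baseline <- stats::setNames(
    stats::runif(length(markers), cfg$baseline_ct_range[1],
                 cfg$baseline_ct_range[2]), markers)
  refs <- panel$gene_name[panel$role == "reference"]
  ref_ct <- cfg$reference_ct %||%
    stats::setNames(seq(15, 26, length.out = max(length(refs), 2))[
      seq_along(refs)], refs)
  ctrl <- panel$gene_name[panel$role == "internal_control"]
  ctrl_ct <- stats::setNames(rep(12, length(ctrl)), ctrl)

  fractions <- c(stats::setNames(c(1, 0),
                                 c(cfg$positive_class, cfg$negative_class)),
                 cfg$class_shift_fraction %||% numeric(0))
  defaults <- default_shift_fractions()

  classes <- names(cfg$n_per_class)
  labels <- rep(classes, cfg$n_per_class)
  sample_ids <- sprintf("%s_%02d", labels,
                        unlist(lapply(cfg$n_per_class, seq_len)))
  names(labels) <- sample_ids

  n <- length(sample_ids)
  assays <- panel$gene_name
  ct <- matrix(NA_real_, length(assays), n,
               dimnames = list(assays, sample_ids))
  for (j in seq_len(n)) {
    y <- labels[j]
    f <- if (y %in% names(fractions)) fractions[[y]]
         else if (y %in% names(defaults)) defaults[[y]]
         else stop("no signature fraction known for class '", y, "'")
    shifted <- informative[seq_len(ceiling(f * length(informative)))]
    mu <- numeric(length(assays))
    names(mu) <- assays
    mu[markers] <- baseline
    mu[shifted] <- mu[shifted] + cfg$effect_size * signs[shifted]
    mu[refs] <- ref_ct[refs]
    mu[ctrl] <- ctrl_ct[ctrl]
    sd_assay <- ifelse(assays %in% c(refs, ctrl), cfg$reference_sd,
                       cfg$noise_sd)
    ct[, j] <- stats::rnorm(length(assays), mu, sd_assay)
  }
  undet <- ct > cfg$censor_beyond
  ct[undet] <- NA_real_
  list(ct = ct_matrix(ct, undet, max_cycles = cfg$censor_beyond),
       labels = labels,
       informative = informative)
}

#' Write a simulated cohort to disk
#'
#' Writes the Ct table (`ct_table.tsv`) and the annotation table
#' (`annotations.tsv`) in the pipeline's table dialects; the pair
#' round-trips losslessly through [read_ct_table()] and
#' [read_annotations()].
#'
#' @param m a [ct_matrix()].
#' @param labels named character vector (sample id -> diagnosis).
#' @param dir output directory (created if needed).
#' @return Named character vector of the two file paths, invisibly.
#' @export
write_cohort <- function(m, labels, dir) {
  stopifnot(inherits(m, "ct_matrix"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory ", dir)
  ct_path <- file.path(dir, "ct_table.tsv")
  ann_path <- file.path(dir, "annotations.tsv")
  write_ct_table(m, ct_path)
  write_annotations(labels, ann_path)
  invisible(c(ct = ct_path, annotations = ann_path))
}
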