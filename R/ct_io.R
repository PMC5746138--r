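#' Raw Ct matrix with censoring mask
#'
#' Container for raw cycle-threshold values (assays x samples) together with
#' a logical mask of "Undetermined" wells, i.e. wells that never crossed the
#' fluorescence threshold within the run's cycle cap.
#'
#' @param ct numeric matrix, assays in rows, samples in columns, with
#'   dimnames.
#' @param undetermined logical matrix of the same shape; `TRUE` marks a
#'   censored well whose `ct` entry carries no meaning until imputation.
#' @param max_cycles cycle cap of the qPCR protocol (default 40); determined
#'   Ct values must lie in `(0, max_cycles]`.
#' @return An object of class `ct_matrix`.
#' @seealso [read_ct_table()], [impute_undetermined()], [normalize_delta_ct()]
#' @export
ct_matrix <- function(ct, undetermined = NULL, max_cycles = 40) {
  ct <- as.matrix(ct)
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("ct matrix needs assay rownames and sample colnames")
  if (is.null(undetermined))
    undetermined <- matrix(FALSE, nrow(ct), ncol(ct), dimnames = dimnames(ct))
  undetermined <- as.matrix(undetermined)
  if (!identical(dim(ct), dim(undetermined)))
    stop("ct and undetermined mask dimensions differ")
  det <- ct[!undetermined]
  if (any(!is.finite(det)))
    stop("non-finite Ct value in a determined well")
  if (any(det <= 0 | det > max_cycles))
    stop("determined Ct values must lie in (0, ", max_cycles, "]")
  structure(list(ct = ct, undetermined = undetermined,
                 max_cycles = max_cycles),
            class = "ct_matrix")
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat("<ct_matrix> ", nrow(x$ct), " assays x ", ncol(x$ct), " samples; ",
      sum(x$undetermined), " undetermined well(s); cycle cap ",
      x$max_cycles, "\n", sep = "")
  invisible(x)
}

#' Read a raw Ct table
#'
#' Reads a TSV/CSV table with assays in rows (first column = assay name) and
#' samples in columns. Cells are Ct numerals or the token `"Undetermined"`
#' for censored wells. The result is restricted to the panel's assays and
#' reordered to panel order.
#'
#' @param table_path path to the Ct table.
#' @param panel a [marker_panel()]; all panel assays must be present.
#' @param max_cycles cycle cap (default 40).
#' @return A [ct_matrix()].
#' @export
read_ct_table <- function(table_path, panel, max_cycles = 40) {
  stopifnot(inherits(panel, "marker_panel"))
  tab <- read_delim_table(table_path)
  assays <- tab[[1]]
  missing <- setdiff(panel$gene_name, assays)
  if (length(missing) > 0)
    stop("panel assay(s) missing from Ct table: ",
         paste(missing, collapse = ", "))
  tab <- tab[match(panel$gene_name, assays), -1, drop = FALSE]
  samples <- colnames(tab)
  cells <- as.matrix(tab)
  undet <- cells == "Undetermined"
  ct <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(!undet & is.na(ct), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-numeric Ct cell at assay '", panel$gene_name[bad[1, 1]],
         "', sample '", samples[bad[1, 2]], "': \"",
         cells[bad[1, , drop = FALSE]], "\"")
  ct[undet] <- NA_real_
  dimnames(ct) <- dimnames(undet) <- list(panel$gene_name, samples)
  ct_matrix(ct, undet, max_cycles = max_cycles)
}

#' Write a raw Ct table
#'
#' Inverse of [read_ct_table()]: censored wells are written as the token
#' `"Undetermined"`, determined wells with 6 decimal places.
#'
#' @param m a [ct_matrix()].
#' @param path output file; `.csv` extension selects comma, anything else tab.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(m, path) {
  stopifnot(inherits(m, "ct_matrix"))
  cells <- matrix(sprintf("%.6f", m$ct), nrow(m$ct), ncol(m$ct))
  cells[m$undetermined] <- "Undetermined"
  out <- data.frame(assay = rownames(m$ct), cells, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out) <- c("assay", colnames(m$ct))
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Impute censored wells at the cycle cap
#'
#' Replaces every undetermined well by `max_cycles` and clears the mask.
#' "Undetermined" means no amplification within the protocol's cycle count,
#' so the cap is the natural censoring value: it places the well at the
#' lowest observable expression.
#'
#' @param m a [ct_matrix()].
#' @param max_cycles imputation value (default the matrix's own cycle cap).
#' @return A fully determined [ct_matrix()].
#' @export
impute_undetermined <- function(m, max_cycles = m$max_cycles) {
  stopifnot(inherits(m, "ct_matrix"))
  ct <- m$ct
  ct[m$undetermined] <- max_cycles
  ct_matrix(ct, NULL, max_cycles = max_cycles)
}

#' Normalized delta-Ct dataset
#'
#' The unit of all downstream statistics: a markers x samples matrix of
#' delta-Ct values (marker Ct minus the mean Ct of the same-chemistry
#' reference assays in the same sample; higher delta-Ct = lower expression),
#' plus optional diagnosis labels and the two diagnostic classes.
#'
#' @param dct numeric matrix, markers x samples, finite, with dimnames.
#' @param labels optional named character vector mapping sample id to
#'   diagnosis label.
#' @param positive_class label treated as malignant (default `"PDAC"`).
#' @param negative_class label treated as benign (default `"CP"`).
#' @return An object of class `delta_ct_dataset`.
#' @export
delta_ct_dataset <- function(dct, labels = NULL,
                             positive_class = "PDAC", negative_class = "CP") {
  dct <- as.matrix(dct)
  if (is.null(rownames(dct)) || (ncol(dct) > 0 && is.null(colnames(dct))))
    stop("dct matrix needs marker rownames and sample colnames")
  if (any(!is.finite(dct)))
    stop("delta-Ct matrix must be finite everywhere (impute censored wells ",
         "before normalization)")
  if (!is.null(labels)) {
    labels <- labels[colnames(dct)]
    if (anyNA(labels))
      stop("label missing for sample(s): ",
           paste(colnames(dct)[is.na(labels)], collapse = ", "))
    names(labels) <- colnames(dct)
  }
  structure(list(dct = dct, labels = labels,
                 positive_class = positive_class,
                 negative_class = negative_class),
            class = "delta_ct_dataset")
}

#' @export
print.delta_ct_dataset <- function(x, ...) {
  cat("<delta_ct_dataset> ", nrow(x$dct), " markers x ", ncol(x$dct),
      " samples", sep = "")
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("; labels: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Chemistry-aware delta-Ct normalization
#'
#' For each sample and each marker of chemistry c,
#' `dCt = Ct(marker) - mean(Ct of reference assays of chemistry c)`.
#' mRNA and miRNA assays are normalized strictly separately against their own
#' reference sets; the internal control participates in neither mean.
#' References and the internal control are consumed and dropped: the output
#' contains marker assays only, in panel order.
#'
#' @param m a fully imputed [ct_matrix()] (hard error otherwise).
#' @param panel the [marker_panel()] that defines roles and chemistries.
#' @param labels,positive_class,negative_class passed to
#'   [delta_ct_dataset()].
#' @return A [delta_ct_dataset()].
#' @export
normalize_delta_ct <- function(m, panel, labels = NULL,
                               positive_class = "PDAC",
                               negative_class = "CP") {
  stopifnot(inherits(m, "ct_matrix"), inherits(panel, "marker_panel"))
  if (any(m$undetermined))
    stop("Ct matrix contains undetermined wells; run impute_undetermined() ",
         "before normalization")
  missing <- setdiff(panel$gene_name, rownames(m$ct))
  if (length(missing) > 0)
    stop("panel assay(s) missing from Ct matrix: ",
         paste(missing, collapse = ", "))
  ct <- m$ct[panel$gene_name, , drop = FALSE]
  marker_rows <- which(panel$role == "marker")
  dct <- ct[marker_rows, , drop = FALSE]
  for (chem in unique(panel$chemistry[marker_rows])) {
    refs <- panel_references(panel, chem)
    ref_mean <- colMeans(ct[refs, , drop = FALSE])
    rows <- panel$chemistry[marker_rows] == chem
    dct[rows, ] <- sweep(dct[rows, , drop = FALSE], 2, ref_mean, "-")
  }
  delta_ct_dataset(dct, labels = labels, positive_class = positive_class,
                   negative_class = negative_class)
}

#' Write / read a delta-Ct table
#'
#' Markers x samples TSV (or CSV by extension) with 6 decimal places;
#' reading a written table reproduces the values bit-identically at that
#' precision.
#'
#' @param ds a [delta_ct_dataset()].
#' @param path file path.
#' @return `write_delta_ct`: `path` invisibly; `read_delta_ct`: a
#'   [delta_ct_dataset()] (unlabeled unless `labels` is supplied).
#' @export
write_delta_ct <- function(ds, path) {
  stopifnot(inherits(ds, "delta_ct_dataset"))
  cells <- matrix(sprintf("%.6f", ds$dct), nrow(ds$dct), ncol(ds$dct))
  out <- data.frame(marker = rownames(ds$dct), cells, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out) <- c("marker", colnames(ds$dct))
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_delta_ct
#' @param labels,positive_class,negative_class passed to
#'   [delta_ct_dataset()].
#' @export
read_delta_ct <- function(path, labels = NULL,
                          positive_class = "PDAC", negative_class = "CP") {
  tab <- read_delim_table(path)
  markers <- tab[[1]]
  cells <- as.matrix(tab[, -1, drop = FALSE])
  dct <- array(as.numeric(cells), dim = dim(cells),
               dimnames = list(markers, colnames(cells)))
  if (anyNA(dct)) stop("non-numeric cell in delta-Ct table ", path)
  delta_ct_dataset(dct, labels = labels, positive_class = positive_class,
                   negative_class = negative_class)
}

#' Read / write a sample annotation table
#'
#' Two-column TSV/CSV with header `sample_id,diagnosis`.
#'
#' @param path file path.
#' @return `read_annotations`: named character vector (sample id ->
#'   diagnosis); `write_annotations`: `path` invisibly.
#' @export
read_annotations <- function(path) {
  tab <- read_delim_table(path)
  if (!all(c("sample_id", "diagnosis") %in% names(tab)))
    stop("annotation table must have columns sample_id, diagnosis")
  stats::setNames(as.character(tab$diagnosis), as.character(tab$sample_id))
}

#' @rdname read_annotations
#' @param labels named character vector (sample id -> diagnosis).
#' @export
write_annotations <- function(labels, path) {
  out <- data.frame(sample_id = names(labels) %||% character(0),
                    diagnosis = unname(labels),
                    stringsAsFactors = FALSE)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a delta-Ct dataset to samples and/or markers
#'
#' @param ds a [delta_ct_dataset()].
#' @param samples sample ids to keep (default all).
#' @param markers marker names to keep, in the dataset's order
#'   (default all).
#' @return A [delta_ct_dataset()].
#' @export
subset_dataset <- function(ds, samples = NULL, markers = NULL) {
  stopifnot(inherits(ds, "delta_ct_dataset"))
  dct <- ds$dct
  if (!is.null(markers)) {
    missing <- setdiff(markers, rownames(dct))
    if (length(missing) > 0)
      stop("unknown marker(s): ", paste(missing, collapse = ", "))
    dct <- dct[rownames(dct)[rownames(dct) %in% markers], , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(dct))
    if (length(missing) > 0)
      stop("unknown sample(s): ", paste(missing, collapse = ", "))
    dct <- dct[, samples, drop = FALSE]
  }
  delta_ct_dataset(dct,
                   labels = if (!is.null(ds$labels)) ds$labels[colnames(dct)],
                   positive_class = ds$positive_class,
                   negative_class = ds$negative_class)
}
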