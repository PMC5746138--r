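#' Marker panel definition
#'
#' A `marker_panel` describes the assay roster of a mixed-chemistry TaqMan
#' array: one row per reaction chamber, with the assay name, its role
#' (`marker`, `reference`, or `internal_control`) and its chemistry (`mRNA`
#' or `miRNA`). Row order is the physical panel order and is preserved
#' throughout the pipeline; it is the deterministic tie-break for marker
#' rankings.
#'
#' @param entries a data.frame with columns `gene_name`, `role`, `chemistry`.
#' @return An object of class `marker_panel` (a validated data.frame).
#' @details Invariants enforced: assay names unique; every chemistry that has
#'   marker assays also has at least one reference assay of the same
#'   chemistry (reference averaging is per-chemistry); roles and chemistries
#'   restricted to the allowed vocabularies.
#' @seealso [load_panel()], [default_panel()]
#' @export
marker_panel <- function(entries) {
  required <- c("gene_name", "role", "chemistry")
  if (!all(required %in% names(entries)))
    stop("panel table must have columns: ", paste(required, collapse = ", "))
  entries <- as.data.frame(entries)[, required]
  entries$gene_name <- as.character(entries$gene_name)
  entries$role <- normalize_role(entries$role)
  entries$chemistry <- as.character(entries$chemistry)

  bad_chem <- setdiff(unique(entries$chemistry), c("mRNA", "miRNA"))
  if (length(bad_chem) > 0)
    stop("unknown chemistry token(s): ", paste(bad_chem, collapse = ", "))
  dup <- entries$gene_name[duplicated(entries$gene_name)]
  if (length(dup) > 0)
    stop("duplicate assay name(s): ", paste(unique(dup), collapse = ", "))
  for (chem in unique(entries$chemistry[entries$role == "marker"])) {
    if (!any(entries$role == "reference" & entries$chemistry == chem))
      stop("chemistry '", chem, "' has markers but no reference assay")
  }
  rownames(entries) <- NULL
  structure(entries, class = c("marker_panel", "data.frame"))
}

normalize_role <- function(role) {
  canon <- tolower(gsub("[ -]", "_", trimws(as.character(role))))
  allowed <- c("marker", "reference", "internal_control")
  bad <- setdiff(unique(canon), allowed)
  if (length(bad) > 0)
    stop("unknown role token(s): ", paste(bad, collapse = ", "))
  canon
}

#' Read a marker panel from a delimited table
#'
#' Reads a TSV/CSV panel definition with header
#' `gene_name,role,chemistry` (delimiter auto-detected between tab and
#' comma), preserving row order.
#'
#' @param table_path path to the panel table.
#' @return A [marker_panel()].
#' @export
load_panel <- function(table_path) {
  marker_panel(read_delim_table(table_path))
}

#' The packaged 96-assay mixed miRNA/mRNA panel
#'
#' Returns the panel shipped with the package: 79 mRNA markers, 5 mRNA
#' reference genes (RPLP0, PPIA, RPL37A, RPL30, RPS17), 9 miRNA markers,
#' 2 small-RNA reference genes (RNU44, RNU48) and the 18S-rRNA internal
#' control -- 96 assays in total, one per reaction chamber of the array
#' card. The internal control takes part in no reference mean.
#'
#' @return A [marker_panel()] with 96 rows.
#' @export
default_panel <- function() {
  load_panel(system.file("extdata", "panel_table1.tsv", package = "ctpanel",
                         mustWork = TRUE))
}

#' Marker names of a panel
#'
#' @param panel a [marker_panel()].
#' @param chemistry optional chemistry filter (`"mRNA"` or `"miRNA"`).
#' @return Character vector of assay names with role `marker`, in panel order.
#' @export
panel_markers <- function(panel, chemistry = NULL) {
  stopifnot(inherits(panel, "marker_panel"))
  keep <- panel$role == "marker"
  if (!is.null(chemistry)) keep <- keep & panel$chemistry == chemistry
  panel$gene_name[keep]
}

#' Reference assay names of a panel for one chemistry
#'
#' @param panel a [marker_panel()].
#' @param chemistry `"mRNA"` or `"miRNA"`.
#' @return Character vector of reference assay names, in panel order.
#' @export
panel_references <- function(panel, chemistry) {
  stopifnot(inherits(panel, "marker_panel"))
  panel$gene_name[panel$role == "reference" & panel$chemistry == chemistry]
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("<marker_panel> ", nrow(x), " assays: ",
      sum(x$role == "marker"), " markers, ",
      sum(x$role == "reference"), " references, ",
      sum(x$role == "internal_control"), " internal control(s)\n", sep = "")
  tab <- table(chemistry = x$chemistry, role = x$role)
  print(tab)
  invisible(x)
}
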