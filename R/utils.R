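#' @keywords internal
"_PACKAGE"

# Detect the field delimiter of a delimited text file from its header line.
# Tab wins over comma so that assay names containing commas (multi-target
# assays such as "ELA3A,ELA3B") survive round-tripping.
detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

read_delim_table <- function(path) {
  utils::read.table(path, sep = detect_delim(path), header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character", quote = "\"",
                    comment.char = "", na.strings = NULL)
}

# Deterministic expansion of one user-facing seed into independent
# sub-stream seeds (per CV run, per searched subset, ...). Plain integer
# hashing keeps everything below 2^31 and independent of execution order.
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(stream) * 16807
  as.integer(s %% 2147483629) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
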