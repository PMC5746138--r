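panel2 <- marker_panel(data.frame(
  gene_name = c("M1", "M2", "CTRL", "R1", "R2", "mir-A", "RNU"),
  role = c("marker", "marker", "internal_control", "reference", "reference",
           "marker", "reference"),
  chemistry = c("mRNA", "mRNA", "mRNA", "mRNA", "mRNA", "miRNA", "miRNA")))

write_ct_fixture <- function(cells, path, assays = panel2$gene_name,
                             samples = c("s1", "s2")) {
  tab <- data.frame(assay = assays, cells, stringsAsFactors = FALSE)
  colnames(tab) <- c("assay", samples)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("read_ct_table parses numerals and Undetermined, enforces range", {
  path <- withr::local_tempfile(fileext = ".tsv")
  cells <- matrix("25.0", 7, 2)
  cells[1, 2] <- "Undetermined"
  write_ct_fixture(cells, path)
  m <- read_ct_table(path, panel2)
  expect_equal(dim(m$ct), c(7L, 2L))
  expect_true(m$undetermined["M1", "s2"])
  expect_true(is.na(m$ct["M1", "s2"]))
  expect_equal(sum(m$undetermined), 1)

  cells[1, 2] <- "41.2"
  write_ct_fixture(cells, path)
  expect_error(read_ct_table(path, panel2), "\\(0, 40\\]")

  cells[1, 2] <- "n/a"
  write_ct_fixture(cells, path)
  expect_error(read_ct_table(path, panel2), "M1.*s2")

  write_ct_fixture(matrix("25.0", 6, 2), path, assays = panel2$gene_name[-3])
  expect_error(read_ct_table(path, panel2), "CTRL")
})

test_that("imputation replaces censored wells by the cycle cap", {
  ct <- matrix(c(30, 20, 22, NA, 21, 14, 35, NA, NA, NA, NA, NA, NA, NA),
               7, 2, dimnames = list(panel2$gene_name, c("s1", "s2")))
  undet <- is.na(ct)
  m <- ct_matrix(ct, undet)
  imp <- impute_undetermined(m)
  expect_false(any(imp$undetermined))
  expect_equal(imp$ct["R1", "s1"], 40)
  expect_equal(unname(imp$ct[, "s2"]), rep(40, 7))  # all-undetermined sample
  # no-op on a fully determined matrix
  full <- ct_matrix(matrix(25, 7, 2,
                           dimnames = list(panel2$gene_name, c("s1", "s2"))))
  expect_equal(impute_undetermined(full)$ct, full$ct)
})

test_that("delta-Ct normalization subtracts the chemistry-matched reference mean", {
  # sample s1: mRNA refs {20, 22} -> mean 21; miRNA ref {15}
  ct <- matrix(c(21, 30, 10, 20, 22, 18, 15,
                 25, 25, 11, 24, 26, 20, 16),
               7, 2, dimnames = list(panel2$gene_name, c("s1", "s2")))
  ds <- normalize_delta_ct(ct_matrix(ct), panel2)
  expect_equal(rownames(ds$dct), c("M1", "M2", "mir-A"))  # markers only
  expect_equal(ds$dct["M1", "s1"], 0)     # marker equals reference mean
  expect_equal(ds$dct["M2", "s1"], 9)     # 30 - 21
  expect_equal(ds$dct["mir-A", "s1"], 3)  # own chemistry: 18 - 15, not pooled
  expect_equal(ds$dct["mir-A", "s2"], 4)
  # the internal control influences no reference mean: change it, nothing moves
  ct2 <- ct; ct2["CTRL", ] <- c(39, 39)
  expect_equal(normalize_delta_ct(ct_matrix(ct2), panel2)$dct, ds$dct)
  # unimputed input is a hard error
  undet <- matrix(FALSE, 7, 2, dimnames = dimnames(ct))
  undet["M1", "s1"] <- TRUE
  expect_error(normalize_delta_ct(ct_matrix(ct, undet), panel2),
               "impute_undetermined")
})

test_that("per-sample constant Ct offsets cancel in delta-Ct", {
  d <- quick_dataset(seed = 3)
  sim <- simulate_cohort(tiny_panel(), simulation_config(
    n_per_class = c(PDAC = 12, CP = 10), informative_markers = 2, seed = 3))
  m <- impute_undetermined(sim$ct)
  shifted <- m$ct - matrix(rep(seq(0.5, by = 0.05,
                                   length.out = ncol(m$ct)),
                               each = nrow(m$ct)), nrow(m$ct))
  ds_shift <- normalize_delta_ct(ct_matrix(shifted), tiny_panel())
  expect_equal(ds_shift$dct, d$ds$dct, tolerance = 1e-12)
})

test_that("delta-Ct tables round-trip bit-identically at 6 decimals", {
  d <- quick_dataset(seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_delta_ct(d$ds, path)
  back <- read_delta_ct(path)
  expect_equal(back$dct, d$ds$dct, tolerance = 1e-6)
  # writing what was read reproduces the file byte-for-byte
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_delta_ct(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("annotations round-trip and accept both delimiters", {
  labels <- c(a = "PDAC", b = "CP", c = "IPMN")
  for (ext in c(".tsv", ".csv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_annotations(labels, path)
    expect_identical(read_annotations(path), labels)
  }
  # empty label map -> header-only file
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(character(0), path)
  expect_equal(readLines(path), "sample_id\tdiagnosis")
})
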