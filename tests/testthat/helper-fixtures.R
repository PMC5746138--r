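# Shared fixtures: panels and cohorts are always built in code.

# A small but structurally complete panel: both chemistries, references and
# an internal control, in a fixed order.
tiny_panel <- function(n_mrna = 4, n_mirna = 2) {
  entries <- rbind(
    data.frame(gene_name = sprintf("G%02d", seq_len(n_mrna)),
               role = "marker", chemistry = "mRNA"),
    data.frame(gene_name = "CTRL-18S", role = "internal_control",
               chemistry = "mRNA"),
    data.frame(gene_name = c("REF1", "REF2"), role = "reference",
               chemistry = "mRNA"),
    data.frame(gene_name = sprintf("mir-%d", seq_len(n_mirna)),
               role = "marker", chemistry = "miRNA"),
    data.frame(gene_name = "RNU", role = "reference", chemistry = "miRNA"))
  marker_panel(entries)
}

# A labeled delta-Ct dataset simulated from a panel, already normalized.
quick_dataset <- function(panel = tiny_panel(), seed = 1, n_pos = 12,
                          n_neg = 10, effect = 2, noise = 0.75,
                          informative = 2) {
  cfg <- simulation_config(n_per_class = c(PDAC = n_pos, CP = n_neg),
                           informative_markers = informative,
                           effect_size = effect, noise_sd = noise,
                           seed = seed)
  sim <- simulate_cohort(panel, cfg)
  list(ds = normalize_delta_ct(impute_undetermined(sim$ct), panel,
                               labels = sim$labels),
       informative = sim$informative)
}

# Independent oracle for the threshold scores: enumerate every labeled
# threshold classifier explicitly (predict, then count), with no shared
# code with the package's scan.
brute_threshold <- function(values, labels, positive_class,
                            objective = c("balanced", "accuracy")) {
  objective <- match.arg(objective)
  v <- sort(unique(values))
  cuts <- c(min(v) - 1, if (length(v) > 1) (v[-length(v)] + v[-1]) / 2,
            max(v) + 1)
  truth_pos <- labels == positive_class
  best <- -Inf
  for (t in cuts) {
    for (orient in c("positive_above", "positive_below")) {
      call_pos <- if (orient == "positive_above") values > t else values < t
      sens <- sum(call_pos & truth_pos) / sum(truth_pos)
      spec <- sum(!call_pos & !truth_pos) / sum(!truth_pos)
      obj <- if (objective == "balanced") (sens + spec) / 2
             else mean(call_pos == truth_pos)
      if (obj > best) best <- obj
    }
  }
  best
}
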