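# Shared fixtures, built in code at test time.

# A small loxP config with fixed flanks, distinct in their first/last 3
# bases next to the core.
toy_loxp_config <- function(...) {
  loxp_config(
    flank_5prime_up   = "GATTACAGATTACAGATTACAGATTACAGATTA",  # A
    flank_5prime_down = "CCGGTTAACCGGTTAACCGGTTAACCGGTTAAC",  # B
    flank_3prime_up   = "TTGACCATTGACCATTGACCATTGACCATTGAC",  # C
    flank_3prime_down = "AGGCATTAGGCATTAGGCATTAGGCATTAGGCA",  # D
    ...
  )
}

# Build a single junction read: n flank bases either side of the core.
junction_read <- function(config, up, down, n_up = 3, n_down = 3) {
  paste0(
    substring(up, nchar(up) - n_up + 1L),
    config$core,
    substring(down, 1L, n_down)
  )
}

# Rank-based AUC of score for separating truth (logical) positives.
rank_auc <- function(score, positive) {
  r <- rank(score)
  (mean(r[positive]) - (sum(positive) + 1) / 2) / sum(!positive)
}

# Planted-signature count simulation used by several tests.
planted_counts_sim <- function(n_genes = 300, n_cells = 600,
                               sig_genes = 1:50, log2fc = 1,
                               cv = 0.55, seed = 3) {
  simulate_count_matrix(counts_spec(
    n_genes = n_genes, n_cells = n_cells, biological_cv = cv,
    type_proportions = c(background = 0.8, planted = 0.2),
    planted_signatures = list(
      list(cell_type = "planted", genes = sig_genes, log2fc = log2fc)
    ),
    seed = seed
  ))
}
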