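# Planted-structure recovery measurements shared by the property tests
# and the acceptance suite. Each takes a simulated bundle and compares a
# pipeline result against the generator's truth.

# Specificity of the cis screen: fraction of beta_cna = 0 genes NOT
# flagged cis-driven. Returns c(true_neg, n_null).
cis_screen_specificity <- function(bundle, r_min = 0.65, alpha = 1e-4) {
  scr <- cna_mrna_screen(bundle$cna, bundle$mrna, r_min = r_min,
                         alpha = alpha)
  null_genes <- names(bundle$truth$beta_cna)[bundle$truth$beta_cna == 0]
  flagged <- scr$gene[scr$cis_driven]
  c(true_neg = sum(!null_genes %in% flagged), n_null = length(null_genes))
}

# Default fixture plus a third, "passenger" amplification segment whose
# genes gain copies with no dosage effect (beta = 0): the condition under
# which cis-screen specificity is a non-trivial measurement.
passenger_config <- function(seed) {
  sim_config(seed = seed, amp_segments = list(
    list(bands = 1L, p_amp = 0.5, gain = 2),
    list(bands = 5L, p_amp = 0.5, gain = 2),
    list(bands = 7L, p_amp = 0.5, gain = 2, beta = 0)))
}

# Mean Jaccard between each planted block and the recovered cluster
# containing its seed (first member), using the default thresholds.
block_recovery_jaccard <- function(bundle, r_min = 0.6, max_gap = 0L) {
  vapply(bundle$truth$blocks, function(blk) {
    seed <- blk$genes[1L]
    prof <- seed_profile(bundle$mrna, seed)
    sig <- union(threshold_profile(prof, r_min), seed)
    cl <- adjacency_clusters(sig, bundle$annotation, max_gap = max_gap)
    hit <- which(vapply(cl$members, function(m) seed %in% m, logical(1)))
    if (length(hit) == 0) return(0)
    rec <- cl$members[[hit[1L]]]
    length(intersect(rec, blk$genes)) / length(union(rec, blk$genes))
  }, numeric(1))
}

# TRUE iff every planted divergent pair (and nothing overlapping it) is
# flagged bidirectional.
divergent_pairs_recovered <- function(bundle, max_dist = 1000L) {
  pp <- find_bidirectional_pairs(bundle$annotation, max_dist)
  flagged <- pp[pp$bidirectional, c("gene_left", "gene_right")]
  planted <- do.call(rbind, lapply(bundle$truth$divergent_pairs,
                                   function(dp)
    data.frame(gene_left = dp$gene_left, gene_right = dp$gene_right,
               stringsAsFactors = FALSE)))
  nrow(flagged) == nrow(planted) &&
    all(paste(flagged$gene_left, flagged$gene_right) %in%
          paste(planted$gene_left, planted$gene_right))
}

# TRUE iff every planted shared-miRNA pair passes the ceRNA call at the
# default thresholds.
cerna_pairs_recovered <- function(bundle, ...) {
  tgt_pairs <- unique(t(vapply(bundle$truth$mirna_links,
                               function(ml) sort(ml$targets)[1:2],
                               character(2))))
  cand <- cerna_candidates(tgt_pairs, bundle$mirna_sets, bundle$mrna,
                           bundle$mirna, ...)
  all(cand$verdict)
}
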