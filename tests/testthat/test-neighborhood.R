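test_that("seed profile has identity self-entry and honors thresholding", {
  set.seed(31)
  m <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  prof <- seed_profile(m, "g3")
  expect_equal(prof$r[prof$gene == "g3"], 1)
  expect_equal(nrow(prof), 5L)
  expect_error(seed_profile(m, "nope"), "not in expression")

  prof$r <- c(0.7, 0.59, 1, 0.6, -0.2)
  expect_setequal(threshold_profile(prof, 0.6), c("g1", "g4"))  # inclusive
  expect_length(threshold_profile(prof, 1.01), 0L)
})

test_that("band fractions match exhaustive hypergeometric enumeration", {
  bands <- cytoband_map(chrom = "chr1", start = c(0, 1000),
                        end = c(1000, 2000), name = c("b1", "b2"))
  ann <- assign_cytobands(
    gene_annotation(gene_id = sprintf("g%d", 1:10), chrom = "chr1",
                    start = c(seq(0, 800, length.out = 5),
                              seq(1000, 1800, length.out = 5)),
                    end = c(seq(0, 800, length.out = 5),
                            seq(1000, 1800, length.out = 5)) + 50,
                    strand = "+"), bands)
  bf <- band_fractions(sprintf("g%d", 1:4), ann)
  b1 <- bf[bf$band == "b1", ]
  expect_equal(b1$fraction, 0.8)
  expect_equal(b1$p_value, 5 / 210)  # C(5,4) C(5,0) / C(10,4)
  expect_equal(b1$p_value, oracle_hyper_upper(4, 5, 10, 4))
  expect_equal(sum(bf$n_total), 10L)

  empty <- band_fractions(character(0), ann)
  expect_true(all(empty$fraction == 0))
  expect_true(all(empty$p_value == 1))
})

test_that("adjacency clustering reproduces the hand-enumerated scans", {
  ann <- toy_annotation(10)
  sig <- c("g2", "g3", "g4", "g7", "g8")
  cl0 <- adjacency_clusters(sig, ann, max_gap = 0)
  expect_equal(cl0$members, list(c("g2", "g3", "g4"), c("g7", "g8")))
  cl2 <- adjacency_clusters(sig, ann, max_gap = 2)
  expect_equal(cl2$members, list(sig))
  expect_equal(cl2$size, 5L)
  # min_size filtering
  cl_min <- adjacency_clusters(c("g1", "g5", "g6"), ann, min_size = 2)
  expect_equal(cl_min$members, list(c("g5", "g6")))
  # invariant to input ordering
  expect_equal(adjacency_clusters(rev(sig), ann)$members, cl0$members)
})

test_that("clusters are disjoint, ordered, and shrink as r_min rises", {
  b <- simulate_bundle(sim_config(seed = 77))
  seed <- b$truth$blocks[[1L]]$genes[1L]
  prof <- seed_profile(b$mrna, seed)
  for (r_min in c(0.4, 0.6)) {
    sig <- union(threshold_profile(prof, r_min), seed)
    cl <- adjacency_clusters(sig, b$annotation, profile = prof)
    mem <- unlist(cl$members)
    expect_equal(anyDuplicated(mem), 0L)
    # concatenation preserves annotation order
    expect_identical(mem, b$annotation$gene_id[b$annotation$gene_id %in%
                                                 mem])
  }
  lo <- adjacency_clusters(union(threshold_profile(prof, 0.4), seed),
                           b$annotation)
  hi <- adjacency_clusters(union(threshold_profile(prof, 0.8), seed),
                           b$annotation)
  # monotone shrinkage: every high-threshold cluster lies inside some
  # low-threshold cluster
  for (m_hi in hi$members) {
    expect_true(any(vapply(lo$members, function(m_lo)
      all(m_hi %in% m_lo), logical(1))))
  }
})

test_that("planted blocks dominate their band and rank atop the profile", {
  top_band_ok <- vapply(1:10, function(s) {
    b <- simulate_bundle(sim_config(seed = 500 + s))
    blk <- b$truth$blocks[[1L]]
    seed <- blk$genes[1L]
    prof <- seed_profile(b$mrna, seed)
    # co-members occupy the top of the ranking (after the seed itself)
    ranked <- prof$gene[order(-prof$r)]
    co <- setdiff(blk$genes, seed)
    if (!all(co %in% ranked[2:(length(co) + 1L)])) return(FALSE)
    sig <- threshold_profile(prof, 0.6)
    bf <- band_fractions(sig, b$annotation)
    host <- unique(b$annotation$cytoband[b$annotation$gene_id %in%
                                           blk$genes])
    bf$band[which.min(bf$q_bh)] == host
  }, logical(1))
  expect_gte(mean(top_band_ok), 0.9)
})
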