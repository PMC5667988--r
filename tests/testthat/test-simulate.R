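test_that("genome layout honors spacers, bands and determinism", {
  cfg <- sim_config(seed = 11)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)

  dp <- g1$truth$divergent_pairs[[1L]]
  left <- g1$annotation[g1$annotation$gene_id == dp$gene_left, ]
  right <- g1$annotation[g1$annotation$gene_id == dp$gene_right, ]
  expect_equal(right$start - left$end, 89)
  expect_equal(left$strand, "-")
  expect_equal(right$strand, "+")

  expect_equal(nrow(g1$annotation), 60L)
  expect_false(anyNA(g1$annotation$cytoband))
  expect_identical(unname(g1$truth$band_truth[g1$annotation$gene_id]),
                   g1$annotation$cytoband)
  # genes laid out without overlap
  expect_true(all(g1$annotation$start[-1] >=
                    g1$annotation$end[-nrow(g1$annotation)]))
})

test_that("copy-number simulation hits its limiting cases and binomial rate", {
  base <- sim_config(seed = 3)
  g <- simulate_genome(base)

  cfg0 <- sim_config(seed = 3, amp_segments = list(
    list(bands = 1L, p_amp = 0, gain = 2)))
  cna0 <- simulate_cna(simulate_genome(cfg0)$truth, cfg0)
  expect_true(all(cna0 == 2))

  cfg1 <- sim_config(seed = 3, amp_segments = list(
    list(bands = 1L, p_amp = 1, gain = 2)))
  t1 <- simulate_genome(cfg1)$truth
  cna1 <- simulate_cna(t1, cfg1)
  expect_true(all(cna1[t1$segments[[1L]]$genes, ] == 4))
  outside <- setdiff(rownames(cna1), t1$segments[[1L]]$genes)
  expect_true(all(cna1[outside, ] == 2))

  cfgh <- sim_config(seed = 5, n_samples = 1000L, amp_segments = list(
    list(bands = 1L, p_amp = 0.5, gain = 2)))
  th <- simulate_genome(cfgh)$truth
  cnah <- simulate_cna(th, cfgh)
  frac <- mean(cnah[th$segments[[1L]]$genes[1L], ] > 2)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("noise-free expression is perfectly collinear with copy number", {
  cfg <- sim_config(seed = 9, noise_sd = 0, coexpr_blocks = list(),
                    mirna_links = list(), n_decoy_mirnas = 0L)
  g <- simulate_genome(cfg)
  cna <- simulate_cna(g$truth, cfg)
  ex <- simulate_expression(g$truth, cna, cfg)
  amp_gene <- g$truth$segments[[1L]]$genes[1L]
  expect_equal(cor(ex$mrna[amp_gene, ], cna[amp_gene, ]), 1)
  expect_equal(ex$mrna[amp_gene, ], cfg$mu +
                 g$truth$beta_cna[[amp_gene]] * (cna[amp_gene, ] - 2))
})

test_that("shared-miRNA coupling induces the model-implied correlations", {
  # two genes under one miRNA with gamma > 0: cov = gamma^2, var =
  # gamma^2 + sigma^2, so r = gamma^2 / (gamma^2 + sigma^2); each gene
  # vs the miRNA: r = -gamma / sqrt(gamma^2 + sigma^2). Checked by
  # Monte Carlo at n = 1e5.
  cfg <- sim_config(seed = 21, n_samples = 100000L, amp_segments = list(),
                    coexpr_blocks = list(),
                    mirna_links = list(list(mirna = "m1",
                                            targets = c(1L, 2L),
                                            gamma = 1,
                                            sources = "tarbase")),
                    n_decoy_mirnas = 0L)
  g <- simulate_genome(cfg)
  cna <- simulate_cna(g$truth, cfg)
  ex <- simulate_expression(g$truth, cna, cfg)
  r_pair <- cor(ex$mrna["G001", ], ex$mrna["G002", ])
  expect_lt(abs(r_pair - 0.5), 0.02)
  r_mir <- cor(ex$mrna["G001", ], ex$mirna["m1", ])
  expect_lt(abs(r_mir + 1 / sqrt(2)), 0.02)
})

test_that("planted blocks are tighter than background across seeds", {
  ok <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = 100 + s)
    b <- simulate_bundle(cfg)
    blk <- b$truth$blocks[[1L]]$genes
    bg <- setdiff(rownames(b$mrna), unlist(lapply(b$truth$blocks,
                                                  `[[`, "genes")))
    cm <- cor(t(b$mrna[c(blk, bg[1:10]), ]))
    within <- mean(cm[blk, blk][upper.tri(cm[blk, blk])])
    cross <- mean(cm[blk, bg[1:10]])
    within > cross
  }, logical(1))
  expect_true(all(ok))
})

test_that("fixture bundles round-trip through the readers and stay deterministic", {
  cfg <- sim_config(seed = 42)
  b <- simulate_bundle(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_fixture_bundle(b, d1)
  f2 <- write_fixture_bundle(simulate_bundle(cfg), d2)
  for (nm in names(f1)) {
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]),
                     info = nm)
  }
  expect_identical(read_omics_matrix(f1[["mrna"]]), b$mrna)
  expect_identical(read_omics_matrix(f1[["cna"]]), b$cna)
  expect_identical(read_omics_matrix(f1[["mirna"]]), b$mirna)
  ann <- read_gene_annotation(f1[["annotation"]], "bed")
  expect_identical(ann$start, b$annotation$start)
  expect_identical(ann$end, b$annotation$end)
  expect_identical(ann$strand, b$annotation$strand)

  # CpG-rich spacer satisfies its construction constraint
  sp <- read_fasta(f1[["spacers"]])
  isl <- cpg_island_scan(sp[[1L]], len_min = 50, window = 50)
  expect_gte(nrow(isl), 1L)

  truth <- jsonlite::read_json(f1[["truth"]], simplifyVector = TRUE)
  expect_setequal(unlist(lapply(b$truth$blocks, `[[`, "genes")),
                  unlist(lapply(truth$blocks[["genes"]], identity)))
})

test_that("parameter recovery: estimated cis correlation tracks the model", {
  # r_implied = beta * sd(cna) / sd(expr); with beta = 0.5, sigma = 1
  # the mean estimate across seeds must land within +/- 0.1 of the
  # population-implied value beta * 1 / sqrt(beta^2 + sigma^2)
  ests <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = 200 + s, beta_cna = 0.5,
                      coexpr_blocks = list(), mirna_links = list(),
                      n_decoy_mirnas = 0L)
    g <- simulate_genome(cfg)
    cna <- simulate_cna(g$truth, cfg)
    ex <- simulate_expression(g$truth, cna, cfg)
    gene <- g$truth$segments[[1L]]$genes[1L]
    pearson_cor(cna[gene, ], ex$mrna[gene, ])$r
  }, numeric(1))
  implied <- 0.5 * 1 / sqrt(0.5^2 + 1)  # sd(cna) = g * sqrt(p(1-p)) = 1
  expect_lt(abs(mean(ests) - implied), 0.1)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(amp_segments = list(
    list(bands = 1L, p_amp = 1.5, gain = 2))), "p_amp")
  expect_error(sim_config(coexpr_blocks = list(
    list(genes = c(1L, 3L), tau = 1))), "consecutive")
  expect_error(sim_config(divergent_pairs = list(
    list(genes = c(5L, 6L), spacer = 0, cpg_rich = FALSE))), "spacer")
  expect_error(sim_config(mirna_links = list(
    list(mirna = "m", targets = 999L, gamma = 1, sources = "s"))),
    "out of range")
})
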