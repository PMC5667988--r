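test_that("pearson_cor matches hand-evaluated and limiting cases", {
  x <- c(1, 5, 2, 9)
  expect_equal(pearson_cor(x, x)$r, 1)
  res <- pearson_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res$r, 0.6)  # sum of products 3, sums of squares 5 and 5
  expect_equal(res$n_used, 4L)
  # p from the exact t transform
  tt <- 0.6 * sqrt(2 / (1 - 0.36))
  expect_equal(res$p_value, 2 * pt(-tt, df = 2))
  # cross-check the single-pair route against stats::cor.test
  ct <- cor.test(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res$r, unname(ct$estimate))
  expect_equal(res$p_value, ct$p.value)
})

test_that("pearson_cor enforces its preconditions", {
  expect_error(pearson_cor(c(1, 1, 1, 1), c(1, 2, 3, 4)), "constant")
  expect_error(pearson_cor(c(1, 2), c(3, 4)), "insufficient")
  expect_error(pearson_cor(c(1, 2, NA, NA), c(NA, 2, 3, 4)),
               "insufficient")
  expect_error(pearson_cor(1:3, 1:4), "equal length")
})

test_that("missing values are deleted pairwise and n_used reported", {
  x <- c(1, 2, NA, 4, 5)
  y <- c(2, NA, 3, 8, 10)
  res <- pearson_cor(x, y)
  expect_equal(res$n_used, 3L)
  expect_equal(res$r, oracle_pearson(c(1, 4, 5), c(2, 8, 10)))
})

test_that("pearson properties: symmetry, affine invariance, oracle agreement", {
  set.seed(401)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    r1 <- pearson_cor(x, y)$r
    expect_identical(r1, pearson_cor(y, x)$r)
    expect_lt(abs(r1 - oracle_pearson(x, y)), 1e-12)
    expect_lt(abs(pearson_cor(2.5 * x + 7, y)$r - r1), 1e-12)
  }
})

test_that("correlate_rows aligns samples, computes BH and reports exclusions", {
  set.seed(7)
  m <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  self <- correlate_rows(m, m, pairing = "matched")
  expect_equal(self$r, rep(1, 4))

  # BH step-up on (0.01, 0.02, 0.03) gives q = 0.03 for all three
  p <- c(0.01, 0.02, 0.03)
  expect_equal(p.adjust(p, "BH"), rep(0.03, 3))
  # shuffled columns still align by sample id
  m2 <- m[, sample(colnames(m))]
  shuf <- correlate_rows(m, m2, pairing = "matched")
  expect_equal(shuf$r, rep(1, 4))

  # disjoint samples are an alignment error
  m3 <- m
  colnames(m3) <- paste0("t", 1:10)
  expect_error(correlate_rows(m, m3), "shared sample")

  # constant rows land in exclusions, not in the batch
  mc <- m
  mc["g2", ] <- 5
  res <- correlate_rows(mc, mc, pairing = "matched")
  expect_equal(nrow(res), 3L)
  expect_equal(attr(res, "exclusions")$id_a, "g2")

  ap <- correlate_rows(m[1:2, ], m[3:4, ], pairing = "all_pairs")
  expect_equal(nrow(ap), 4L)
})

test_that("null calibration: rejection rate at p<0.05 is 0.05 within 3 SE", {
  set.seed(402)
  n_pairs <- 2000
  n <- 30
  rej <- vapply(seq_len(n_pairs), function(i) {
    pearson_cor(rnorm(n), rnorm(n))$p_value < 0.05
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / n_pairs)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)
})

test_that("cis screen flags by strict thresholds and keeps exclusions", {
  # noise-free limit: amplified genes at exactly r = 1
  cfg <- sim_config(seed = 12, noise_sd = 0, coexpr_blocks = list(),
                    mirna_links = list(), n_decoy_mirnas = 0L)
  g <- simulate_genome(cfg)
  cna <- simulate_cna(g$truth, cfg)
  ex <- simulate_expression(g$truth, cna, cfg)
  scr <- cna_mrna_screen(cna, ex$mrna)
  amp <- unlist(lapply(g$truth$segments, `[[`, "genes"))
  expect_true(all(scr$cis_driven[scr$gene %in% amp]))
  expect_equal(scr$r[scr$gene %in% amp], rep(1, length(amp)))
  # non-amplified genes have constant CNA rows -> exclusions, never flags
  expect_setequal(attr(scr, "exclusions")$id_a,
                  setdiff(rownames(cna), amp))
  expect_true(all(diff(scr$r) <= 0))  # sorted by descending r

  # genes present in only one matrix are reported, not dropped silently
  scr2 <- cna_mrna_screen(cna[-1, ], ex$mrna)
  expect_true(rownames(cna)[1L] %in% attr(scr2, "exclusions")$id_a)
})

test_that("false-positive control: passenger-amplified beta = 0 genes stay unflagged", {
  # passenger segment: copies gained, no dosage effect; |r| vs CNA must
  # stay low and the screen must not flag
  fp <- vapply(1:10, function(s) {
    b <- simulate_bundle(passenger_config(300 + s))
    passenger <- intersect(
      b$truth$segments[[3L]]$genes,
      names(b$truth$beta_cna)[b$truth$beta_cna == 0])
    scr <- cna_mrna_screen(b$cna, b$mrna)
    r_null <- scr$r[scr$gene %in% passenger]
    c(n_big_r = sum(abs(r_null) >= 0.3),
      n_flagged = sum(scr$cis_driven[scr$gene %in% passenger]))
  }, numeric(2))
  expect_equal(sum(fp["n_flagged", ]), 0)
  expect_lte(sum(fp["n_big_r", ] > 0), 1)  # >=95% of seeds all-below-0.3
})
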