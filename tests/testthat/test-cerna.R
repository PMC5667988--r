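toy_mirna_sets <- function() {
  regulator_sets(
    regulator = c("m1", "m1", "m2", "m2", "m3", "m3", "m2", "m4"),
    source = c("tarbase", "tarbase", "tarbase", "tarbase",
               "starbase", "starbase", "starbase", "starbase"),
    target = c("gA", "gB", "gA", "gB", "gA", "gB", "gA", "gC"))
}

test_that("shared miRNAs per source and cross-source union", {
  sets <- toy_mirna_sets()
  sm <- shared_mirnas(c("gA", "gB"), sets, c("tarbase", "starbase"))
  expect_setequal(sm$per_source$tarbase, c("m1", "m2"))
  expect_setequal(sm$per_source$starbase, "m3")  # m2 lacks gB in starbase
  expect_setequal(sm$union, c("m1", "m2", "m3"))
  expect_equal(sm$union_n, 3L)
  # order-invariance in the gene group
  expect_identical(sm$per_source,
                   shared_mirnas(c("gB", "gA"), sets,
                                 c("tarbase", "starbase"))$per_source)
  # single gene: its full per-source miRNA set
  one <- shared_mirnas("gA", sets, "tarbase")
  expect_setequal(one$per_source$tarbase, c("m1", "m2"))
  expect_error(shared_mirnas("gA", sets, "nope"), "unknown source")
})

test_that("set-algebra: per-source intersections pool with dedup", {
  # three sources whose pair intersections share members: the union
  # counts each miRNA once
  sets <- regulator_sets(
    regulator = rep(sprintf("mi%02d", 1:8), each = 2, times = 3),
    source = rep(c("s1", "s2", "s3"), each = 16),
    target = rep(c("gA", "gB"), times = 24))
  # restrict source membership: s1 gets mi01-04, s2 mi03-06, s3 mi05-08
  df <- as.data.frame(sets)
  keep <- (df$source == "s1" & df$regulator %in% sprintf("mi%02d", 1:4)) |
    (df$source == "s2" & df$regulator %in% sprintf("mi%02d", 3:6)) |
    (df$source == "s3" & df$regulator %in% sprintf("mi%02d", 5:8))
  sets <- regulator_sets(df$regulator[keep], df$source[keep],
                         df$target[keep])
  sm <- shared_mirnas(c("gA", "gB"), sets, c("s1", "s2", "s3"))
  expect_equal(lengths(sm$per_source), c(s1 = 4L, s2 = 4L, s3 = 4L))
  expect_equal(sm$union_n, 8L)  # not 12: overlaps deduplicated
  expect_lte(sm$union_n, sum(lengths(sm$per_source)))
})

test_that("anti-correlation flag requires negative r at significance", {
  set.seed(91)
  m <- rnorm(60)
  mirna <- matrix(m, 1, 60, dimnames = list("m1", paste0("s", 1:60)))
  expr <- rbind(gNeg = -m, gPos = m, gNoise = rnorm(60))
  colnames(expr) <- paste0("s", 1:60)
  res <- mirna_anticorrelation("m1", "gNeg", mirna, expr)
  expect_true(res$flag)
  expect_equal(res$r, -1)
  expect_false(mirna_anticorrelation("m1", "gPos", mirna, expr)$flag)
})

test_that("ceRNA verdicts combine shared pool, co-expression and support", {
  b <- simulate_bundle(sim_config(seed = 14))
  pair <- sort(b$truth$mirna_links[[1L]]$targets)
  cand <- cerna_candidates(matrix(pair, 1), b$mirna_sets, b$mrna,
                           b$mirna)
  expect_equal(cand$union_n, 6L)
  expect_true(cand$verdict)
  expect_gte(cand$r_pair, 0.6)
  expect_gte(cand$anticorr_support, 3L)

  # zero shared miRNAs: false regardless of correlation
  none <- cerna_candidates(matrix(c("G001", "G002"), 1), b$mirna_sets,
                           b$mrna, b$mirna)
  expect_equal(none$union_n, 0L)
  expect_false(none$verdict)

  # monotone thresholds: raising any never flips false -> true
  for (args in list(list(min_shared = 7L), list(r_pair_min = 0.99),
                    list(min_support = 7L))) {
    stricter <- do.call(cerna_candidates,
                        c(list(matrix(pair, 1), b$mirna_sets, b$mrna,
                               b$mirna), args))
    expect_false(stricter$verdict)
  }
})

test_that("planted repression yields anti-correlation flags across seeds", {
  ok <- vapply(1:10, function(s) {
    b <- simulate_bundle(sim_config(seed = 800 + s))
    ml <- b$truth$mirna_links[[1L]]
    all(vapply(ml$targets, function(g)
      mirna_anticorrelation(ml$mirna, g, b$mirna, b$mrna)$flag,
      logical(1)))
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
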