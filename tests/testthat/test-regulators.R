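test_that("venn partition assigns every element to exactly one cell", {
  vp <- venn_partition(list(A = c("a", "b", "c"), B = c("b", "c", "d"),
                            C = c("c", "d", "e")))
  expect_equal(venn_full_intersection(vp), "c")
  expect_equal(venn_cell(vp, "110"), "b")
  expect_equal(venn_cell(vp, "011"), "d")
  expect_equal(venn_cell(vp, "001"), "e")
  expect_equal(venn_cell(vp, "100"), "a")
  all_elems <- sort(unlist(vp$cells, use.names = FALSE))
  expect_equal(all_elems, c("a", "b", "c", "d", "e"))  # conservation
  expect_equal(anyDuplicated(all_elems), 0L)

  disjoint <- venn_partition(list(X = "p", Y = "q"))
  expect_length(venn_full_intersection(disjoint), 0L)

  expect_error(venn_partition(list(c("a"), c("b"))), "names")
})

test_that("venn conservation holds on random set systems", {
  set.seed(81)
  for (i in 1:30) {
    k <- sample(2:5, 1)
    sets <- lapply(seq_len(k), function(j)
      sample(letters, sample(3:12, 1)))
    names(sets) <- paste0("S", seq_len(k))
    vp <- venn_partition(sets)
    uni <- sort(unique(unlist(sets)))
    got <- sort(unlist(vp$cells, use.names = FALSE))
    expect_equal(got, uni)
    # each cell's elements belong to exactly the sets its signature says
    for (sig in names(vp$cells)) {
      bits <- as.integer(strsplit(sig, "")[[1L]])
      for (el in vp$cells[[sig]]) {
        expect_equal(vapply(sets, function(s) el %in% s, logical(1)),
                     bits == 1L, ignore_attr = TRUE)
      }
    }
  }
})

test_that("shared-regulator enrichment equals hand and exhaustive values", {
  sets <- regulator_sets(c("R1", "R1", "R1"), "src",
                         c("g1", "g2", "g3"))
  res <- shared_regulator_enrichment(sets, query = c("g1", "g2", "g4", "g5"),
                                     universe = sprintf("g%d", 1:8))
  expect_equal(res$overlap, 2L)
  expect_equal(res$p_value, 0.5)  # (30 + 5) / 70 by direct enumeration
  expect_equal(res$p_value, oracle_hyper_upper(2, 3, 8, 4))

  # degenerate certainty: targets = query = universe
  all_in <- shared_regulator_enrichment(
    regulator_sets("R", "s", c("g1", "g2")), query = c("g1", "g2"),
    universe = c("g1", "g2"))
  expect_equal(all_in$p_value, 1)

  expect_error(shared_regulator_enrichment(sets, query = "zz",
                                           universe = "g1"),
               "outside universe")
})

test_that("planted block factor ranks first among decoys", {
  ranks_ok <- vapply(1:10, function(s) {
    b <- simulate_bundle(sim_config(seed = 700 + s))
    blk <- b$truth$blocks[[1L]]$genes
    enr <- shared_regulator_enrichment(b$tf_sets, query = blk,
                                       universe = rownames(b$mrna))
    enr$regulator[1L] == "TF-block-1"
  }, logical(1))
  expect_gte(mean(ranks_ok), 0.9)
})

test_that("TF sign classification splits on r >= 0 and reports fractions", {
  set.seed(82)
  target <- rnorm(50)
  expr <- rbind(target = target, act = target, rep = -target,
                weak = 0.1 * target + rnorm(50))
  colnames(expr) <- paste0("s", 1:50)
  res <- tf_sign_classification(c("act", "rep", "weak", "gone"), expr,
                                "target")
  expect_equal(res$class[res$tf == "act"], "activator_like")
  expect_equal(res$r[res$tf == "act"], 1)
  expect_equal(res$class[res$tf == "rep"], "repressor_like")
  expect_equal(res$r[res$tf == "rep"], -1)
  expect_equal(attr(res, "exclusions"), "gone")
  expect_equal(attr(res, "activator_fraction"),
               mean(res$class == "activator_like"))
})

test_that("pathway partition mirrors the shared-pathway table layout", {
  vp <- pathway_partition(list(gA = c("P1", "P2"), gB = c("P2", "P3"),
                               gC = c("P2")))
  expect_equal(venn_full_intersection(vp), "P2")
  tab <- format_pathway_table(vp)
  expect_equal(tab$genes[1L], "gA;gB;gC")
  expect_equal(tab$total[1L], 1L)
  identical_sets <- pathway_partition(list(g1 = c("P1", "P2"),
                                           g2 = c("P1", "P2")))
  expect_length(identical_sets$cells, 1L)
  expect_setequal(venn_full_intersection(identical_sets), c("P1", "P2"))
  expect_error(pathway_partition(list(g1 = "P1")), "2-8")
})
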