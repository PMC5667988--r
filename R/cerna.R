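#' Shared microRNAs of a gene group, per evidence source
#'
#' For each evidence source, the set of microRNAs whose target list
#' contains every gene of the group (the intersection of the genes'
#' per-source miRNA sets), plus the union across sources. Element lists
#' are retained, not just counts, and the per-source intersection is
#' invariant to the ordering of the gene group.
#'
#' @param gene_group Character vector of gene ids.
#' @param sets A [regulator_sets()] collection mapping miRNA ids to
#'   target genes per source.
#' @param sources Character vector of evidence sources to interrogate;
#'   each must be present in `sets`.
#' @return A list: `per_source` (named list of miRNA id vectors),
#'   `union` (miRNA ids pooled across sources), `union_n`.
#' @export
shared_mirnas <- function(gene_group, sets, sources) {
  stopifnot(inherits(sets, "regulator_sets"))
  gene_group <- unique(as.character(gene_group))
  if (length(gene_group) == 0) stop("empty gene group", call. = FALSE)
  known <- unique(sets$source)
  bad <- setdiff(sources, known)
  if (length(bad)) {
    stop("unknown source(s): ", paste(bad, collapse = ", "),
         " (available: ", paste(known, collapse = ", "), ")",
         call. = FALSE)
  }
  per_source <- lapply(sources, function(src) {
    sub <- sets[sets$source == src, , drop = FALSE]
    mirnas <- unique(sub$regulator)
    keep <- vapply(mirnas, function(m) {
      all(gene_group %in% sub$target[sub$regulator == m])
    }, logical(1))
    sort(mirnas[keep])
  })
  names(per_source) <- sources
  uni <- sort(unique(unlist(per_source, use.names = FALSE)))
  list(per_source = per_source, union = uni, union_n = length(uni))
}

#' miRNA-target anti-correlation test
#'
#' Flags a repressive miRNA-target relationship: Pearson `r < 0` with
#' `p < alpha` between the miRNA's abundance row and the gene's
#' expression row over shared samples.
#'
#' @param mirna miRNA row id in `mirna_expr`.
#' @param gene Gene row id in `expr`.
#' @param mirna_expr,expr Numeric matrices sharing sample ids.
#' @param alpha Significance level (default 0.05, exclusive).
#' @return A list: `r`, `p_value`, `n_used`, `flag`.
#' @export
mirna_anticorrelation <- function(mirna, gene, mirna_expr, expr,
                                  alpha = 0.05) {
  if (!mirna %in% rownames(mirna_expr)) {
    stop("miRNA '", mirna, "' not in miRNA matrix", call. = FALSE)
  }
  if (!gene %in% rownames(expr)) {
    stop("gene '", gene, "' not in expression matrix", call. = FALSE)
  }
  shared <- intersect(colnames(mirna_expr), colnames(expr))
  if (length(shared) < 3) stop("fewer than 3 shared samples", call. = FALSE)
  res <- pearson_cor(mirna_expr[mirna, shared], expr[gene, shared],
                     id_a = mirna, id_b = gene)
  list(r = res$r, p_value = res$p_value, n_used = res$n_used,
       flag = res$r < 0 && res$p_value < alpha)
}

#' Call competing-endogenous-RNA candidate pairs
#'
#' A gene pair is called a ceRNA candidate when (i) the union of shared
#' miRNAs across evidence sources reaches `min_shared`, (ii) the pair's
#' expression correlation reaches `r_pair_min`, and (iii) at least
#' `min_support` of the shared miRNAs are anti-correlated
#' (`r < 0`, `p < alpha`) with *both* genes — the signature of two
#' transcripts competing for one limited miRNA pool. Verdicts are
#' monotone in all three thresholds: raising any of them can only turn
#' calls off.
#'
#' @param pairs Two-column character matrix or data.frame of gene pairs.
#' @param sets A [regulator_sets()] collection (miRNA -> targets).
#' @param expr Gene expression matrix.
#' @param mirna_expr miRNA abundance matrix.
#' @param sources Evidence sources to pool (default: all in `sets`).
#' @param min_shared Minimum shared-miRNA union count (default 5).
#' @param r_pair_min Minimum pair expression correlation (default 0.6).
#' @param min_support Minimum anti-correlated shared miRNAs (default 3).
#' @param alpha Anti-correlation significance level (default 0.05).
#' @return A `data.frame`, one row per pair: `gene_a`, `gene_b`,
#'   per-source shared counts (`shared_<source>`), `union_n`, `r_pair`,
#'   `anticorr_support`, `verdict`, plus a list column `shared_union`
#'   with the miRNA ids.
#' @export
cerna_candidates <- function(pairs, sets, expr, mirna_expr,
                             sources = NULL, min_shared = 5L,
                             r_pair_min = 0.6, min_support = 3L,
                             alpha = 0.05) {
  stopifnot(inherits(sets, "regulator_sets"))
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2)
  if (is.null(sources)) sources <- sort(unique(sets$source))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ga <- pairs[i, 1L]; gb <- pairs[i, 2L]
    sm <- shared_mirnas(c(ga, gb), sets, sources)
    r_pair <- tryCatch(
      pearson_cor(expr[ga, ], expr[gb, ], ga, gb)$r,
      error = function(e) NA_real_)
    support <- 0L
    if (length(sm$union)) {
      testable <- intersect(sm$union, rownames(mirna_expr))
      support <- sum(vapply(testable, function(m) {
        fa <- mirna_anticorrelation(m, ga, mirna_expr, expr, alpha)$flag
        fb <- mirna_anticorrelation(m, gb, mirna_expr, expr, alpha)$flag
        fa && fb
      }, logical(1)))
    }
    verdict <- sm$union_n >= min_shared && !is.na(r_pair) &&
      r_pair >= r_pair_min && support >= min_support
    row <- data.frame(gene_a = ga, gene_b = gb, stringsAsFactors = FALSE)
    for (src in sources) {
      row[[paste0("shared_", src)]] <- length(sm$per_source[[src]])
    }
    row$union_n <- sm$union_n
    row$r_pair <- r_pair
    row$anticorr_support <- support
    row$verdict <- verdict
    row$shared_union <- I(list(sm$union))
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "thresholds") <- list(min_shared = min_shared,
                                  r_pair_min = r_pair_min,
                                  min_support = min_support, alpha = alpha)
  out
}
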