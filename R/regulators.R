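#' Shared-regulator enrichment over a query gene set
#'
#' For each `(regulator, source)` entry: the one-sided hypergeometric
#' upper-tail probability of drawing at least the observed overlap
#' between the regulator's targets and the query when sampling
#' `|query|` genes without replacement from the universe. Target sets
#' are intersected with the universe first; Benjamini-Hochberg q-values
#' are computed across all tested regulators and results sorted by
#' p-value.
#'
#' @param sets A [regulator_sets()] collection.
#' @param query Character vector of query gene ids (must lie inside
#'   `universe`).
#' @param universe Character vector: the population of genes, typically
#'   all genes in the expression matrix.
#' @return A `data.frame`: `regulator`, `source`, `n_targets`, `overlap`,
#'   `covered` (overlapping gene ids, `;`-joined), `p_value`, `q_bh`.
#' @export
shared_regulator_enrichment <- function(sets, query, universe) {
  stopifnot(inherits(sets, "regulator_sets"))
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    stop("query gene(s) outside universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  entries <- unique(as.data.frame(sets)[c("regulator", "source")])
  N <- length(universe)
  n <- length(query)
  rows <- lapply(seq_len(nrow(entries)), function(i) {
    tg <- intersect(regulator_targets(sets, entries$regulator[i],
                                      entries$source[i]), universe)
    K <- length(tg)
    hit <- intersect(tg, query)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(regulator = entries$regulator[i], source = entries$source[i],
               n_targets = K, overlap = k,
               covered = paste(sort(hit), collapse = ";"),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_bh <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, -out$overlap, out$regulator), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify transcription factors as activator- or repressor-like
#'
#' Correlates each TF's expression row with the target gene's row;
#' `r >= 0` is classed activator-like and `r < 0` repressor-like (a
#' strict partition — the boundary `r = 0` counts as activator-like).
#' The summary fraction of activator-like TFs is attached as an
#' attribute; TFs without an expression row are listed in the
#' `"exclusions"` attribute.
#'
#' @param tf_ids Character vector of TF ids.
#' @param expr Numeric genes-by-samples expression matrix containing the
#'   TF rows and the target row.
#' @param target_gene Row id of the target gene.
#' @return A `data.frame`: `tf`, `r`, `n_used`, `p_value`, `class`
#'   (`"activator_like"`/`"repressor_like"`), sorted by descending `r`,
#'   with attributes `activator_fraction` and `exclusions`.
#' @export
tf_sign_classification <- function(tf_ids, expr, target_gene) {
  if (!target_gene %in% rownames(expr)) {
    stop("target gene '", target_gene, "' not in expression matrix",
         call. = FALSE)
  }
  tf_ids <- unique(as.character(tf_ids))
  missing <- setdiff(tf_ids, rownames(expr))
  present <- setdiff(tf_ids, missing)
  if (length(present) == 0) stop("no TF rows present", call. = FALSE)
  batch <- correlate_rows(expr[present, , drop = FALSE],
                          expr[target_gene, , drop = FALSE],
                          pairing = "all_vs_seed", seed_id = target_gene)
  out <- data.frame(tf = batch$id_a, r = batch$r, n_used = batch$n_used,
                    p_value = batch$p_value,
                    class = ifelse(batch$r >= 0, "activator_like",
                                   "repressor_like"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$r), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "activator_fraction") <- mean(out$class == "activator_like")
  attr(out, "exclusions") <- missing
  out
}
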