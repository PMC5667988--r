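#' Genome-wide co-expression profile against a seed gene
#'
#' Correlates every gene in the expression matrix against one seed gene
#' (the seed's own entry has `r = 1` by identity). Genes that cannot be
#' correlated (constant rows, too much missingness) are carried in the
#' `"exclusions"` attribute.
#'
#' @param expr Numeric genes-by-samples matrix.
#' @param seed Row id of the seed gene.
#' @return A `data.frame` of class `coexpression_profile` with columns
#'   `gene`, `r`, `n_used`, `p_value` and attributes `seed`, `exclusions`.
#' @export
seed_profile <- function(expr, seed) {
  if (!seed %in% rownames(expr)) {
    stop("seed gene '", seed, "' not in expression matrix", call. = FALSE)
  }
  batch <- correlate_rows(expr, expr[seed, , drop = FALSE],
                          pairing = "all_vs_seed", seed_id = seed)
  out <- data.frame(gene = batch$id_a, r = batch$r, n_used = batch$n_used,
                    p_value = batch$p_value, stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  attr(out, "exclusions") <- attr(batch, "exclusions")
  class(out) <- c("coexpression_profile", "data.frame")
  out
}

#' Threshold a co-expression profile
#'
#' Keeps genes with `r >= r_min` (boundary inclusive, matching the
#' screening rule "Pearson score >= 0.6"). The seed itself is excluded
#' from the returned set and the exclusion is reported via the
#' `"seed_excluded"` attribute, so counts of co-expressed genes never
#' include the trivial self-correlation.
#'
#' @param profile A [seed_profile()] result.
#' @param r_min Inclusive correlation threshold (default 0.6).
#' @return Character vector of gene ids.
#' @export
threshold_profile <- function(profile, r_min = 0.6) {
  stopifnot(inherits(profile, "coexpression_profile"))
  seed <- attr(profile, "seed")
  genes <- profile$gene[profile$r >= r_min & profile$gene != seed]
  structure(genes, seed_excluded = seed %in%
              profile$gene[profile$r >= r_min])
}

#' Cytoband fractions and positional enrichment of a gene set
#'
#' For each cytoband: the count of significant genes, the band's total
#' gene count, their ratio (the fraction "significant genes / all genes
#' on this DNA region"), and a one-sided hypergeometric upper-tail
#' p-value for positional enrichment (population = all annotated genes,
#' successes = the band's genes, draws = the significant set), with
#' Benjamini-Hochberg q-values across bands. The enrichment p-value makes
#' fractions comparable across bands of different size.
#'
#' @param genes Character vector of significant gene ids.
#' @param annotation A [gene_annotation()] with cytoband labels assigned.
#' @return A `data.frame` with columns `band`, `n_significant`, `n_total`,
#'   `fraction`, `p_value`, `q_bh`. Genes lacking a band label are
#'   excluded and reported in the `"exclusions"` attribute.
#' @export
band_fractions <- function(genes, annotation) {
  stopifnot(inherits(annotation, "gene_annotation"))
  labelled <- annotation[!is.na(annotation$cytoband), , drop = FALSE]
  unlabelled <- intersect(genes, annotation$gene_id[is.na(annotation$cytoband)])
  unknown <- setdiff(genes, annotation$gene_id)
  genes <- intersect(genes, labelled$gene_id)
  bands <- unique(labelled$cytoband)
  N <- nrow(labelled)
  n_draw <- length(genes)
  out <- do.call(rbind, lapply(bands, function(b) {
    members <- labelled$gene_id[labelled$cytoband == b]
    K <- length(members)
    k <- length(intersect(genes, members))
    p <- if (n_draw == 0) 1 else
      stats::phyper(k - 1, K, N - K, n_draw, lower.tail = FALSE)
    data.frame(band = b, n_significant = k, n_total = K,
               fraction = if (K > 0) k / K else 0, p_value = p,
               stringsAsFactors = FALSE)
  }))
  out$q_bh <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  attr(out, "exclusions") <- c(unlabelled, unknown)
  out
}

#' Cluster significant genes into physically adjacent runs
#'
#' Scans the annotation in coordinate order (per chromosome) and collects
#' maximal runs of significant genes; within a run, each interruption of
#' at most `max_gap` consecutive non-significant genes is tolerated (the
#' interrupting genes are skipped, not made members). Runs shorter than
#' `min_size` are discarded. The result is independent of the ordering of
#' the input gene set, and raising the co-expression threshold upstream
#' can only shrink clusters.
#'
#' @param genes Character vector of significant gene ids.
#' @param annotation A sorted [gene_annotation()].
#' @param max_gap Maximum tolerated consecutive non-significant genes per
#'   interruption (default 0: strict adjacency).
#' @param min_size Minimum member count per reported cluster (default 2).
#' @param profile Optional [seed_profile()]; when given, each cluster
#'   reports the min/max `r` of its members against the seed.
#' @return A `data.frame` with one row per cluster: `cluster_id`, `size`,
#'   `band_span`, `min_r`, `max_r`, `max_gap_used` and a list column
#'   `members` (gene ids in coordinate order).
#' @export
adjacency_clusters <- function(genes, annotation, max_gap = 0L,
                               min_size = 2L, profile = NULL) {
  stopifnot(inherits(annotation, "gene_annotation"),
            max_gap >= 0, min_size >= 1)
  genes <- unique(genes)
  clusters <- list()
  for (ch in unique(annotation$chrom)) {
    ann <- annotation[annotation$chrom == ch, , drop = FALSE]
    sig <- ann$gene_id %in% genes
    current <- character(0)
    gap_run <- 0L
    flush <- function() {
      if (length(current) >= min_size) {
        clusters[[length(clusters) + 1L]] <<- list(members = current,
                                                   chrom = ch)
      }
      current <<- character(0)
      gap_run <<- 0L
    }
    for (i in seq_len(nrow(ann))) {
      if (sig[i]) {
        current <- c(current, ann$gene_id[i])
        gap_run <- 0L
      } else if (length(current)) {
        gap_run <- gap_run + 1L
        if (gap_run > max_gap) flush()
      }
    }
    flush()
  }
  if (length(clusters) == 0) {
    out <- data.frame(cluster_id = character(), size = integer(),
                      band_span = character(), min_r = numeric(),
                      max_r = numeric(), max_gap_used = integer(),
                      stringsAsFactors = FALSE)
    out$members <- list()
    return(out)
  }
  rows <- lapply(seq_along(clusters), function(k) {
    mem <- clusters[[k]]$members
    bands <- annotation$cytoband[match(mem, annotation$gene_id)]
    bands <- unique(bands[!is.na(bands)])
    span <- if (length(bands) == 0) NA_character_ else if
      (length(bands) == 1) bands else
        paste(bands[1L], bands[length(bands)], sep = "-")
    rr <- if (!is.null(profile)) profile$r[match(mem, profile$gene)] else
      NA_real_
    has_r <- any(!is.na(rr))
    data.frame(cluster_id = sprintf("cluster_%02d", k),
               size = length(mem), band_span = span,
               min_r = if (has_r) min(rr, na.rm = TRUE) else NA_real_,
               max_r = if (has_r) max(rr, na.rm = TRUE) else NA_real_,
               max_gap_used = as.integer(max_gap),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$members <- lapply(clusters, `[[`, "members")
  rownames(out) <- NULL
  out
}
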