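#' Pearson correlation with pairwise deletion and exact t-based p-value
#'
#' Missing entries are removed pairwise (never imputed) and the number of
#' complete pairs actually used is reported. The two-sided p-value comes
#' from the exact transform `t = r * sqrt((n - 2) / (1 - r^2))` against a
#' t distribution with `n - 2` degrees of freedom.
#'
#' A constant vector (after deletion) has no defined correlation and is an
#' error rather than a silent `r = 0`; fewer than 3 complete pairs is an
#' insufficient-data error.
#'
#' @param x,y Numeric vectors of equal length; `NA` allowed.
#' @param id_a,id_b Optional identifiers echoed into the result.
#' @return A one-row `data.frame` with `id_a`, `id_b`, `r`, `n_used`,
#'   `p_value`.
#' @examples
#' pearson_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))$r  # 0.6
#' @export
pearson_cor <- function(x, y, id_a = "x", id_b = "y") {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  keep <- !(is.na(x) | is.na(y))
  n <- sum(keep)
  if (n < 3) stop("insufficient data: ", n, " complete pairs (need >= 3)",
                  call. = FALSE)
  xs <- x[keep]; ys <- y[keep]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  r <- stats::cor(xs, ys)
  p <- pearson_p(r, n)
  data.frame(id_a = id_a, id_b = id_b, r = r, n_used = n, p_value = p,
             stringsAsFactors = FALSE)
}

# Two-sided p for a Pearson r at n complete pairs. |r| = 1 gives p = 0.
pearson_p <- function(r, n) {
  r <- pmin(1, pmax(-1, r))
  tt <- ifelse(abs(r) >= 1, Inf, r * sqrt((n - 2) / (1 - r^2)))
  2 * stats::pt(-abs(tt), df = n - 2)
}

#' Batch Pearson correlation between rows of two matrices
#'
#' Columns are aligned on the intersection of sample ids before any
#' computation; missing cells are deleted pairwise per pair and `n_used`
#' recorded. Benjamini-Hochberg q-values are computed over the whole
#' batch.
#'
#' @param a,b Numeric matrices with row and column (sample) names.
#' @param pairing `"matched"` pairs identical row ids of `a` and `b`
#'   (e.g. each gene's expression against its own copy number);
#'   `"all_vs_seed"` pairs every row of `a` against the single row
#'   `seed_id` of `b`; `"all_pairs"` crosses every row of `a` with every
#'   row of `b`.
#' @param seed_id Row id of `b` for `pairing = "all_vs_seed"`.
#' @return A `data.frame` with one row per pair: `id_a`, `id_b`, `r`,
#'   `n_used`, `p_value`, `q_bh`. Rows that could not be correlated
#'   (constant or too few complete pairs) are returned in the
#'   `"exclusions"` attribute with a reason, not silently dropped.
#' @export
correlate_rows <- function(a, b,
                           pairing = c("matched", "all_vs_seed",
                                       "all_pairs"),
                           seed_id = NULL) {
  pairing <- match.arg(pairing)
  shared <- intersect(colnames(a), colnames(b))
  if (length(shared) < 3) {
    stop("alignment error: ", length(shared),
         " shared sample id(s) (need >= 3)", call. = FALSE)
  }
  a <- a[, shared, drop = FALSE]
  b <- b[, shared, drop = FALSE]
  pairs <- switch(pairing,
    matched = {
      ids <- intersect(rownames(a), rownames(b))
      if (length(ids) == 0) stop("no matched row ids", call. = FALSE)
      cbind(ids, ids)
    },
    all_vs_seed = {
      if (is.null(seed_id) || !seed_id %in% rownames(b)) {
        stop("seed_id must name a row of b", call. = FALSE)
      }
      cbind(rownames(a), seed_id)
    },
    all_pairs = as.matrix(expand.grid(rownames(a), rownames(b),
                                      stringsAsFactors = FALSE))
  )
  res <- vector("list", nrow(pairs))
  excl <- list()
  for (k in seq_len(nrow(pairs))) {
    res[[k]] <- tryCatch(
      pearson_cor(a[pairs[k, 1L], ], b[pairs[k, 2L], ],
                  id_a = pairs[k, 1L], id_b = pairs[k, 2L]),
      error = function(e) {
        excl[[length(excl) + 1L]] <<- data.frame(
          id_a = pairs[k, 1L], id_b = pairs[k, 2L],
          reason = conditionMessage(e), stringsAsFactors = FALSE)
        NULL
      })
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(id_a = character(), id_b = character(), r = numeric(),
                      n_used = integer(), p_value = numeric(),
                      q_bh = numeric(), stringsAsFactors = FALSE)
  } else {
    out$q_bh <- stats::p.adjust(out$p_value, method = "BH")
  }
  rownames(out) <- NULL
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(id_a = character(), id_b = character(), reason = character())
  out
}

#' Copy-number to mRNA cis-effect screen
#'
#' Correlates each gene's expression with its own copy-number profile and
#' flags genes whose expression is copy-number driven: `r > r_min` and
#' p-value below `alpha` (both strict, matching the screening rule
#' "r > 0.65, p < 0.0001"). `p_mode = "raw"` thresholds the raw p-value;
#' `"bh"` thresholds the Benjamini-Hochberg q-value computed across the
#' screen (the q column is reported in both modes).
#'
#' @param cna,expr Numeric matrices (genes x samples) sharing gene and
#'   sample ids.
#' @param r_min Minimum correlation, exclusive (default 0.65).
#' @param alpha Significance level, exclusive (default 1e-4).
#' @param p_mode `"raw"` or `"bh"`.
#' @return A `data.frame` sorted by descending `r` with columns `gene`,
#'   `r`, `n_used`, `p_value`, `q_bh`, `cis_driven`. Genes present in only
#'   one matrix are listed in the `"exclusions"` attribute.
#' @export
cna_mrna_screen <- function(cna, expr, r_min = 0.65, alpha = 1e-4,
                            p_mode = c("raw", "bh")) {
  p_mode <- match.arg(p_mode)
  batch <- correlate_rows(expr, cna, pairing = "matched")
  only_expr <- setdiff(rownames(expr), rownames(cna))
  only_cna <- setdiff(rownames(cna), rownames(expr))
  excl <- attr(batch, "exclusions")
  if (length(only_expr)) {
    excl <- rbind(excl, data.frame(id_a = only_expr, id_b = NA_character_,
                                   reason = "gene absent from CNA matrix"))
  }
  if (length(only_cna)) {
    excl <- rbind(excl, data.frame(id_a = only_cna, id_b = NA_character_,
                                   reason = "gene absent from expression matrix"))
  }
  pcol <- if (p_mode == "raw") batch$p_value else batch$q_bh
  out <- data.frame(gene = batch$id_a, r = batch$r, n_used = batch$n_used,
                    p_value = batch$p_value, q_bh = batch$q_bh,
                    cis_driven = batch$r > r_min & pcol < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$r), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  attr(out, "thresholds") <- list(r_min = r_min, alpha = alpha,
                                  p_mode = p_mode)
  out
}
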