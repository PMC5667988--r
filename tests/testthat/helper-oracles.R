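# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Definitional Pearson formula: sum of cross-deviations over the root
# product of squared deviations.
oracle_pearson <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Exhaustive hypergeometric upper tail: enumerate every size-n draw from
# a universe of N elements whose first K are successes and count draws
# with overlap >= k.
oracle_hyper_upper <- function(k, K, N, n) {
  if (n == 0) return(if (k <= 0) 1 else 0)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Quadratic brute-force bidirectional filter: test every gene pair (not
# just coordinate-adjacent ones) and keep divergent pairs below max_dist
# that have no third gene starting between them.
oracle_bidirectional <- function(ann, max_dist = 1000) {
  hits <- list()
  for (i in seq_len(nrow(ann))) {
    for (j in seq_len(nrow(ann))) {
      if (i == j) next
      a <- ann[i, ]; b <- ann[j, ]
      if (a$chrom != b$chrom || a$start > b$start) next
      between <- ann$chrom == a$chrom & ann$start > a$start &
        ann$start < b$start
      if (any(between)) next
      dist <- max(b$start, a$end) - a$end
      overlap <- b$start < a$end
      if (a$strand == "-" && b$strand == "+" && !overlap &&
          dist < max_dist) {
        hits[[length(hits) + 1L]] <- c(a$gene_id, b$gene_id)
      }
    }
  }
  hits
}

# All-offsets PWM scorer, computed position by position from the
# definition without any indexing tricks.
oracle_pwm_hits <- function(seq, pwm, threshold) {
  revcomp <- function(s) {
    map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(map[strsplit(s, "")[[1L]]]), collapse = "")
  }
  score_at <- function(s, o, W) {
    sc <- 0
    for (i in seq_len(W)) {
      base <- substr(s, o + i, o + i)
      if (base == "N") return(NA_real_)
      sc <- sc + log2((pwm$freq[base, i] + pwm$pseudocount) /
                        (0.25 + pwm$pseudocount))
    }
    sc
  }
  W <- pwm$width
  L <- nchar(seq)
  out <- list()
  for (o in 0:(L - W)) {
    sc <- score_at(seq, o, W)
    if (!is.na(sc) && sc >= threshold) {
      out[[length(out) + 1L]] <- data.frame(offset = o, strand = "+",
                                            score = sc)
    }
  }
  rc <- revcomp(seq)
  for (o in 0:(L - W)) {
    sc <- score_at(rc, o, W)
    if (!is.na(sc) && sc >= threshold) {
      out[[length(out) + 1L]] <- data.frame(offset = L - W - o,
                                            strand = "-", score = sc)
    }
  }
  if (length(out) == 0) {
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$offset, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Small ad-hoc annotation builder for hand-constructed layouts.
toy_annotation <- function(n, chrom = "chr1", start0 = 0, len = 100,
                           gap = 50, strand = "+") {
  starts <- start0 + (seq_len(n) - 1) * (len + gap)
  gene_annotation(gene_id = sprintf("g%d", seq_len(n)), chrom = chrom,
                  start = starts, end = starts + len,
                  strand = rep_len(strand, n))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
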