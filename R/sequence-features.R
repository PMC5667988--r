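#' CpG island scan (Gardiner-Garden & Frommer style)
#'
#' Slides a window along the sequence; a window qualifies when its GC
#' fraction is at least `gc_min` and its observed/expected CpG ratio
#' `(N_CpG * L) / (N_C * N_G)` is at least `oe_min`. Overlapping or
#' abutting qualifying windows are merged and each merged region is
#' re-checked against all three thresholds (length, GC, obs/exp) before
#' being reported, so reported islands are disjoint and individually
#' valid. `N` bases are excluded from all counts (the effective length
#' `L` counts only called bases). A sequence shorter than the window
#' yields an empty result.
#'
#' Defaults are the classical 200 bp / 50% GC / 0.6 obs-exp criteria; all
#' three are configurable, e.g. a lowered `len_min` admits the short
#' (sub-200 bp) CpG islands typical of compact bidirectional promoter
#' spacers.
#'
#' @param seq Character scalar over `A`, `C`, `G`, `T`, `N`.
#' @param len_min Minimum island length in bp (default 200).
#' @param gc_min Minimum GC fraction (default 0.5).
#' @param oe_min Minimum observed/expected CpG ratio (default 0.6).
#' @param window Window width in bp (default 100).
#' @param step Window step in bp (default 1).
#' @return A `data.frame` of islands: `start`, `end` (0-based half-open
#'   offsets within `seq`), `length`, `gc_fraction`, `obs_exp_cpg`.
#' @export
cpg_island_scan <- function(seq, len_min = 200L, gc_min = 0.5,
                            oe_min = 0.6, window = 100L, step = 1L) {
  seq <- check_dna(seq)
  L <- nchar(seq)
  empty <- data.frame(start = integer(), end = integer(),
                      length = integer(), gc_fraction = numeric(),
                      obs_exp_cpg = numeric())
  if (L < window) return(empty)
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  isC <- b == "C"; isG <- b == "G"; isN <- b == "N"
  cpg_at <- c(isC[-L] & isG[-1L], FALSE)  # CpG dinucleotide start sites
  cumC <- cumsum(isC); cumG <- cumsum(isG); cumN <- cumsum(isN)
  cumCpG <- cumsum(cpg_at)
  stat <- function(s, e) {  # 0-based half-open [s, e)
    nC <- cumC[e] - if (s > 0) cumC[s] else 0
    nG <- cumG[e] - if (s > 0) cumG[s] else 0
    nN <- cumN[e] - if (s > 0) cumN[s] else 0
    # CpG starts strictly inside [s, e-1)
    nCpG <- (if (e > 1) cumCpG[e - 1L] else 0) - if (s > 0) cumCpG[s] else 0
    eff <- (e - s) - nN
    gc <- if (eff > 0) (nC + nG) / eff else 0
    oe <- if (nC > 0 && nG > 0) nCpG * eff / (nC * nG) else 0
    c(gc = gc, oe = oe)
  }
  starts <- seq.int(0L, L - window, by = step)
  ok <- vapply(starts, function(s) {
    st <- stat(s, s + window)
    st["gc"] >= gc_min && st["oe"] >= oe_min
  }, logical(1))
  if (!any(ok)) return(empty)
  # merge overlapping/abutting qualifying windows
  qs <- starts[ok]; qe <- qs + window
  merged <- list(c(qs[1L], qe[1L]))
  for (i in seq_along(qs)[-1L]) {
    last <- merged[[length(merged)]]
    if (qs[i] <= last[2L]) {
      merged[[length(merged)]][2L] <- max(last[2L], qe[i])
    } else {
      merged[[length(merged) + 1L]] <- c(qs[i], qe[i])
    }
  }
  rows <- lapply(merged, function(iv) {
    st <- stat(iv[1L], iv[2L])
    len <- iv[2L] - iv[1L]
    if (len >= len_min && st["gc"] >= gc_min && st["oe"] >= oe_min) {
      data.frame(start = iv[1L], end = iv[2L], length = len,
                 gc_fraction = unname(st["gc"]),
                 obs_exp_cpg = unname(st["oe"]))
    } else {
      NULL
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else { rownames(out) <- NULL; out }
}

check_dna <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    stop("sequence must be over {A,C,G,T,N}", call. = FALSE)
  }
  seq
}

#' TATA-box consensus scan
#'
#' Tests both strands for the TATAWAW consensus (W = A or T). A
#' TATA-less spacer is one hallmark of the CpG-rich bidirectional
#' promoter class.
#'
#' @param seq Character scalar over `A`, `C`, `G`, `T`, `N`.
#' @return A list: `found` (logical) and `hits`, a `data.frame` of
#'   0-based forward-strand offsets of each 7-mer match and its strand.
#' @export
tata_scan <- function(seq) {
  seq <- check_dna(seq)
  hits <- data.frame(offset = integer(), strand = character(),
                     stringsAsFactors = FALSE)
  if (nchar(seq) >= 7) {
    dna <- Biostrings::DNAString(seq)
    fwd <- Biostrings::matchPattern("TATAWAW", dna, fixed = FALSE)
    rev <- Biostrings::matchPattern(
      "TATAWAW", Biostrings::reverseComplement(dna), fixed = FALSE)
    L <- nchar(seq)
    off_f <- Biostrings::start(fwd) - 1L
    off_r <- L - (Biostrings::start(rev) - 1L) - 7L
    hits <- data.frame(offset = c(off_f, off_r),
                       strand = rep(c("+", "-"),
                                    c(length(off_f), length(off_r))),
                       stringsAsFactors = FALSE)
    hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
    rownames(hits) <- NULL
  }
  list(found = nrow(hits) > 0, hits = hits)
}

#' Read position frequency matrices in JASPAR plain-text format
#'
#' Parses the four bracketed count rows following each `>` header line
#' and normalizes columns to frequencies. Each returned motif carries its
#' id, the 4 x width frequency matrix (rows `A`, `C`, `G`, `T`) and the
#' pseudocount used for log-odds scoring.
#'
#' @param path Path to a JASPAR `.pfm`/`.jaspar` text file (one or more
#'   motifs).
#' @param pseudocount Pseudocount added to frequencies when scoring
#'   (default 0.01).
#' @return A named list of `pwm` objects.
#' @export
read_jaspar_pwm <- function(path, pseudocount = 0.01) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no '>' motif headers in ", path,
                               call. = FALSE)
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (h in seq_along(heads)) {
    block <- lines[(bounds[h] + 1L):(bounds[h + 1L] - 1L)]
    if (length(block) < 4) stop("motif block with <4 rows in ", path,
                                call. = FALSE)
    id <- sub("^>\\s*", "", lines[heads[h]])
    id <- strsplit(id, "[ \t]+")[[1L]][1L]
    rows <- lapply(block[1:4], function(ln) {
      ln <- sub("^[ACGTacgt]\\s*", "", ln)
      ln <- gsub("[\\[\\]]", " ", ln, perl = TRUE)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1L]])
    })
    w <- unique(lengths(rows))
    if (length(w) != 1L) stop("ragged PFM rows for motif ", id,
                              call. = FALSE)
    mat <- do.call(rbind, rows)
    rownames(mat) <- c("A", "C", "G", "T")
    out[[id]] <- pwm_motif(id, mat, pseudocount)
  }
  out
}

#' Construct a PWM motif object
#'
#' @param motif_id Motif identifier.
#' @param counts 4 x width numeric matrix (rows `A`, `C`, `G`, `T`) of
#'   counts or frequencies; columns are normalized to sum to 1.
#' @param pseudocount Pseudocount for log-odds scoring (default 0.01).
#' @return A list of class `pwm`.
#' @export
pwm_motif <- function(motif_id, counts, pseudocount = 0.01) {
  stopifnot(is.matrix(counts), nrow(counts) == 4, ncol(counts) >= 1,
            all(counts >= 0))
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  csum <- colSums(counts)
  if (any(csum == 0)) stop("PWM column with zero total", call. = FALSE)
  freq <- sweep(counts, 2, csum, "/")
  structure(list(motif_id = motif_id, freq = freq,
                 width = ncol(freq), pseudocount = pseudocount),
            class = "pwm")
}

#' Scan a sequence with a PWM
#'
#' Scores every offset on both strands with the log-odds score
#' `sum_i log2((f[b_i, i] + eps) / (0.25 + eps))` in bits, against a
#' uniform background; the reverse strand is scored on the reverse
#' complement and hits are reported at the motif's forward-strand offset.
#' Offsets containing `N` are skipped.
#'
#' @param seq Character scalar over `A`, `C`, `G`, `T`, `N`.
#' @param pwm A [pwm_motif()] object.
#' @param threshold_bits Minimum score for a reported hit.
#' @return A `data.frame` of hits: `motif_id`, `offset` (0-based,
#'   forward strand), `strand`, `score`, sorted by offset.
#' @export
pwm_scan <- function(seq, pwm, threshold_bits) {
  stopifnot(inherits(pwm, "pwm"))
  seq <- check_dna(seq)
  L <- nchar(seq)
  W <- pwm$width
  if (W < 1) stop("zero-width matrix", call. = FALSE)
  empty <- data.frame(motif_id = character(), offset = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (L < W) return(empty)
  S <- log2((pwm$freq + pwm$pseudocount) / (0.25 + pwm$pseudocount))
  scan_one <- function(s) {
    code <- match(strsplit(s, "", fixed = TRUE)[[1L]],
                  c("A", "C", "G", "T"))
    n_off <- nchar(s) - W + 1L
    vapply(seq_len(n_off), function(o) {
      idx <- code[o:(o + W - 1L)]
      if (anyNA(idx)) return(NA_real_)  # window contains N
      sum(S[cbind(idx, seq_len(W))])
    }, numeric(1))
  }
  fwd <- scan_one(seq)
  rev <- scan_one(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq))))
  hit_f <- which(!is.na(fwd) & fwd >= threshold_bits)
  hit_r <- which(!is.na(rev) & rev >= threshold_bits)
  out <- rbind(
    if (length(hit_f)) data.frame(motif_id = pwm$motif_id,
                                  offset = hit_f - 1L, strand = "+",
                                  score = fwd[hit_f],
                                  stringsAsFactors = FALSE) else NULL,
    if (length(hit_r)) data.frame(motif_id = pwm$motif_id,
                                  offset = L - W - (hit_r - 1L),
                                  strand = "-", score = rev[hit_r],
                                  stringsAsFactors = FALSE) else NULL)
  if (is.null(out)) return(empty)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read/write FASTA sequences
#'
#' Thin wrappers over Biostrings giving named character vectors, the
#' representation the sequence-feature scanners take.
#'
#' @param path FASTA file path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
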