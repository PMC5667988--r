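#' Classify the orientation of an adjacent gene pair
#'
#' With the pair ordered by start coordinate: left on `-` and right on
#' `+` means the 5' ends face each other across the intergenic spacer
#' (divergent, head-to-head — the bidirectional-promoter configuration);
#' left `+` / right `-` is convergent (tail-to-tail); equal strands are
#' tandem. The 5'-end convention follows from half-open coordinates: a
#' `+` gene's TSS is its interval start, a `-` gene's TSS its interval
#' end.
#'
#' @param left,right One-row slices of a [gene_annotation()], ordered by
#'   start coordinate and on the same chromosome.
#' @return One of `"divergent_head_to_head"`,
#'   `"convergent_tail_to_tail"`, `"tandem"`.
#' @export
classify_orientation <- function(left, right) {
  check_pair(left, right)
  if (left$strand == "." || right$strand == ".") {
    stop("cannot classify orientation of an unstranded gene", call. = FALSE)
  }
  if (left$strand == right$strand) return("tandem")
  if (left$strand == "-" && right$strand == "+") {
    "divergent_head_to_head"
  } else {
    "convergent_tail_to_tail"
  }
}

check_pair <- function(left, right) {
  stopifnot(nrow(left) == 1L, nrow(right) == 1L)
  if (left$chrom != right$chrom) {
    stop("genes on different chromosomes", call. = FALSE)
  }
  if (identical(left$gene_id, right$gene_id)) {
    stop("pair must be two distinct genes", call. = FALSE)
  }
  if (left$start > right$start) {
    stop("pair must be ordered by start coordinate", call. = FALSE)
  }
  invisible(TRUE)
}

#' Intergenic interval and distance of an ordered gene pair
#'
#' Under half-open coordinates the intergenic interval is
#' `[left.end, right.start)` and its length equals the base-pair distance
#' exactly; e.g. ends at 32207791 against a start at 32207880 give the
#' 89-bp spacer. Abutting genes give distance 0 with an empty interval;
#' overlapping genes give distance 0 with the `overlap` flag set.
#'
#' @inheritParams classify_orientation
#' @return A list with `chrom`, `start`, `end`, `distance_bp`, `overlap`.
#' @export
intergenic_interval <- function(left, right) {
  check_pair(left, right)
  overlap <- right$start < left$end
  s <- left$end
  e <- max(right$start, left$end)
  list(chrom = left$chrom, start = if (overlap) NA_real_ else s,
       end = if (overlap) NA_real_ else e,
       distance_bp = e - s, overlap = overlap)
}

#' Find candidate bidirectional promoter pairs
#'
#' Walks coordinate-adjacent gene pairs per chromosome, classifies each
#' pair's orientation and flags as bidirectional those in divergent
#' (head-to-head) orientation with an intergenic distance strictly below
#' `max_dist` ("less than 1000 base pairs of intervening sequence").
#' Overlapping pairs are reported but never flagged. Only adjacent pairs
#' are considered: a bidirectional promoter is by definition the spacer
#' between two neighbouring genes.
#'
#' @param annotation A sorted [gene_annotation()]; unstranded genes are
#'   skipped (reported in the `"exclusions"` attribute).
#' @param max_dist Exclusive distance cutoff in bp (default 1000).
#' @return A `data.frame` with one row per adjacent pair: `gene_left`,
#'   `gene_right`, `orientation`, `intergenic_start`, `intergenic_end`,
#'   `distance_bp`, `overlap`, `bidirectional`.
#' @export
find_bidirectional_pairs <- function(annotation, max_dist = 1000L) {
  stopifnot(inherits(annotation, "gene_annotation"))
  skipped <- annotation$gene_id[annotation$strand == "."]
  ann <- annotation[annotation$strand != ".", , drop = FALSE]
  rows <- list()
  for (ch in unique(ann$chrom)) {
    sub <- ann[ann$chrom == ch, , drop = FALSE]
    if (nrow(sub) < 2) next
    for (i in seq_len(nrow(sub) - 1L)) {
      left <- sub[i, , drop = FALSE]
      right <- sub[i + 1L, , drop = FALSE]
      orient <- classify_orientation(left, right)
      ig <- intergenic_interval(left, right)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_left = left$gene_id, gene_right = right$gene_id,
        chrom = ch, orientation = orient,
        intergenic_start = ig$start, intergenic_end = ig$end,
        distance_bp = ig$distance_bp, overlap = ig$overlap,
        bidirectional = orient == "divergent_head_to_head" &&
          !ig$overlap && ig$distance_bp < max_dist,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_left = character(), gene_right = character(),
               chrom = character(), orientation = character(),
               intergenic_start = numeric(), intergenic_end = numeric(),
               distance_bp = numeric(), overlap = logical(),
               bidirectional = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "exclusions") <- skipped
  attr(out, "max_dist") <- max_dist
  out
}
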