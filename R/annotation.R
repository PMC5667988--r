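#' Construct a gene annotation table
#'
#' The coordinate backbone of every analysis stage: a sorted table of
#' strand-aware gene intervals with optional cytoband labels. All
#' coordinates are 0-based half-open, so `end - start` is the gene length
#' in base pairs.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param symbol Character vector of gene symbols (defaults to `gene_id`).
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; 0-based half-open interval per gene.
#' @param strand Character vector over `"+"`, `"-"`, `"."` (`"."` marks an
#'   unstranded feature and is rejected by orientation classification).
#' @param cytoband Optional character vector of band labels; `NA` when not
#'   yet assigned (see [assign_cytobands()]).
#'
#' @return A `data.frame` of class `gene_annotation`, sorted by
#'   `(chrom, start)`.
#' @seealso [read_gene_annotation()], [assign_cytobands()]
#' @export
gene_annotation <- function(gene_id, symbol = gene_id, chrom, start, end,
                            strand = ".", cytoband = NA_character_) {
  n <- length(gene_id)
  df <- data.frame(
    gene_id = as.character(gene_id),
    symbol = as.character(symbol),
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = rep_len(as.character(strand), n),
    cytoband = rep_len(as.character(cytoband), n),
    stringsAsFactors = FALSE
  )
  validate_gene_annotation(df)
}

validate_gene_annotation <- function(df) {
  if (anyDuplicated(df$gene_id)) {
    dup <- unique(df$gene_id[duplicated(df$gene_id)])
    stop("duplicate gene_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(df$start < 0)) stop("negative start coordinate", call. = FALSE)
  if (any(df$end < df$start)) {
    bad <- df$gene_id[df$end < df$start]
    stop("end < start for gene(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'", call. = FALSE)
  }
  df <- df[order(df$chrom, df$start, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}

#' Interval length under the half-open convention
#'
#' @param start,end 0-based half-open coordinates.
#' @return `end - start`, the number of bases covered.
#' @examples
#' interval_length(32207791, 32207880)  # 89
#' @export
interval_length <- function(start, end) {
  stopifnot(all(end >= start))
  end - start
}

#' Construct a cytoband map
#'
#' Named cytogenetic bands partitioning a chromosome (UCSC `cytoBand.txt`
#' semantics: 0-based half-open). Bands must not overlap within a
#' chromosome.
#'
#' @param chrom,start,end Band intervals (0-based half-open).
#' @param name Band names, e.g. `"20q11.21"`.
#' @param gie_stain Optional Giemsa stain codes (kept for round-trips).
#' @return A `data.frame` of class `cytoband_map` sorted by
#'   `(chrom, start)`.
#' @export
cytoband_map <- function(chrom, start, end, name, gie_stain = "gneg") {
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    name = as.character(name),
    gie_stain = rep_len(as.character(gie_stain), length(chrom)),
    stringsAsFactors = FALSE
  )
  if (any(df$end <= df$start)) stop("empty or inverted band", call. = FALSE)
  df <- df[order(df$chrom, df$start, method = "radix"), , drop = FALSE]
  for (ch in unique(df$chrom)) {
    b <- df[df$chrom == ch, ]
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)])) {
      stop("overlapping cytobands on ", ch, call. = FALSE)
    }
  }
  rownames(df) <- NULL
  class(df) <- c("cytoband_map", "data.frame")
  df
}

#' Assign cytoband labels to genes
#'
#' Each gene is labelled with the band containing its start coordinate;
#' a gene straddling a band boundary therefore belongs to the band of its
#' start (documented convention, deterministic for edge cases). The
#' operation is idempotent.
#'
#' @param annotation A [gene_annotation()].
#' @param bands A [cytoband_map()].
#' @return The annotation with its `cytoband` column filled in.
#' @export
assign_cytobands <- function(annotation, bands) {
  stopifnot(inherits(annotation, "gene_annotation"),
            inherits(bands, "cytoband_map"))
  lab <- rep(NA_character_, nrow(annotation))
  for (i in seq_len(nrow(annotation))) {
    hit <- bands$chrom == annotation$chrom[i] &
      bands$start <= annotation$start[i] &
      annotation$start[i] < bands$end
    if (!any(hit)) {
      stop("gene ", annotation$gene_id[i],
           " at ", annotation$chrom[i], ":", annotation$start[i],
           " not covered by any cytoband", call. = FALSE)
    }
    lab[i] <- bands$name[which(hit)[1L]]
  }
  annotation$cytoband <- lab
  annotation
}
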