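#' Read gene annotation from BED or GFF3
#'
#' BED input is interpreted natively as 0-based half-open; GFF3 (1-based,
#' inclusive) is converted to the internal 0-based half-open convention at
#' the boundary, so interval lengths agree between the two dialects. For
#' BED, the name field supplies both `gene_id` and `symbol`; for GFF3,
#' records of type `gene` are kept and `ID`/`Name` attributes map to
#' `gene_id`/`symbol`.
#'
#' @param path Path to the annotation file.
#' @param format `"bed"` (6 columns) or `"gff3"`.
#' @return A [gene_annotation()] sorted by `(chrom, start)`.
#' @export
read_gene_annotation <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "bed") read_bed6(path) else read_gff3_genes(path)
}

# BED reader is in-package: the parse contract requires errors that name
# the offending line, and fixtures round-trip byte-identically through the
# companion writer. Fields may be tab- or space-separated.
read_bed6 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) stop("no records in ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6)) {
    stop("malformed BED line ", which(nf < 6)[1L], ": expected 6 fields, got ",
         nf[which(nf < 6)[1L]], call. = FALSE)
  }
  m <- t(vapply(fields, function(f) f[1:6], character(6)))
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("malformed BED line ", bad[1L], ": non-numeric coordinate",
         call. = FALSE)
  }
  gene_annotation(gene_id = m[, 4], symbol = m[, 4], chrom = m[, 1],
                  start = start, end = end, strand = m[, 6])
}

read_gff3_genes <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("GFF3 parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if ("type" %in% names(S4Vectors::mcols(gr))) {
    keep <- as.character(gr$type) == "gene"
    if (any(keep)) gr <- gr[keep]
  }
  if (length(gr) == 0) stop("no gene records in ", path, call. = FALSE)
  mc <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(mc)) as.character(mc$ID) else NULL
  if (is.null(id) || anyNA(id)) {
    stop("GFF3 gene records must carry an ID attribute", call. = FALSE)
  }
  sym <- if ("Name" %in% names(mc) && !anyNA(mc$Name)) {
    as.character(mc$Name)
  } else {
    id
  }
  gene_annotation(
    gene_id = id, symbol = sym,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # 1-based -> 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Write gene annotation as 6-column BED
#'
#' Emits tab-separated BED (0-based half-open, score 0); the output
#' round-trips losslessly through [read_gene_annotation()] for the fields
#' BED carries (cytoband labels are not part of the format).
#'
#' @param annotation A [gene_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation_bed <- function(annotation, path) {
  stopifnot(inherits(annotation, "gene_annotation"))
  strand <- ifelse(annotation$strand == ".", ".", annotation$strand)
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     annotation$chrom, as.integer(annotation$start),
                     as.integer(annotation$end), annotation$gene_id, strand),
             path)
  invisible(path)
}

#' Read a UCSC-layout cytoband file
#'
#' Expects the `cytoBand.txt` column layout:
#' `chrom<TAB>start<TAB>end<TAB>name<TAB>gieStain`, 0-based half-open.
#'
#' @param path Path to the file.
#' @return A [cytoband_map()].
#' @export
read_cytoband_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "gie_stain"))
  cytoband_map(df$chrom, df$start, df$end, df$name, df$gie_stain)
}

#' @rdname read_cytoband_map
#' @param bands A [cytoband_map()] to serialize.
#' @export
write_cytoband_map <- function(bands, path) {
  stopifnot(inherits(bands, "cytoband_map"))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s", bands$chrom,
                     as.integer(bands$start), as.integer(bands$end),
                     bands$name, bands$gie_stain), path)
  invisible(path)
}
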