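#' Read a genes-by-samples numeric matrix from TSV
#'
#' The expected layout is a header row of sample identifiers and a first
#' column of row identifiers (genes, regulators or microRNAs). Empty cells
#' become `NA` (the explicit missing sentinel carried through all
#' downstream correlation with pairwise deletion); any other non-numeric
#' cell is a parse error, as is a ragged row or a duplicated row id.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix with row and column names.
#' @export
read_omics_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = "\t", quote = "",
                            blank.lines.skip = FALSE)
  if (length(nf) < 2) stop("matrix file needs a header and >=1 row",
                           call. = FALSE)
  if (any(nf != nf[1L])) {
    bad <- which(nf != nf[1L])[1L]
    stop("ragged row at line ", bad, ": ", nf[bad], " fields, expected ",
         nf[1L], call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          na.strings = "")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate row id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad)) {
        stop("non-numeric cell at row ", bad[1L], ", column '",
             names(vals)[j], "': '", col[bad[1L]], "'", call. = FALSE)
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) {
    stop("duplicate sample id in header", call. = FALSE)
  }
  m
}

#' Write a genes-by-samples matrix as TSV
#'
#' Values are serialized with full precision (17 significant digits) so a
#' write/read round-trip is bit-exact.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @param id_col Header label for the row-identifier column.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(mat, path, id_col = "id") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  fmt_cell <- function(v) {
    out <- vapply(v, function(x) {
      if (is.na(x)) "" else format(x, digits = 17, scientific = FALSE,
                                   trim = TRUE)
    }, character(1))
    out
  }
  header <- paste(c(id_col, colnames(mat)), collapse = "\t")
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], fmt_cell(mat[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
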