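#' Venn partition of named sets
#'
#' Assigns every element of the union to exactly one membership
#' signature — a bit string over the input sets in order, e.g. `"110"`
#' for an element of the first two of three sets only. Cells are pairwise
#' disjoint and together exactly cover the union.
#'
#' @param named_sets Named list of 1–8 character vectors.
#' @return A list of class `venn_partition`: `set_names` and `cells`
#'   (signature string -> sorted element vector; only non-empty cells are
#'   kept).
#' @export
venn_partition <- function(named_sets) {
  k <- length(named_sets)
  stopifnot(k >= 1, k <= 8)
  nm <- names(named_sets)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm)) {
    stop("sets must carry unique non-empty names", call. = FALSE)
  }
  sets <- lapply(named_sets, function(s) unique(as.character(s)))
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  if (length(universe) == 0) {
    return(structure(list(set_names = nm, cells = list()),
                     class = "venn_partition"))
  }
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, nrow = length(universe))
  sig <- apply(member, 1L, function(bits) paste(as.integer(bits),
                                                collapse = ""))
  cells <- split(universe, sig)
  cells <- lapply(cells, sort)
  structure(list(set_names = nm, cells = cells), class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("venn_partition over %d sets (%s): %d non-empty cells\n",
              length(x$set_names), paste(x$set_names, collapse = ", "),
              length(x$cells)))
  for (s in names(x$cells)) {
    cat(sprintf("  %s: %d element(s)\n", s, length(x$cells[[s]])))
  }
  invisible(x)
}

#' Retrieve one cell of a Venn partition
#'
#' @param vp A [venn_partition()].
#' @param signature Bit-string signature, e.g. `"110"`.
#' @return Sorted character vector (empty if the cell is empty).
#' @export
venn_cell <- function(vp, signature) {
  stopifnot(inherits(vp, "venn_partition"))
  if (nchar(signature) != length(vp$set_names) ||
      grepl("[^01]", signature)) {
    stop("signature must be a ", length(vp$set_names), "-bit string",
         call. = FALSE)
  }
  cell <- vp$cells[[signature]]
  if (is.null(cell)) character(0) else cell
}

#' @rdname venn_cell
#' @details `venn_full_intersection()` returns the all-ones cell — the
#'   elements shared by every input set.
#' @export
venn_full_intersection <- function(vp) {
  stopifnot(inherits(vp, "venn_partition"))
  venn_cell(vp, strrep("1", length(vp$set_names)))
}

#' Serialize a Venn partition as JSON
#'
#' @param vp A [venn_partition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_venn_json <- function(vp, path) {
  stopifnot(inherits(vp, "venn_partition"))
  jsonlite::write_json(list(set_names = vp$set_names, cells = vp$cells),
                       path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Venn partition of per-gene pathway memberships
#'
#' The dual of the gene-set Venn: pathways are the elements and each
#' gene's pathway set is one input set, so each cell lists the pathways
#' shared by exactly that subset of genes (the layout of a
#' pathways-shared-by-adjacent-genes table).
#'
#' @param gene_pathway_sets Named list (2–8 genes) of pathway-id vectors.
#' @return A [venn_partition()] with pathways as elements.
#' @export
pathway_partition <- function(gene_pathway_sets) {
  k <- length(gene_pathway_sets)
  if (k < 2 || k > 8) stop("need 2-8 genes", call. = FALSE)
  venn_partition(gene_pathway_sets)
}

#' Format a pathway partition as a readable table
#'
#' One row per non-empty cell: the concatenated gene names of the
#' sharing subset, the pathway count, and the pathway list, ordered by
#' decreasing subset size.
#'
#' @param vp A [venn_partition()] from [pathway_partition()].
#' @return A `data.frame` with columns `genes`, `total`, `elements`.
#' @export
format_pathway_table <- function(vp) {
  stopifnot(inherits(vp, "venn_partition"))
  sigs <- names(vp$cells)
  rows <- lapply(sigs, function(s) {
    bits <- as.integer(strsplit(s, "")[[1L]])
    data.frame(genes = paste(vp$set_names[bits == 1L], collapse = ";"),
               n_sharing = sum(bits),
               total = length(vp$cells[[s]]),
               elements = paste(vp$cells[[s]], collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_sharing, -out$total), , drop = FALSE]
  rownames(out) <- NULL
  out[c("genes", "total", "elements")]
}
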