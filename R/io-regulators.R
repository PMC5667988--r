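#' Regulator target-set collections
#'
#' A `regulator_sets` object maps `(regulator, source)` pairs to sets of
#' target gene ids. It is stored in long form (one row per
#' regulator/source/target triple, duplicates collapsed), which makes
#' merging evidence sources a simple `rbind` while keeping entries from
#' different sources distinct.
#'
#' @param regulator,source,target Character vectors of equal length.
#' @return A `data.frame` of class `regulator_sets`.
#' @export
regulator_sets <- function(regulator, source, target) {
  df <- unique(data.frame(regulator = as.character(regulator),
                          source = as.character(source),
                          target = as.character(target),
                          stringsAsFactors = FALSE))
  df <- df[order(df$source, df$regulator, df$target, method = "radix"), ,
           drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("regulator_sets", "data.frame")
  df
}

#' Read regulator target sets from GMT or two-column TSV
#'
#' GMT carries one set per line (`name<TAB>description<TAB>member...`);
#' TSV2COL carries `regulator<TAB>target` rows. Duplicate member mentions
#' are collapsed; an entry with an empty member list is a validation
#' error. Every entry is tagged with the supplied evidence `source`, so
#' the same regulator read from two sources stays distinct.
#'
#' @param path Path to the file.
#' @param format `"gmt"` or `"tsv2col"`.
#' @param source Evidence-source tag (e.g. `"chipseq"`, `"tarbase"`).
#' @return A [regulator_sets()] collection.
#' @export
read_regulator_sets <- function(path, format = c("gmt", "tsv2col"), source) {
  format <- match.arg(format)
  stopifnot(is.character(source), length(source) == 1L)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (format == "gmt") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3)) {
      stop("GMT line ", which(nf < 3)[1L],
           ": empty member list (need name, description, >=1 member)",
           call. = FALSE)
    }
    reg <- rep(vapply(fields, `[`, character(1), 1L), nf - 2L)
    tgt <- unlist(lapply(fields, function(f) f[-(1:2)]), use.names = FALSE)
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 2)) {
      stop("TSV2COL line ", which(nf < 2)[1L], ": expected 2 columns",
           call. = FALSE)
    }
    reg <- vapply(fields, `[`, character(1), 1L)
    tgt <- vapply(fields, `[`, character(1), 2L)
  }
  keep <- nzchar(tgt)
  if (!any(keep)) stop("no targets parsed from ", path, call. = FALSE)
  regulator_sets(reg[keep], source, tgt[keep])
}

#' Write one evidence source of a collection as GMT
#'
#' @param sets A [regulator_sets()] collection.
#' @param path Output path.
#' @param source Which evidence source to serialize.
#' @return `path`, invisibly.
#' @export
write_regulator_gmt <- function(sets, path, source) {
  stopifnot(inherits(sets, "regulator_sets"))
  sub <- sets[sets$source == source, , drop = FALSE]
  if (nrow(sub) == 0) stop("no entries for source '", source, "'",
                           call. = FALSE)
  regs <- unique(sub$regulator)
  writeLines(vapply(regs, function(r) {
    paste(c(r, source, sort(sub$target[sub$regulator == r])),
          collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Merge regulator-set collections
#'
#' Entries remain keyed by `(regulator, source)`; merging the same
#' regulator from two sources keeps two distinct entries.
#'
#' @param ... [regulator_sets()] collections.
#' @return A single merged [regulator_sets()].
#' @export
merge_regulator_sets <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1), "regulator_sets")))
  df <- do.call(rbind, lapply(parts, as.data.frame))
  regulator_sets(df$regulator, df$source, df$target)
}

#' Look up one regulator's target set
#'
#' @param sets A [regulator_sets()] collection.
#' @param regulator Regulator id.
#' @param source Evidence source; `NULL` pools all sources.
#' @return Character vector of target gene ids (possibly empty).
#' @export
regulator_targets <- function(sets, regulator, source = NULL) {
  stopifnot(inherits(sets, "regulator_sets"))
  keep <- sets$regulator == regulator
  if (!is.null(source)) keep <- keep & sets$source == source
  unique(sets$target[keep])
}

#' @export
print.regulator_sets <- function(x, ...) {
  cat(sprintf(
    "regulator_sets: %d (regulator, source) entries, %d triples\n",
    nrow(unique(as.data.frame(x)[c("regulator", "source")])), nrow(x)))
  invisible(x)
}
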