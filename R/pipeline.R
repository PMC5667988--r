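#' Build a pipeline configuration
#'
#' Collects input file paths and every stage threshold with the
#' screening defaults used throughout the package (cis screen r > 0.65
#' at p < 1e-4, co-expression r >= 0.6, strict adjacency, bidirectional
#' distance < 1000 bp, classical CpG-island criteria, ceRNA thresholds).
#' The effective configuration is echoed into the run report for
#' provenance.
#'
#' @param inputs Named list of file paths: `annotation` (BED),
#'   `cytobands`, `mrna`, `cna`, `mirna`, `tf_gmt` (named by source tag
#'   if a character vector), `mirna_gmt` (character vector named by
#'   source tag), `spacers_fasta` (optional).
#' @param seed_gene Seed gene id for the neighborhood stage.
#' @param cerna_pairs Optional two-column matrix of gene pairs for the
#'   ceRNA stage; defaults to all flagged bidirectional pairs plus
#'   adjacent pairs inside recovered clusters.
#' @param out_dir Output directory for stage reports.
#' @param r_min_cis,alpha_cis Cis-screen thresholds.
#' @param r_min_coexpr Co-expression profile threshold (inclusive).
#' @param max_gap,min_size Adjacency-clustering parameters.
#' @param max_dist Bidirectional-promoter distance cutoff (exclusive).
#' @param cpg_len_min,cpg_gc_min,cpg_oe_min,cpg_window CpG-island scan
#'   parameters.
#' @param cerna_min_shared,cerna_r_pair_min,cerna_min_support,cerna_alpha
#'   ceRNA calling thresholds.
#' @param seed Integer seed echoed into the report.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs, seed_gene, out_dir,
                            cerna_pairs = NULL,
                            r_min_cis = 0.65, alpha_cis = 1e-4,
                            r_min_coexpr = 0.6, max_gap = 0L,
                            min_size = 2L, max_dist = 1000L,
                            cpg_len_min = 200L, cpg_gc_min = 0.5,
                            cpg_oe_min = 0.6, cpg_window = 100L,
                            cerna_min_shared = 5L, cerna_r_pair_min = 0.6,
                            cerna_min_support = 3L, cerna_alpha = 0.05,
                            seed = 1L) {
  structure(list(inputs = inputs, seed_gene = seed_gene,
                 cerna_pairs = cerna_pairs, out_dir = out_dir,
                 r_min_cis = r_min_cis, alpha_cis = alpha_cis,
                 r_min_coexpr = r_min_coexpr, max_gap = max_gap,
                 min_size = min_size, max_dist = max_dist,
                 cpg_len_min = cpg_len_min, cpg_gc_min = cpg_gc_min,
                 cpg_oe_min = cpg_oe_min, cpg_window = cpg_window,
                 cerna_min_shared = cerna_min_shared,
                 cerna_r_pair_min = cerna_r_pair_min,
                 cerna_min_support = cerna_min_support,
                 cerna_alpha = cerna_alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Any field of [pipeline_config()] may appear in the file; omitted
#' fields keep their defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(is.list(y), !is.null(y$inputs), !is.null(y$seed_gene),
            !is.null(y$out_dir))
  known <- names(formals(pipeline_config))
  do.call(pipeline_config, y[intersect(names(y), known)])
}

#' Validate a pipeline configuration
#'
#' Returns findings instead of throwing: blocking `error` rows (missing
#' input files, thresholds outside documented ranges) and non-blocking
#' `warning` rows (e.g. a CpG minimum length below the classical 200 bp,
#' which admits short promoter-spacer islands but is non-standard).
#'
#' @param config A [pipeline_config()].
#' @return A `data.frame` with columns `level`, `field`, `message`;
#'   zero rows when the configuration is clean.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  finding <- function(level, field, message) {
    data.frame(level = level, field = field, message = message,
               stringsAsFactors = FALSE)
  }
  out <- list()
  required <- c("annotation", "cytobands", "mrna", "cna")
  for (f in required) {
    if (is.null(config$inputs[[f]])) {
      out[[length(out) + 1L]] <- finding("error", paste0("inputs$", f),
                                         "required input missing")
    }
  }
  for (f in names(config$inputs)) {
    for (path in config$inputs[[f]]) {
      if (!is.null(path) && !file.exists(path)) {
        out[[length(out) + 1L]] <- finding(
          "error", paste0("inputs$", f), paste0("file not found: ", path))
      }
    }
  }
  chk01 <- function(field, lo = 0, hi = 1) {
    v <- config[[field]]
    if (!is.numeric(v) || v < lo || v > hi) {
      out[[length(out) + 1L]] <<- finding(
        "error", field, sprintf("must lie in [%g, %g]", lo, hi))
    }
  }
  chk01("r_min_cis", -1, 1); chk01("r_min_coexpr", -1, 1)
  chk01("cerna_r_pair_min", -1, 1)
  chk01("alpha_cis"); chk01("cerna_alpha")
  chk01("cpg_gc_min"); chk01("cpg_oe_min", 0, Inf)
  if (config$max_gap < 0) {
    out[[length(out) + 1L]] <- finding("error", "max_gap",
                                       "must be >= 0")
  }
  if (config$min_size < 1) {
    out[[length(out) + 1L]] <- finding("error", "min_size",
                                       "must be >= 1")
  }
  if (config$max_dist < 1) {
    out[[length(out) + 1L]] <- finding("error", "max_dist",
                                       "must be >= 1")
  }
  if (config$cpg_len_min < 200) {
    out[[length(out) + 1L]] <- finding(
      "warning", "cpg_len_min",
      "below the classical 200 bp island minimum; short islands will be reported")
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(level = character(), field = character(),
               message = character(), stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — input parsing, cis screen,
#' neighborhood profiling/clustering, promoter-pair classification with
#' sequence features, shared-regulator analysis, ceRNA calling — writing
#' one TSV per stage plus a JSON run report into `config$out_dir`. A
#' stage failure halts the run but preserves the completed stages'
#' outputs. With `resume = TRUE`, stages whose cached state is already
#' present in the output directory are loaded instead of recomputed;
#' because every stage is deterministic the downstream results are
#' identical either way.
#'
#' @param config A validated [pipeline_config()].
#' @param resume Reuse cached per-stage state when present.
#' @return A list of class `run_report`: per-stage summaries, the
#'   effective config, package version and accumulated warnings.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  findings <- validate_config(config)
  if (any(findings$level == "error")) {
    stop("configuration errors:\n",
         paste(sprintf("  %s: %s", findings$field, findings$message)
               [findings$level == "error"], collapse = "\n"),
         call. = FALSE)
  }
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cache_dir <- file.path(out_dir, ".cache")
  if (!dir.exists(cache_dir)) dir.create(cache_dir)
  report <- list(package = "adjacoex",
                 version = as.character(utils::packageVersion("adjacoex")),
                 config = unclass(config), stages = list(),
                 warnings = as.list(findings$message[
                   findings$level == "warning"]))
  state <- new.env(parent = emptyenv())
  run_stage <- function(name, fun) {
    cache <- file.path(cache_dir, paste0(name, ".rds"))
    t0 <- proc.time()[["elapsed"]]
    if (resume && file.exists(cache)) {
      saved <- readRDS(cache)
      for (nm in names(saved$state)) assign(nm, saved$state[[nm]], state)
      summary <- saved$summary
      status <- "resumed"
    } else {
      summary <- tryCatch(fun(), error = function(e) {
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
      saveRDS(list(state = as.list(state), summary = summary), cache)
      status <- "ok"
    }
    # timing and resumption go to stderr only: report files stay
    # byte-identical across (resumed) reruns of the same config and seed
    report$stages[[name]] <<- c(list(status = "ok"), summary)
    message(sprintf("[%s] %s (%.2fs)", name, status,
                    proc.time()[["elapsed"]] - t0))
  }

  run_stage("io", function() {
    state$annotation <- assign_cytobands(
      read_gene_annotation(config$inputs$annotation, "bed"),
      read_cytoband_map(config$inputs$cytobands))
    state$mrna <- read_omics_matrix(config$inputs$mrna)
    state$cna <- read_omics_matrix(config$inputs$cna)
    state$mirna <- if (!is.null(config$inputs$mirna)) {
      read_omics_matrix(config$inputs$mirna)
    }
    read_tagged <- function(paths) {
      if (is.null(paths)) return(NULL)
      tags <- names(paths)
      if (is.null(tags)) tags <- sub("\\.gmt$", "", basename(paths))
      do.call(merge_regulator_sets, lapply(seq_along(paths), function(i) {
        read_regulator_sets(paths[[i]], "gmt", tags[[i]])
      }))
    }
    state$tf_sets <- read_tagged(config$inputs$tf_gmt)
    state$mirna_sets <- read_tagged(config$inputs$mirna_gmt)
    state$spacers <- if (!is.null(config$inputs$spacers_fasta)) {
      read_fasta(config$inputs$spacers_fasta)
    }
    list(n_genes = nrow(state$annotation),
         n_samples = ncol(state$mrna))
  })

  run_stage("correlate", function() {
    scr <- cna_mrna_screen(state$cna, state$mrna,
                           r_min = config$r_min_cis,
                           alpha = config$alpha_cis)
    state$cis_screen <- scr
    utils::write.table(scr, file.path(out_dir, "cis_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_cis_driven = sum(scr$cis_driven),
         n_excluded = nrow(attr(scr, "exclusions")))
  })

  run_stage("neighborhood", function() {
    prof <- seed_profile(state$mrna, config$seed_gene)
    sig <- threshold_profile(prof, config$r_min_coexpr)
    bf <- band_fractions(sig, state$annotation)
    cl <- adjacency_clusters(union(sig, config$seed_gene),
                             state$annotation, config$max_gap,
                             config$min_size, profile = prof)
    state$profile <- prof; state$significant <- sig
    state$band_table <- bf; state$clusters <- cl
    utils::write.table(as.data.frame(prof),
                       file.path(out_dir, "seed_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(bf, file.path(out_dir, "band_fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    flat <- cl[setdiff(names(cl), "members")]
    flat$members <- vapply(cl$members, paste, character(1), collapse = ";")
    utils::write.table(flat, file.path(out_dir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(seed = config$seed_gene, n_significant = length(sig),
         n_clusters = nrow(cl))
  })

  run_stage("promoters", function() {
    pairs <- find_bidirectional_pairs(state$annotation, config$max_dist)
    state$promoter_pairs <- pairs
    bidir <- pairs[pairs$bidirectional, , drop = FALSE]
    feats <- NULL
    if (!is.null(state$spacers) && nrow(bidir)) {
      feats <- do.call(rbind, lapply(seq_len(nrow(bidir)), function(i) {
        nm <- paste0("spacer_", bidir$gene_left[i], "_",
                     bidir$gene_right[i])
        if (!nm %in% names(state$spacers)) return(NULL)
        s <- state$spacers[[nm]]
        isl <- cpg_island_scan(
          s, len_min = config$cpg_len_min, gc_min = config$cpg_gc_min,
          oe_min = config$cpg_oe_min,
          window = min(config$cpg_window, nchar(s)))
        data.frame(gene_left = bidir$gene_left[i],
                   gene_right = bidir$gene_right[i],
                   spacer_len = nchar(s), n_cpg_islands = nrow(isl),
                   tata_less = !tata_scan(s)$found,
                   stringsAsFactors = FALSE)
      }))
    }
    state$promoter_features <- feats
    utils::write.table(pairs, file.path(out_dir, "promoter_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(feats)) {
      utils::write.table(feats,
                         file.path(out_dir, "promoter_features.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    list(n_pairs = nrow(pairs), n_bidirectional = sum(pairs$bidirectional))
  })

  run_stage("regulators", function() {
    if (is.null(state$tf_sets)) return(list(skipped = "no tf_gmt input"))
    query <- state$significant
    enr <- shared_regulator_enrichment(state$tf_sets,
                                       query = intersect(query,
                                                         rownames(state$mrna)),
                                       universe = rownames(state$mrna))
    state$tf_enrichment <- enr
    utils::write.table(enr, file.path(out_dir, "tf_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_regulators = nrow(enr),
         top_regulator = if (nrow(enr)) enr$regulator[1L] else NA)
  })

  run_stage("cerna", function() {
    if (is.null(state$mirna_sets) || is.null(state$mirna)) {
      return(list(skipped = "no miRNA inputs"))
    }
    pairs <- config$cerna_pairs
    if (is.null(pairs)) {
      bidir <- state$promoter_pairs[state$promoter_pairs$bidirectional, ,
                                    drop = FALSE]
      cl_pairs <- do.call(rbind, lapply(state$clusters$members,
                                        function(mem) {
        if (length(mem) < 2) return(NULL)
        cbind(mem[-length(mem)], mem[-1L])
      }))
      pairs <- unique(rbind(cbind(bidir$gene_left, bidir$gene_right),
                            cl_pairs))
      tgt <- unique(state$mirna_sets$target)
      covered <- pairs[, 1L] %in% tgt & pairs[, 2L] %in% tgt
      extra <- t(vapply(
        unique(state$mirna_sets$regulator), function(m) {
          tg <- sort(intersect(regulator_targets(state$mirna_sets, m),
                               rownames(state$mrna)))
          if (length(tg) == 2) tg else c(NA_character_, NA_character_)
        }, character(2)))
      extra <- extra[!is.na(extra[, 1L]), , drop = FALSE]
      pairs <- unique(rbind(pairs[covered, , drop = FALSE], extra))
    }
    if (nrow(pairs) == 0) return(list(skipped = "no candidate pairs"))
    cand <- cerna_candidates(pairs, state$mirna_sets, state$mrna,
                             state$mirna,
                             min_shared = config$cerna_min_shared,
                             r_pair_min = config$cerna_r_pair_min,
                             min_support = config$cerna_min_support,
                             alpha = config$cerna_alpha)
    state$cerna <- cand
    flat <- cand[setdiff(names(cand), "shared_union")]
    utils::write.table(flat, file.path(out_dir, "cerna_candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_pairs_tested = nrow(cand), n_verdict_true = sum(cand$verdict))
  })

  class(report) <- "run_report"
  jsonlite::write_json(unclass_report(report),
                       file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report
}

unclass_report <- function(report) {
  r <- unclass(report)
  r$config$cerna_pairs <- NULL
  r
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report (adjacoex %s): %d stage(s)\n", x$version,
              length(x$stages)))
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    extra <- setdiff(names(st), "status")
    cat(sprintf("  %-12s %-8s %s\n", nm, st$status,
                paste(sprintf("%s=%s", extra,
                              vapply(st[extra], function(v)
                                paste(format(v), collapse = ","),
                                character(1))),
                      collapse = " ")))
  }
  invisible(x)
}
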