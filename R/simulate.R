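#' Simulation configuration with planted structure
#'
#' Describes a single synthetic chromosome arm carrying every feature the
#' analysis is designed to detect: focal amplification segments whose
#' genes share per-sample copy-number gains, linear cis effects of copy
#' number on expression, blocks of physically adjacent genes coupled
#' through a shared latent factor, divergent (head-to-head) gene pairs
#' with CpG-rich TATA-less spacers, and pairs of genes repressed by the
#' same planted microRNAs (the ceRNA configuration).
#'
#' The expression model is linear-Gaussian:
#' `expr(g,s) = mu + beta_cna[g] * (cna(g,s) - 2) + sum_b tau_b * f_b(s)
#' - sum_m gamma_m * m(s) + eps`, with `f_b` and `m` standard-normal
#' latent sample factors and `eps ~ N(0, sigma^2)`.
#'
#' Defaults describe the reference fixture: 60 genes in 8 bands on one
#' arm, 200 samples, two focal amplification segments (gain +2 with
#' per-sample probability 0.5), `beta_cna = 1` inside amplified segments
#' and 0 outside, two planted co-expression blocks of sizes 5 and 3 with
#' `tau = 1.5`, one divergent pair at an 89-bp CpG-rich spacer, one gene
#' pair repressed by 6 shared miRNAs with `gamma = 1`, and `sigma = 1`.
#'
#' @param n_genes,n_samples,n_bands Genome and cohort dimensions.
#' @param amp_segments List of segments, each
#'   `list(bands = <band indices>, p_amp = <gain probability>,
#'   gain = <copy gain>)`, optionally with a per-segment `beta`
#'   overriding `beta_cna` (set `beta = 0` to plant a "passenger"
#'   amplification whose genes gain copies without a dosage effect on
#'   expression).
#' @param beta_cna Scalar cis-effect slope applied to genes inside
#'   amplification segments (0 elsewhere), or a full length-`n_genes`
#'   vector.
#' @param coexpr_blocks List of blocks, each
#'   `list(genes = <consecutive gene indices>, tau = <effect size>)`.
#' @param divergent_pairs List of pairs, each
#'   `list(genes = c(i, i + 1), spacer = <bp>, cpg_rich = <flag>)`.
#' @param mirna_links List of links, each `list(mirna = <id>,
#'   targets = <gene indices>, gamma = <repression strength>,
#'   sources = <evidence-source tags>)`.
#' @param noise_sd Residual standard deviation `sigma`.
#' @param mu Baseline expression mean (log2-like scale).
#' @param n_decoy_tfs,n_decoy_mirnas Decoy regulators with random target
#'   sets and no expression effect, written alongside the planted ones.
#' @param seed Integer seed governing every random draw.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 60L, n_samples = 200L, n_bands = 8L,
                       amp_segments = list(
                         list(bands = 1L, p_amp = 0.5, gain = 2),
                         list(bands = 5L, p_amp = 0.5, gain = 2)),
                       beta_cna = 1,
                       coexpr_blocks = list(
                         list(genes = 11:15, tau = 1.5),
                         list(genes = 32:34, tau = 1.5)),
                       divergent_pairs = list(
                         list(genes = c(21L, 22L), spacer = 89L,
                              cpg_rich = TRUE)),
                       mirna_links = default_mirna_links(),
                       noise_sd = 1, mu = 8,
                       n_decoy_tfs = 10L, n_decoy_mirnas = 6L,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples = as.integer(n_samples),
              n_bands = as.integer(n_bands),
              amp_segments = amp_segments, beta_cna = beta_cna,
              coexpr_blocks = coexpr_blocks,
              divergent_pairs = divergent_pairs,
              mirna_links = mirna_links, noise_sd = noise_sd, mu = mu,
              n_decoy_tfs = as.integer(n_decoy_tfs),
              n_decoy_mirnas = as.integer(n_decoy_mirnas),
              seed = as.integer(seed))
  validate_sim_config(cfg)
}

# 6 miRNAs repressing the gene pair (41, 42), split across three
# evidence sources so the per-source intersections differ but pool to a
# union of 6.
default_mirna_links <- function() {
  srcs <- list(c("tarbase"), c("tarbase", "mirtarbase"), c("mirtarbase"),
               c("mirtarbase", "starbase"), c("starbase"), c("starbase"))
  lapply(1:6, function(i) {
    list(mirna = sprintf("mir-sim-%02d", i), targets = c(41L, 42L),
         gamma = 1, sources = srcs[[i]])
  })
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 2, cfg$n_samples >= 3, cfg$n_bands >= 1,
            cfg$noise_sd >= 0)
  for (seg in cfg$amp_segments) {
    if (seg$p_amp < 0 || seg$p_amp > 1) {
      stop("p_amp must lie in [0, 1]", call. = FALSE)
    }
    if (any(seg$bands < 1 | seg$bands > cfg$n_bands)) {
      stop("amp segment references band outside 1..n_bands", call. = FALSE)
    }
  }
  for (blk in cfg$coexpr_blocks) {
    idx <- sort(blk$genes)
    if (any(diff(idx) != 1L)) {
      stop("co-expression block members must be consecutive gene indices",
           call. = FALSE)
    }
    if (min(idx) < 1 || max(idx) > cfg$n_genes) {
      stop("block gene index out of range", call. = FALSE)
    }
  }
  for (dp in cfg$divergent_pairs) {
    if (length(dp$genes) != 2 || diff(sort(dp$genes)) != 1L) {
      stop("divergent pair must be two consecutive gene indices",
           call. = FALSE)
    }
    if (dp$spacer < 1) stop("spacer length must be >= 1", call. = FALSE)
  }
  for (ml in cfg$mirna_links) {
    if (any(ml$targets < 1 | ml$targets > cfg$n_genes)) {
      stop("mirna link target index out of range", call. = FALSE)
    }
  }
  if (!length(cfg$beta_cna) %in% c(1L, cfg$n_genes)) {
    stop("beta_cna must be a scalar or length n_genes", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Lay out the synthetic genome
#'
#' Places `n_genes` non-overlapping genes along one chromosome arm
#' (deterministically, so two runs of the same config agree byte for
#' byte), partitions the arm into `n_bands` contiguous named bands, and
#' records the planted ground truth. Divergent pairs are placed
#' head-to-head (`-` then `+`) separated by exactly the requested spacer
#' under the half-open convention; all other genes sit on `+` with a
#' 30-kb gap.
#'
#' @param config A [sim_config()].
#' @return A list: `annotation` ([gene_annotation()] with bands
#'   assigned), `bands` ([cytoband_map()]), `truth` (planted structure:
#'   gene ids per block/pair/segment, per-gene `beta_cna`, miRNA target
#'   registry, band truth labels).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  gene_len <- 20000L
  gap <- 30000L
  arm_start <- 30000000L
  pair_left <- vapply(config$divergent_pairs,
                      function(dp) min(dp$genes), integer(1))
  spacer_of <- stats::setNames(
    vapply(config$divergent_pairs, function(dp) as.integer(dp$spacer),
           integer(1)), pair_left)
  start <- numeric(n); end <- numeric(n)
  cursor <- arm_start
  for (i in seq_len(n)) {
    start[i] <- cursor
    end[i] <- cursor + gene_len
    after <- if (as.character(i) %in% names(spacer_of)) {
      spacer_of[[as.character(i)]]
    } else {
      gap
    }
    cursor <- end[i] + after
  }
  arm_end <- cursor
  strand <- rep("+", n)
  for (dp in config$divergent_pairs) {
    strand[min(dp$genes)] <- "-"
    strand[max(dp$genes)] <- "+"
  }
  gene_id <- sprintf("G%03d", seq_len(n))
  band_names <- if (config$n_bands == 8L) {
    c("20q11.21", "20q11.22", "20q11.23", "20q13.12",
      "20q13.13", "20q13.31", "20q13.32", "20q13.33")
  } else {
    sprintf("20q%02d", seq_len(config$n_bands))
  }
  edges <- round(seq(arm_start, arm_end, length.out = config$n_bands + 1L))
  bands <- cytoband_map(chrom = "chr20", start = edges[-length(edges)],
                        end = edges[-1L], name = band_names,
                        gie_stain = "gneg")
  ann <- gene_annotation(gene_id = gene_id, chrom = "chr20",
                         start = start, end = end, strand = strand)
  ann <- assign_cytobands(ann, bands)
  band_idx <- match(ann$cytoband, band_names)
  seg_genes <- lapply(config$amp_segments, function(seg) {
    gene_id[band_idx %in% seg$bands]
  })
  beta <- if (length(config$beta_cna) == n) {
    as.numeric(config$beta_cna)
  } else {
    b <- rep(0, n)
    for (k in seq_along(config$amp_segments)) {
      seg_beta <- config$amp_segments[[k]]$beta
      if (is.null(seg_beta)) seg_beta <- as.numeric(config$beta_cna)
      b[gene_id %in% seg_genes[[k]]] <- seg_beta
    }
    b
  }
  truth <- list(
    gene_id = gene_id,
    band_truth = stats::setNames(band_names[band_idx], gene_id),
    segments = lapply(seq_along(config$amp_segments), function(k) {
      list(genes = seg_genes[[k]],
           p_amp = config$amp_segments[[k]]$p_amp,
           gain = config$amp_segments[[k]]$gain)
    }),
    beta_cna = stats::setNames(beta, gene_id),
    blocks = lapply(config$coexpr_blocks, function(blk) {
      list(genes = gene_id[sort(blk$genes)], tau = blk$tau)
    }),
    divergent_pairs = lapply(config$divergent_pairs, function(dp) {
      list(gene_left = gene_id[min(dp$genes)],
           gene_right = gene_id[max(dp$genes)],
           spacer = as.integer(dp$spacer),
           cpg_rich = isTRUE(dp$cpg_rich))
    }),
    mirna_links = lapply(config$mirna_links, function(ml) {
      list(mirna = ml$mirna, targets = gene_id[sort(ml$targets)],
           gamma = ml$gamma, sources = ml$sources)
    })
  )
  list(annotation = ann, bands = bands, truth = truth)
}

#' Simulate the copy-number matrix
#'
#' Baseline copy level 2 everywhere; per sample, each amplification
#' segment gains its magnitude with probability `p_amp`, and all genes
#' inside a gained segment share the gain (a focal amplification). The
#' realized matrix is stored back into the truth for downstream stages.
#'
#' @param truth Truth component from [simulate_genome()].
#' @param config The same [sim_config()].
#' @return A genes-by-samples numeric matrix of copy levels.
#' @export
simulate_cna <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_genes
  s <- config$n_samples
  samples <- sprintf("S%03d", seq_len(s))
  cna <- matrix(2, nrow = n, ncol = s,
                dimnames = list(truth$gene_id, samples))
  for (seg in truth$segments) {
    gained <- stats::rbinom(s, 1L, seg$p_amp) == 1L
    cna[seg$genes, gained] <- cna[seg$genes, gained] + seg$gain
  }
  cna
}

#' Simulate mRNA and miRNA expression
#'
#' Draws latent standard-normal sample factors for each co-expression
#' block and each planted miRNA, then emits the linear-Gaussian model of
#' [sim_config()]. The miRNA matrix reports the latent miRNA abundances
#' (planted links plus inert decoys).
#'
#' @param truth Truth component from [simulate_genome()].
#' @param cna Copy-number matrix from [simulate_cna()].
#' @param config The same [sim_config()].
#' @return A list: `mrna` and `mirna` matrices (columns = samples).
#' @export
simulate_expression <- function(truth, cna, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  n <- config$n_genes
  s <- config$n_samples
  samples <- colnames(cna)
  expr <- config$mu +
    truth$beta_cna[truth$gene_id] * (cna - 2) +
    matrix(stats::rnorm(n * s, 0, config$noise_sd), n, s)
  dimnames(expr) <- list(truth$gene_id, samples)
  for (blk in truth$blocks) {
    f <- stats::rnorm(s)
    expr[blk$genes, ] <- expr[blk$genes, ] +
      blk$tau * matrix(f, length(blk$genes), s, byrow = TRUE)
  }
  planted <- vapply(truth$mirna_links, `[[`, character(1), "mirna")
  mir_ids <- c(planted,
               if (config$n_decoy_mirnas > 0)
                 sprintf("mir-decoy-%02d", seq_len(config$n_decoy_mirnas)))
  mirna <- matrix(stats::rnorm(length(mir_ids) * s), length(mir_ids), s,
                  dimnames = list(mir_ids, samples))
  for (ml in truth$mirna_links) {
    m <- mirna[ml$mirna, ]
    expr[ml$targets, ] <- expr[ml$targets, ] -
      ml$gamma * matrix(m, length(ml$targets), s, byrow = TRUE)
  }
  list(mrna = expr, mirna = mirna)
}

#' Generate a complete synthetic bundle in memory
#'
#' Runs [simulate_genome()], [simulate_cna()] and
#' [simulate_expression()], then derives the regulator-set collections
#' (one planted "TF" per co-expression block plus random decoys; miRNA
#' target sets per evidence source from the planted links plus decoys)
#' and the spacer sequences of the divergent pairs (CpG-rich where
#' flagged).
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_bundle`: `config`, `annotation`,
#'   `bands`, `truth`, `cna`, `mrna`, `mirna`, `tf_sets`, `mirna_sets`,
#'   `spacers`.
#' @export
simulate_bundle <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- simulate_genome(config)
  cna <- simulate_cna(g$truth, config)
  ex <- simulate_expression(g$truth, cna, config)
  set.seed(config$seed + 3L)
  tf_reg <- character(0); tf_tgt <- character(0)
  for (k in seq_along(g$truth$blocks)) {
    blk <- g$truth$blocks[[k]]
    tf_reg <- c(tf_reg, rep(sprintf("TF-block-%d", k), length(blk$genes)))
    tf_tgt <- c(tf_tgt, blk$genes)
  }
  if (config$n_decoy_tfs > 0) {
    for (k in seq_len(config$n_decoy_tfs)) {
      tgt <- sample(g$truth$gene_id, 5L)
      tf_reg <- c(tf_reg, rep(sprintf("TF-decoy-%02d", k), length(tgt)))
      tf_tgt <- c(tf_tgt, tgt)
    }
  }
  tf_sets <- regulator_sets(tf_reg, "chipseq_sim", tf_tgt)
  mir_reg <- character(0); mir_src <- character(0); mir_tgt <- character(0)
  for (ml in g$truth$mirna_links) {
    for (src in ml$sources) {
      mir_reg <- c(mir_reg, rep(ml$mirna, length(ml$targets)))
      mir_src <- c(mir_src, rep(src, length(ml$targets)))
      mir_tgt <- c(mir_tgt, ml$targets)
    }
  }
  all_sources <- unique(mir_src)
  if (length(all_sources) == 0) all_sources <- "tarbase"
  if (config$n_decoy_mirnas > 0) {
    for (k in seq_len(config$n_decoy_mirnas)) {
      src <- sample(all_sources, 1L)
      tgt <- sample(g$truth$gene_id, 2L)
      mir_reg <- c(mir_reg, rep(sprintf("mir-decoy-%02d", k), length(tgt)))
      mir_src <- c(mir_src, rep(src, length(tgt)))
      mir_tgt <- c(mir_tgt, tgt)
    }
  }
  mirna_sets <- regulator_sets(mir_reg, mir_src, mir_tgt)
  spacers <- character(0)
  for (dp in g$truth$divergent_pairs) {
    nm <- paste0("spacer_", dp$gene_left, "_", dp$gene_right)
    spacers[nm] <- random_spacer(dp$spacer, dp$cpg_rich)
  }
  structure(list(config = config, annotation = g$annotation,
                 bands = g$bands, truth = g$truth, cna = cna,
                 mrna = ex$mrna, mirna = ex$mirna, tf_sets = tf_sets,
                 mirna_sets = mirna_sets, spacers = spacers),
            class = "sim_bundle")
}

# A spacer sequence of length n. CpG-rich spacers are drawn with elevated
# C/G frequency and redrawn until GC >= 0.5 and obs/exp CpG >= 0.6 hold,
# so the constraint is guaranteed by construction; plain spacers have
# every CpG dinucleotide broken, pinning obs/exp at 0.
random_spacer <- function(n, cpg_rich) {
  if (cpg_rich) {
    repeat {
      units <- sample(c("CG", "GC", "AT", "TA", "CC", "GG"),
                      ceiling(n / 2), replace = TRUE,
                      prob = c(0.35, 0.15, 0.1, 0.1, 0.15, 0.15))
      s <- substr(paste(units, collapse = ""), 1L, n)
      b <- strsplit(s, "")[[1L]]
      gc <- mean(b %in% c("C", "G"))
      ncg <- sum(b[-length(b)] == "C" & b[-1L] == "G")
      nc <- sum(b == "C"); ng <- sum(b == "G")
      oe <- if (nc > 0 && ng > 0) ncg * n / (nc * ng) else 0
      if (gc >= 0.5 && oe >= 0.6) return(s)
    }
  }
  b <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  cg <- which(b[-length(b)] == "C" & b[-1L] == "G")
  while (length(cg)) {  # break CpGs so obs/exp = 0 exactly
    b[cg + 1L] <- "A"
    cg <- which(b[-length(b)] == "C" & b[-1L] == "G")
  }
  paste(b, collapse = "")
}

#' Write a synthetic bundle to disk
#'
#' Serializes every component through the package's format writers: BED
#' annotation, UCSC-layout `cytoBand.txt`, TSV matrices (mRNA, CNA,
#' miRNA), one GMT per regulator collection and evidence source, FASTA
#' spacers, and a JSON truth manifest. Re-reading the files reproduces
#' the in-memory objects exactly, and identical configs produce
#' byte-identical bundles.
#'
#' @param bundle A [simulate_bundle()] result.
#' @param dir Output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create directory ", dir,
                                      call. = FALSE)
  }
  p <- function(f) file.path(dir, f)
  files <- c(annotation = p("genes.bed"), bands = p("cytoBand.txt"),
             mrna = p("mrna.tsv"), cna = p("cna.tsv"),
             mirna = p("mirna.tsv"), tf = p("tf_chipseq_sim.gmt"),
             spacers = p("spacers.fa"), truth = p("truth.json"))
  write_gene_annotation_bed(bundle$annotation, files["annotation"])
  write_cytoband_map(bundle$bands, files["bands"])
  write_omics_matrix(bundle$mrna, files["mrna"], id_col = "gene")
  write_omics_matrix(bundle$cna, files["cna"], id_col = "gene")
  write_omics_matrix(bundle$mirna, files["mirna"], id_col = "mirna")
  write_regulator_gmt(bundle$tf_sets, files["tf"], "chipseq_sim")
  for (src in sort(unique(bundle$mirna_sets$source))) {
    f <- p(sprintf("mirna_%s.gmt", src))
    write_regulator_gmt(bundle$mirna_sets, f, src)
    files[paste0("mirna_", src)] <- f
  }
  if (length(bundle$spacers)) write_fasta(bundle$spacers, files["spacers"])
  jsonlite::write_json(bundle$truth, files["truth"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(files)
}
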