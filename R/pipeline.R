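#' Pipeline configuration
#'
#' A single JSON-serialisable configuration covering every stage; unknown
#' keys are rejected and the resolved configuration is echoed into the
#' output directory for provenance.
#'
#' @param seed master seed.
#' @param out_dir artifact directory.
#' @param n_fusions,n_simulants event counts for the simulate stage.
#' @param n_nuclei,bin_depth,n_bins single-nucleus layer parameters.
#' @param reps expression replicates per stage.
#' @param stages stage toggles (character subset of simulate, call, enrich,
#'   cna, expr).
#' @param sim overrides passed to [sim_config()] as a named list.
#' @param call overrides for [call_fusions()] (k, max_mismatch, tol,
#'   family_margin, min_support).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("telocrisis_"),
                            n_fusions = 300L, n_simulants = 2000L,
                            n_nuclei = 8L, bin_depth = 500, n_bins = 1000L,
                            reps = 3L,
                            stages = c("simulate", "call", "enrich", "cna",
                                       "expr"),
                            sim = list(), call = list()) {
  known_sim <- names(formals(sim_config))
  unk <- setdiff(names(sim), known_sim)
  if (length(unk) > 0) stop("unknown sim config key: ", unk[1])
  known_call <- c("k", "max_mismatch", "max_ins", "min_seg", "tol",
                  "family_margin", "ins_window", "min_support")
  unk <- setdiff(names(call), known_call)
  if (length(unk) > 0) stop("unknown call config key: ", unk[1])
  bad <- setdiff(stages, c("simulate", "call", "enrich", "cna", "expr"))
  if (length(bad) > 0) stop("unknown stage: ", bad[1])
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_fusions = as.integer(n_fusions),
                 n_simulants = as.integer(n_simulants),
                 n_nuclei = as.integer(n_nuclei), bin_depth = bin_depth,
                 n_bins = as.integer(n_bins), reps = as.integer(reps),
                 stages = stages, sim = sim, call = call),
            class = "pipeline_config")
}

#' Run the full analysis pipeline on simulated data
#'
#' Simulate (reference, fusions, simulants, nuclei bins, counts), call
#' fusions from reads, compute enrichment statistics against the simulant
#' null, call per-nucleus copy-number segments and intersect them with
#' fusions, and link fused genes to expression. Artifacts (calls TSV/BED,
#' enrichment TSVs, segments, summary JSON, resolved config) are written
#' to `cfg$out_dir`; every number in the summary comes straight from a
#' module operation.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, the summary list.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  scfg <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
  jsonlite::write_json(cfg[setdiff(names(cfg), "out_dir")],
                       file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  summary <- list(seed = cfg$seed)

  say("building reference ...")
  ref <- build_reference(scfg)
  sizes <- chrom_sizes(ref)

  sim <- NULL; calls <- NULL; simulants <- NULL
  if ("simulate" %in% cfg$stages) {
    say("simulating %d fusions + %d simulants ...", cfg$n_fusions,
        cfg$n_simulants)
    sim <- simulate_fusions(ref, scfg, cfg$n_fusions)
    amps <- render_amplicons(sim$truth, sim$ref)
    reads <- with_seed(derive_seed(scfg$seed, "reads"),
                       generate_reads(amps, scfg))
    write_fastq_pair(reads, file.path(cfg$out_dir, "fusion_reads"))
    simulants <- generate_simulants(ref, cfg$n_simulants, scfg,
                                    with_reads = FALSE)
    utils::write.table(sim$truth, file.path(cfg$out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$n_truth <- nrow(sim$truth)
    summary$n_simulants <- nrow(simulants$truth)
  }

  if ("call" %in% cfg$stages) {
    if (is.null(sim)) stop("call stage needs the simulate stage")
    say("calling fusions from reads ...")
    reads <- read_fastq_pair(
      file.path(cfg$out_dir, "fusion_reads_R1.fastq"),
      file.path(cfg$out_dir, "fusion_reads_R2.fastq"))
    calls <- do.call(call_fusions,
                     c(list(reads = reads, ref = sim$ref), cfg$call))
    write_calls(calls, file.path(cfg$out_dir, "calls.tsv"), "TSV")
    write_calls(calls, file.path(cfg$out_dir, "calls.bed"), "BED")
    base <- calls[calls$resolution == "base", , drop = FALSE]
    summary$n_reads <- attr(calls, "n_reads")
    summary$n_events <- nrow(base)
    summary$recovery_pct <- 100 * recovery_rate(base, sim$truth, sim$ref)
    summary$mean_mh <- mean(base$mh_bp)
    summary$class_proportions <- as.list(prop.table(table(base$category)))
  }

  if ("enrich" %in% cfg$stages) {
    if (is.null(calls)) stop("enrich stage needs the call stage")
    say("enrichment statistics ...")
    base <- calls[calls$resolution == "base", , drop = FALSE]
    ce <- chrom_enrichment(base, sizes)
    utils::write.table(ce, file.path(cfg$out_dir, "chrom_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    genes <- ref$annotation$genes
    gene_frac <- track_fraction(genes, sizes)
    fc <- feature_coincidence(base, genes, ref, control = gene_frac)
    fcs <- feature_coincidence(base, genes, ref,
                               control = simulants$truth)
    ld <- ltr_depletion(base, simulants$truth, ref, scope = "subtelomere")
    fg <- fused_gene_stats(base, genes, ref, simulants = simulants$truth)
    enr <- rbind(cbind(analysis = "gene_vs_fraction", fc),
                 cbind(analysis = "gene_vs_simulant", fcs),
                 cbind(analysis = "ltr_subtel_vs_simulant", ld))
    utils::write.table(enr, file.path(cfg$out_dir, "feature_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$gene_coincidence_prop <- fc$observed_prop
    summary$gene_fraction <- gene_frac
    summary$ltr_direction <- ld$direction
    summary$fused_gene_mean_len <- fg$mean
    summary$fused_gene_vs_all_z <- if (!is.null(fg$vs_all)) fg$vs_all$z else
      NA_real_
  }

  if ("cna" %in% cfg$stages) {
    say("single-nucleus CNA ...")
    truth_seg <- default_cna_truth(ref, cfg$n_nuclei)
    prof <- simulate_nuclei_bins(ref, truth_seg, n_nuclei = cfg$n_nuclei,
                                 depth = cfg$bin_depth, n_bins = cfg$n_bins,
                                 seed = derive_seed(cfg$seed, "cna_layer"))
    segs <- call_cna(prof)
    utils::write.table(segs, file.path(cfg$out_dir, "cna_segments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$n_cna_segments <- nrow(segs)
    if (!is.null(calls)) {
      base <- calls[calls$resolution == "base", , drop = FALSE]
      ix <- intersect_cna_fusions(segs, base, simulants$truth, ref)
      summary$cna_fusion_overlap <- ix$overlap
      summary$cna_fusion_p <- ix$p_value
      summary$cna_tally <- as.list(ix$tally)
    }
  }

  if ("expr" %in% cfg$stages) {
    say("expression linkage ...")
    em <- simulate_counts(ref, reps = cfg$reps, cfg = scfg)
    sf <- size_factors(em$counts)
    utils::write.table(round(sf$normalized, 3),
                       file.path(cfg$out_dir, "normalized_counts.tsv"),
                       sep = "\t", quote = FALSE)
    fcs <- stage_fold_changes(em)
    utils::write.table(fcs$table, file.path(cfg$out_dir, "fold_changes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$size_factor_range <- range(sf$factors)
    if (!is.null(calls)) {
      base <- calls[calls$resolution == "base", , drop = FALSE]
      link <- tryCatch(
        fused_expression_link(base, em, stage = base$stage[1]),
        error = function(e) NULL)
      if (!is.null(link)) {
        summary$fused_frac_expressed <- link$frac_expressed
        summary$fused_expression_fold <- link$fold
      }
    }
  }

  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: %s", cfg$out_dir)
  invisible(summary)
}

# a small default CNA truth: one gain and one loss per alternating nucleus
default_cna_truth <- function(ref, n_nuclei) {
  sizes <- chrom_sizes(ref)
  chroms <- names(sizes)
  out <- list()
  for (nu in seq_len(n_nuclei)) {
    if (nu %% 2L == 1L) {
      ch <- chroms[1 + (nu %% length(chroms))]
      L <- sizes[[ch]]
      out[[length(out) + 1L]] <- data.frame(
        nucleus = nu, chrom = ch, start = as.integer(L * 0.2),
        end = as.integer(L * 0.35), ratio = 1.25)
      out[[length(out) + 1L]] <- data.frame(
        nucleus = nu, chrom = ch, start = as.integer(L * 0.6),
        end = as.integer(L * 0.75), ratio = 0.75)
    }
  }
  do.call(rbind, out)
}

#' Fraction of truth events recovered by a call set
#'
#' A truth event counts as recovered when a base-resolution call of the
#' same category involves the same fused ends/partner reference with both
#' junction coordinates within `tol` bp (up to the canonical orientation
#' of intra/inter events).
#'
#' @param calls base-resolution `fusion_calls`.
#' @param truth a truth table from [simulate_fusions()].
#' @param ref the matching reference.
#' @param tol coordinate tolerance in bp.
#' @return fraction in [0, 1].
#' @export
recovery_rate <- function(calls, truth, ref, tol = 5L) {
  if (nrow(truth) == 0) return(NA_real_)
  tr <- canonical_truth(truth, ref)
  hit <- logical(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    cand <- calls$category == tr$category[i] &
      calls$end_a == tr$end_a[i] & calls$chrom_b == tr$chrom_b[i] &
      !is.na(calls$bp_a) & !is.na(calls$bp_b)
    if (!any(cand)) next
    hit[i] <- any(abs(calls$bp_a[cand] - tr$bp_a[i]) <= tol &
                    abs(calls$bp_b[cand] - tr$bp_b[i]) <= tol)
  }
  mean(hit)
}

# put truth into the same canonical orientation as calls
canonical_truth <- function(truth, ref) {
  canonicalize_calls(truth, ref)
}
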