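#' Simulate a stage-labelled gene expression count matrix
#'
#' Negative-binomial counts for the genes of the synthetic reference across
#' crisis stages (Early, Deep, Late) with `reps` samples per stage.
#' Per-gene base means are log-normal around 100; per-stage fold changes
#' are programmed through `stage_effects`; library sizes vary by a uniform
#' factor in [0.5, 2].
#'
#' @param ref a `synthetic_reference` (genes come from its annotation).
#' @param stage_effects named list (`Early`/`Deep`/`Late`) of named numeric
#'   vectors `gene_id -> fold` (> 0); unknown gene ids are an error.
#' @param reps samples per stage (>= 1).
#' @param cfg a [sim_config()] (`nb_size`, `seed`).
#' @param base_meanlog,base_sdlog log-normal base-mean parameters.
#' @return an `expression_matrix` list: `counts` (genes x samples integer
#'   matrix), `genes` (`GRanges` with `gene_id`), `samples` (data frame:
#'   sample, line, stage), `base_mean`, `true_fold` (genes x stages).
#' @export
simulate_counts <- function(ref, stage_effects = list(), reps = 3L,
                            cfg = sim_config(),
                            base_meanlog = log(100), base_sdlog = 0.5) {
  if (reps < 1L) stop("reps must be >= 1")
  genes <- ref$annotation$genes
  if (length(genes) == 0) stop("reference has no gene annotation")
  gid <- genes$gene_id
  stages <- c("Early", "Deep", "Late")
  for (s in names(stage_effects)) {
    if (!(s %in% stages)) stop("unknown stage in stage_effects: ", s)
    unk <- setdiff(names(stage_effects[[s]]), gid)
    if (length(unk) > 0)
      stop("unknown gene id in stage_effects: ", unk[1])
    if (any(stage_effects[[s]] <= 0)) stop("folds must be > 0")
  }
  with_seed(derive_seed(cfg$seed, "counts"), {
    base_mean <- stats::rlnorm(length(gid), base_meanlog, base_sdlog)
    names(base_mean) <- gid
    fold <- matrix(1, nrow = length(gid), ncol = length(stages),
                   dimnames = list(gid, stages))
    for (s in names(stage_effects)) {
      fold[names(stage_effects[[s]]), s] <- stage_effects[[s]]
    }
    samples <- data.frame(
      sample = paste0(rep(stages, each = reps), "_", seq_len(reps)),
      line = paste0("L", seq_len(reps)),
      stage = rep(stages, each = reps), stringsAsFactors = FALSE)
    libf <- stats::runif(nrow(samples), 0.5, 2)
    counts <- matrix(0L, nrow = length(gid), ncol = nrow(samples),
                     dimnames = list(gid, samples$sample))
    for (j in seq_len(nrow(samples))) {
      mu <- base_mean * fold[, samples$stage[j]] * libf[j]
      counts[, j] <- stats::rnbinom(length(gid), mu = mu, size = cfg$nb_size)
    }
    structure(list(counts = counts, genes = genes, samples = samples,
                   base_mean = base_mean, true_fold = fold,
                   lib_factor = libf),
              class = "expression_matrix")
  })
}
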