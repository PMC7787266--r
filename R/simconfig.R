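#' Simulation configuration for the synthetic crisis data layers
#'
#' Parameterises the three synthetic data layers: fusion amplicons from the
#' three primer-targeted chromosome ends (17p, the 21q homologous family and
#' XpYp), 4N-nucleus bin counts against a pooled-nuclei baseline, and
#' stage-structured expression count matrices. All sizes are in bp on a
#' scaled-down minigenome.
#'
#' @param seed master integer seed; every stream is derived from it.
#' @param n_chroms,chrom_lengths minigenome shape (defaults: 4 x 500 kb).
#' @param subtel_length length of each subtelomere reference.
#' @param primer_offset 0-based offset of the fusion primer 3' end within
#'   each subtelomere; breakpoints land strictly beyond it.
#' @param telomere_boundary 0-based position where telomere repeats begin;
#'   breakpoints land at or before it, and subtelomeric deletion is measured
#'   back from it.
#' @param class_mix probabilities of (genomic, intra, inter) fusion classes.
#' @param mh_mean mean of the (truncated) geometric microhomology law.
#' @param mh_max truncation cap on injected microhomology (keeps exact-MH
#'   flank windows small).
#' @param ins_prob probability a junction carries an insertion (which then
#'   forces MH = 0: insertions and MH are mutually exclusive per junction).
#' @param ins_len_range inclusive bp range of insertion lengths.
#' @param ins_templated_prob probability an insertion is copied from within
#'   +/- `ins_window` of a breakpoint flank.
#' @param ins_window templating search window, bp.
#' @param deletion_range bp range of subtelomeric deletion per fused end
#'   (breakpoint = telomere_boundary - deletion).
#' @param partner_len_range genomic-partner amplicon segment length range.
#' @param read_len,frag_mean,frag_sd paired-end read model (250PE reads off
#'   ~450 bp fragments, so mates overlap the junction).
#' @param error_rate per-base substitution probability.
#' @param coverage mean fragment depth per amplicon: a fusion amplicon of
#'   length L yields `round(coverage * L / frag_mean)` read pairs.
#' @param family_divergence per-base divergence of non-archetype 21q family
#'   members from the archetype.
#' @param ltr_avoid probability that a biological breakpoint falling in a
#'   subtelomere LTR interval is redrawn (0 = uniform, no avoidance).
#' @param feature_density named per-kb densities for the annotation tracks.
#' @param gene_meanlog,gene_sdlog log-normal gene-length parameters.
#' @param nb_size negative-binomial size (inverse dispersion) of simulated
#'   expression counts.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 4L,
                       chrom_lengths = rep(500000L, n_chroms),
                       subtel_length = 8000L,
                       primer_offset = 200L,
                       telomere_boundary = 7200L,
                       class_mix = c(genomic = 0.4, intra = 0.4, inter = 0.2),
                       mh_mean = 2,
                       mh_max = 12L,
                       ins_prob = 0.3,
                       ins_len_range = c(1L, 15L),
                       ins_templated_prob = 0.5,
                       ins_window = 100L,
                       deletion_range = c(0L, 6000L),
                       partner_len_range = c(500L, 3000L),
                       read_len = 250L,
                       frag_mean = 450L,
                       frag_sd = 40L,
                       error_rate = 0,
                       coverage = 10,
                       family_divergence = 0.08,
                       ltr_avoid = 0,
                       feature_density = c(gene = 1.0, exon = 2.0,
                                           promoter = 1.0, enhancer = 0.5,
                                           fragile = 0.02, ltr = 0.3),
                       gene_meanlog = log(350),
                       gene_sdlog = 0.8,
                       nb_size = 200) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_lengths = as.integer(chrom_lengths),
              subtel_length = as.integer(subtel_length),
              primer_offset = as.integer(primer_offset),
              telomere_boundary = as.integer(telomere_boundary),
              class_mix = class_mix, mh_mean = mh_mean,
              mh_max = as.integer(mh_max),
              ins_prob = ins_prob, ins_len_range = as.integer(ins_len_range),
              ins_templated_prob = ins_templated_prob,
              ins_window = as.integer(ins_window),
              deletion_range = as.integer(deletion_range),
              partner_len_range = as.integer(partner_len_range),
              read_len = as.integer(read_len), frag_mean = frag_mean,
              frag_sd = frag_sd, error_rate = error_rate, coverage = coverage,
              family_divergence = family_divergence, ltr_avoid = ltr_avoid,
              feature_density = feature_density,
              gene_meanlog = gene_meanlog, gene_sdlog = gene_sdlog,
              nb_size = nb_size)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid sim_config field '%s': %s", field, msg),
         call. = FALSE)
  }
  probs <- c(ins_prob = cfg$ins_prob,
             ins_templated_prob = cfg$ins_templated_prob,
             error_rate = cfg$error_rate, ltr_avoid = cfg$ltr_avoid)
  for (p in names(probs)) {
    if (!is.numeric(probs[[p]]) || probs[[p]] < 0 || probs[[p]] > 1)
      fail(p, "must be a probability in [0, 1]")
  }
  if (length(cfg$class_mix) != 3L || any(cfg$class_mix < 0))
    fail("class_mix", "needs 3 non-negative entries (genomic, intra, inter)")
  if (abs(sum(cfg$class_mix) - 1) > 1e-9)
    fail("class_mix", "must sum to 1")
  if (length(cfg$chrom_lengths) != cfg$n_chroms)
    fail("chrom_lengths", "length must equal n_chroms")
  if (any(cfg$chrom_lengths <= 0)) fail("chrom_lengths", "must be positive")
  if (!(cfg$primer_offset < cfg$telomere_boundary))
    fail("primer_offset", "must be < telomere_boundary")
  if (!(cfg$telomere_boundary <= cfg$subtel_length))
    fail("telomere_boundary", "must be <= subtel_length")
  if (cfg$read_len > cfg$frag_mean)
    fail("read_len", "must be <= frag_mean")
  if (cfg$mh_mean < 0) fail("mh_mean", "must be >= 0")
  if (diff(cfg$ins_len_range) < 0 || cfg$ins_len_range[1] < 1L)
    fail("ins_len_range", "must be an increasing range with min >= 1")
  if (diff(cfg$deletion_range) < 0 || cfg$deletion_range[1] < 0L)
    fail("deletion_range", "must be a non-negative increasing range")
  if (cfg$deletion_range[2] > cfg$telomere_boundary - cfg$primer_offset)
    fail("deletion_range",
         "max deletion exceeds telomere_boundary - primer_offset")
  if (cfg$coverage <= 0) fail("coverage", "must be positive")
  invisible(cfg)
}
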