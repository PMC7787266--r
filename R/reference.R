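#' Build a synthetic minigenome with primer-targeted subtelomere references
#'
#' Generates a scaled-down genome plus subtelomere references for the three
#' primer-targeted chromosome ends used by fusion amplicon sequencing: 17p,
#' XpYp and the 21q homologous family (an archetype `21q1` plus a diverged,
#' non-targeted sibling `21q2` that models the cross-mapping ambiguity of the
#' 21q family). Each subtelomere carries its primer offset, the telomere-
#' repeat boundary, and one embedded LTR-like interval midway between primer
#' and telomere. Annotation tracks (genes with log-normal lengths, exons,
#' promoters, enhancers, fragile sites and genome-wide LTR repeats) are laid
#' down at the densities in `cfg$feature_density`.
#'
#' @param cfg a [sim_config()].
#' @return a `synthetic_reference` list with elements `minigenome` (named
#'   character vector of chromosome sequences), `subtelomeres` (data frame:
#'   end_id, family_id, archetype, targeted, primer_offset,
#'   telomere_boundary, ltr_start, ltr_end), `subtel_seqs` (named character
#'   vector), `annotation` (named list of `GRanges` tracks) and `seed`.
#' @export
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
build_reference <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(derive_seed(cfg$seed, "reference"), {
    chroms <- paste0("chr", seq_len(cfg$n_chroms))
    minigenome <- vapply(cfg$chrom_lengths, random_dna, character(1))
    names(minigenome) <- chroms

    ends <- data.frame(
      end_id = c("17p", "21q1", "21q2", "XpYp"),
      family_id = c("17p", "21q", "21q", "XpYp"),
      archetype = c(TRUE, TRUE, FALSE, TRUE),
      targeted = c(TRUE, TRUE, FALSE, TRUE),
      stringsAsFactors = FALSE
    )
    ends$primer_offset <- cfg$primer_offset
    ends$telomere_boundary <- cfg$telomere_boundary
    zone <- cfg$telomere_boundary - cfg$primer_offset
    # one LTR-like interval per end, midway between primer and telomere
    ends$ltr_start <- as.integer(cfg$primer_offset + round(0.45 * zone))
    ends$ltr_end <- as.integer(cfg$primer_offset + round(0.575 * zone))

    seqs <- character(nrow(ends))
    names(seqs) <- ends$end_id
    for (i in seq_len(nrow(ends))) {
      if (ends$end_id[i] == "21q2") next
      seqs[i] <- random_dna(cfg$subtel_length)
    }
    # diverged 21q sibling: archetype mutated at family_divergence per base
    arch <- strsplit(seqs[["21q1"]], "", fixed = TRUE)[[1]]
    mut <- which(stats::runif(length(arch)) < cfg$family_divergence)
    arch[mut] <- other_base(arch[mut])
    seqs[["21q2"]] <- paste(arch, collapse = "")

    annotation <- build_annotation(cfg, chroms)

    ref <- list(minigenome = minigenome, subtelomeres = ends,
                subtel_seqs = seqs, annotation = annotation,
                seed = cfg$seed)
    class(ref) <- "synthetic_reference"
    ref
  })
}

build_annotation <- function(cfg, chroms) {
  dens <- cfg$feature_density
  lens <- cfg$chrom_lengths
  genome_kb <- sum(lens) / 1000

  place_nonoverlapping <- function(chrom, L, widths) {
    n <- length(widths)
    if (n == 0L) return(NULL)
    total <- sum(widths)
    while (total > 0.85 * L) { # keep packing feasible
      widths <- pmax(50L, as.integer(widths * 0.8))
      total <- sum(widths)
    }
    slack <- L - total
    gaps <- stats::rexp(n + 1L)
    gaps <- floor(gaps / sum(gaps) * slack)
    starts <- cumsum(c(gaps[seq_len(n)])) + cumsum(c(0L, widths[-n])) + 1L
    data.frame(chrom = chrom, start = as.integer(starts),
               end = as.integer(starts + widths - 1L))
  }

  gene_df <- NULL
  for (i in seq_along(chroms)) {
    n_g <- round(dens[["gene"]] * lens[i] / 1000)
    if (n_g == 0) next
    w <- as.integer(pmax(100, round(stats::rlnorm(n_g, cfg$gene_meanlog,
                                                  cfg$gene_sdlog))))
    gene_df <- rbind(gene_df, place_nonoverlapping(chroms[i], lens[i], w))
  }
  genes <- df_to_granges(gene_df)
  if (!is.null(gene_df) && length(genes) > 0) {
    genes$gene_id <- sprintf("G%05d", seq_along(genes))
  }

  # exons: sub-intervals of genes, ~dens[exon]/dens[gene] per gene
  exons <- GenomicRanges::GRanges()
  if (length(genes) > 0 && dens[["exon"]] > 0) {
    per_gene <- max(1L, round(dens[["exon"]] / max(dens[["gene"]], 1e-9)))
    ex <- lapply(seq_along(genes), function(i) {
      g <- genes[i]
      w <- GenomicRanges::width(g)
      k <- min(per_gene, max(1L, w %/% 120L))
      es <- sort(sample.int(max(w - 60L, 1L), k))
      IRanges::IRanges(start = GenomicRanges::start(g) + es - 1L,
                       width = pmin(60L, w - es + 1L))
    })
    exons <- GenomicRanges::GRanges(
      rep(as.character(GenomicRanges::seqnames(genes)),
          vapply(ex, length, integer(1))),
      do.call(c, ex))
  }

  # promoters: 150 bp immediately upstream of a random subset of genes
  promoters <- GenomicRanges::GRanges()
  if (length(genes) > 0 && dens[["promoter"]] > 0) {
    n_p <- min(length(genes), round(dens[["promoter"]] * genome_kb))
    idx <- sort(sample.int(length(genes), n_p))
    g <- genes[idx]
    st <- pmax(1L, GenomicRanges::start(g) - 150L)
    promoters <- GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(g)),
      IRanges::IRanges(start = st, end = pmax(st, GenomicRanges::start(g) - 1L)))
  }

  rand_track <- function(name, width) {
    n <- round(dens[[name]] * genome_kb)
    if (n == 0) return(GenomicRanges::GRanges())
    chrom_i <- sample.int(length(chroms), n, replace = TRUE,
                          prob = lens / sum(lens))
    st <- vapply(chrom_i, function(ci) {
      sample.int(max(lens[ci] - width, 1L), 1L)
    }, integer(1))
    GenomicRanges::GRanges(chroms[chrom_i],
                           IRanges::IRanges(start = st, width = width))
  }

  list(genes = genes, exons = exons, promoters = promoters,
       enhancers = rand_track("enhancer", 200L),
       fragile = rand_track("fragile", 5000L),
       ltr = rand_track("ltr", 300L))
}

df_to_granges <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start, end = df$end))
}

#' Chromosome sizes of a synthetic reference
#' @param ref a `synthetic_reference`.
#' @return named integer vector of minigenome chromosome lengths.
#' @export
chrom_sizes <- function(ref) {
  vapply(ref$minigenome, nchar, integer(1))
}

#' Fraction of the genome covered by a feature track
#' @param track a `GRanges` track.
#' @param sizes named chromosome sizes (see [chrom_sizes()]).
#' @return scalar in [0, 1].
#' @export
track_fraction <- function(track, sizes) {
  if (length(track) == 0) return(0)
  red <- GenomicRanges::reduce(track)
  sum(as.numeric(GenomicRanges::width(red))) / sum(as.numeric(sizes))
}

subtel_zone <- function(ref, end_id) {
  s <- ref$subtelomeres[ref$subtelomeres$end_id == end_id, ]
  if (nrow(s) != 1L) stop("unknown subtelomere end: ", end_id)
  s
}

targeted_ends <- function(ref) {
  ref$subtelomeres$end_id[ref$subtelomeres$targeted]
}
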