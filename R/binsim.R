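#' Simulate single-nucleus bin counts with segmental copy-number changes
#'
#' Emulates 4N single-nucleus whole-genome sequencing binned into equal
#' windows, with a pooled-nuclei bulk baseline. Per-bin counts are Poisson
#' around `depth * copy_ratio`; neutral bins have ratio 1, and truth
#' segments impose their ratio (gain 5/4 and loss 3/4 by default — one
#' chromatid gained or lost on a 4N background). The bulk is the aggregate
#' of `bulk_pool` neutral nuclei.
#'
#' @param ref a `synthetic_reference` (bins tile its minigenome).
#' @param truth_segments data frame (may be empty) with columns `nucleus`
#'   (integer index), `chrom`, `start`, `end` (bp, 0-based half-open) and
#'   `ratio` (copy ratio, e.g. 1.25 or 0.75).
#' @param n_nuclei number of single nuclei.
#' @param depth mean neutral count per bin per nucleus (> 0).
#' @param n_bins total bins tiling the genome.
#' @param bulk_pool nuclei pooled into the bulk baseline.
#' @param seed integer seed.
#' @return a `bin_profile` list: `bins` (data frame chrom/start/end),
#'   `counts` (n_nuclei x n_bins matrix), `bulk` (length n_bins vector),
#'   `truth` (the truth segments with bin indices attached).
#' @export
simulate_nuclei_bins <- function(ref, truth_segments = NULL, n_nuclei = 23L,
                                 depth = 500, n_bins = 2000L,
                                 bulk_pool = 500L, seed = 1L) {
  if (depth <= 0) stop("depth must be > 0")
  if (n_bins < 1L) stop("empty bin set")
  sizes <- chrom_sizes(ref)
  bw <- ceiling(sum(sizes) / n_bins)
  bins <- do.call(rbind, lapply(names(sizes), function(ch) {
    st <- seq(0L, sizes[[ch]] - 1L, by = bw)
    data.frame(chrom = ch, start = st,
               end = pmin(st + bw, sizes[[ch]]),
               stringsAsFactors = FALSE)
  }))
  nb <- nrow(bins)
  with_seed(derive_seed(seed, "nuclei_bins"), {
    ratio <- matrix(1, nrow = n_nuclei, ncol = nb)
    if (!is.null(truth_segments) && nrow(truth_segments) > 0) {
      for (i in seq_len(nrow(truth_segments))) {
        tr <- truth_segments[i, ]
        sel <- bins$chrom == tr$chrom & bins$start < tr$end &
          bins$end > tr$start
        ratio[tr$nucleus, sel] <- tr$ratio
      }
    }
    counts <- matrix(stats::rpois(n_nuclei * nb, depth * ratio),
                     nrow = n_nuclei)
    rownames(counts) <- sprintf("nucleus%02d", seq_len(n_nuclei))
    bulk <- stats::rpois(nb, depth * bulk_pool)
    structure(list(bins = bins, counts = counts, bulk = bulk,
                   truth = truth_segments),
              class = "bin_profile")
  })
}
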