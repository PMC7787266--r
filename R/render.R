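#' Render the amplicon sequence of one fusion event
#'
#' A fusion amplicon runs from the subtelomere primer to the breakpoint,
#' through any junction insertion, into the partner segment: genomic
#' partners contribute a segment of length `len_b` in their recorded
#' orientation; intra- and inter-chromosomal partners contribute the
#' reverse-complemented sister subtelomere from its own primer to its
#' breakpoint (the fused ends form a head-to-head palindrome, which is what
#' lets a single-end primer pair amplify the junction).
#'
#' @param f one truth record (one-row data frame or list) as produced by
#'   [simulate_fusions()].
#' @param ref the (patched) reference the truth was generated against.
#' @return the amplicon DNA string.
#' @export
render_amplicon <- function(f, ref) {
  st <- subtel_zone(ref, f$end_a)
  if (f$bp_a <= st$primer_offset || f$bp_a > st$telomere_boundary)
    stop("breakpoint outside (primer_offset, telomere_boundary]")
  seq_a <- ref_sequence(ref, f$end_a)
  a_part <- substr(seq_a, st$primer_offset + 1L, f$bp_a)
  seq_b <- ref_sequence(ref, f$chrom_b)
  if (f$strand_b == "+") {
    b_part <- substr(seq_b, f$bp_b + 1L, f$bp_b + f$len_b)
  } else {
    b_part <- revcomp(substr(seq_b, f$bp_b - f$len_b + 1L, f$bp_b))
  }
  ins <- if (is.na(f$ins_seq)) "" else f$ins_seq
  paste0(a_part, ins, b_part)
}

render_amplicons <- function(truth, ref) {
  if (nrow(truth) == 0) return(character(0))
  amps <- vapply(seq_len(nrow(truth)), function(i) {
    render_amplicon(truth[i, ], ref)
  }, character(1))
  names(amps) <- truth$id
  amps
}

# Resolve each truth junction from its rendered amplicon with perfect
# anchors; used to verify that recorded truth matches what the (possibly
# patched) reference realises, and as the reference point for recovery
# tests.
resolve_truth_junctions <- function(truth, ref) {
  res <- lapply(seq_len(nrow(truth)), function(i) {
    f <- truth[i, ]
    st <- subtel_zone(ref, f$end_a)
    amp <- render_amplicon(f, ref)
    b_last0 <- if (f$strand_b == "+") f$bp_b + f$len_b - 1L else
      f$bp_b - f$len_b
    sa <- list(read = amp, a_end = f$end_a, a_pos0 = st$primer_offset,
               b_ref = f$chrom_b, b_strand = f$strand_b, b_last0 = b_last0)
    r <- resolve_junction(sa, ref)
    data.frame(id = f$id, bp_a = r$bp_a, bp_b = r$bp_b, mh_bp = r$mh_bp,
               ins_seq = r$ins_seq, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
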