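#' Resolve a fusion junction to breakpoints, microhomology and insertion
#'
#' Given a split alignment whose A segment is anchored in a subtelomere and
#' whose B segment is anchored at the partner locus, enumerates (in closed
#' form) every perfect placement of the junction-spanning sequence against
#' both references. The microhomology `mh_bp` is the width of the valid
#' placement window (max valid split minus min valid split); if no perfect
#' placement exists the maximal read segment matching neither flank is
#' returned as the insertion and `mh_bp = 0`. Breakpoints are reported at the
#' leftmost valid placement, 0-based half-open.
#'
#' The closed form uses the maximal exact extension `a` of the read along
#' the A reference and the maximal exact backward extension `s` along the B
#' reference: valid read split positions are exactly `[n - s, a]`, so
#' `mh = a + s - n` when `a + s >= n`, else the middle `read[(a+1)..(n-s)]`
#' is the insertion. Equivalence with brute-force split enumeration is a
#' tested invariant.
#'
#' @param sa a split alignment as returned by [split_align()]: a list with
#'   `read` (sequence), `a_end` (subtelomere end id), `a_pos0` (0-based
#'   position where read base 1 maps), `b_ref` (partner sequence name),
#'   `b_strand` ("+" or "-") and `b_last0` (0-based position on `b_ref`
#'   where the last read base maps).
#' @param refs a `synthetic_reference` (or any list with `subtel_seqs` and
#'   `minigenome`).
#' @return list with `bp_a`, `bp_b` (0-based junction coordinates at the
#'   leftmost placement; for a "-" partner `bp_b` is the half-open end of
#'   the reverse-complemented segment), `mh_bp`, `ins_seq` and `n_placements`.
#' @export
resolve_junction <- function(sa, refs) {
  read <- sa$read
  n <- nchar(read)
  ref_a <- ref_sequence(refs, sa$a_end)
  ref_b <- ref_sequence(refs, sa$b_ref)
  a <- lcp_len(read, 1L, ref_a, sa$a_pos0 + 1L)
  if (sa$b_strand == "+") {
    s <- lcs_len(read, n, ref_b, sa$b_last0 + 1L)
  } else {
    s <- lcp_len(revcomp(read), 1L, ref_b, sa$b_last0 + 1L)
  }
  if (a + s >= n) { # perfect placements exist; window width = mh
    mh <- a + s - n
    i_min <- n - s
    bp_a <- sa$a_pos0 + i_min
    ins <- ""
    n_place <- mh + 1L
  } else {
    mh <- 0L
    i_min <- a
    bp_a <- sa$a_pos0 + a
    ins <- substr(read, a + 1L, n - s)
    n_place <- 0L
  }
  bp_b <- if (sa$b_strand == "+") sa$b_last0 - s + 1L else sa$b_last0 + s
  list(bp_a = as.integer(bp_a), bp_b = as.integer(bp_b),
       mh_bp = as.integer(mh), ins_seq = ins,
       n_placements = as.integer(n_place))
}

# look up any reference sequence (subtelomere end id or minigenome chrom)
ref_sequence <- function(refs, name) {
  if (!is.null(refs$subtel_seqs) && name %in% names(refs$subtel_seqs))
    return(refs$subtel_seqs[[name]])
  if (!is.null(refs$minigenome) && name %in% names(refs$minigenome))
    return(refs$minigenome[[name]])
  stop("unknown reference sequence: ", name)
}

#' Classify a junction insertion as templated or untemplated
#'
#' An insertion is templated when its sequence (or, by default, its reverse
#' complement) occurs verbatim within +/- `window` bp of either breakpoint
#' in the corresponding reference flank; an empty insertion returns `NA`.
#'
#' @param ins_seq insertion sequence (may be "").
#' @param ref_a,ref_b flank reference sequences (full sequences).
#' @param bp_a,bp_b 0-based junction coordinates on each reference.
#' @param window search window in bp (default 100).
#' @param search_rc also search the reverse complement of the insertion.
#' @return one of "templated", "untemplated" or `NA_character_`.
#' @export
classify_insertion <- function(ins_seq, ref_a, ref_b, bp_a, bp_b,
                               window = 100L, search_rc = TRUE) {
  if (is.na(ins_seq) || nchar(ins_seq) == 0L) return(NA_character_)
  flank <- function(ref, bp) {
    lo <- max(1L, bp - window + 1L)
    hi <- min(nchar(ref), bp + window)
    substr(ref, lo, hi)
  }
  flanks <- c(flank(ref_a, bp_a), flank(ref_b, bp_b))
  pats <- ins_seq
  if (search_rc) pats <- c(pats, revcomp(ins_seq))
  hit <- any(vapply(pats, function(p) {
    any(grepl(p, flanks, fixed = TRUE))
  }, logical(1)))
  if (hit) "templated" else "untemplated"
}

#' Classify a resolved fusion by partner locus
#'
#' Partner in the same end's subtelomere gives an intra-chromosomal (sister
#' chromatid) fusion, a different subtelomere gives inter-chromosomal, and
#' anything else genomic. For partners mapping into a multi-member
#' subtelomere family (the 21q homologues), intra status is assigned only
#' when sequence identity to the family archetype exceeds identity to every
#' other member by at least `family_margin`, computed over a window of the
#' mapped member against each member's aligned positions; otherwise the
#' conservative inter assignment is made.
#'
#' @param sa split alignment (see [resolve_junction()]) with `a_end`,
#'   `b_ref`, `b_strand`.
#' @param bp_b 0-based partner junction coordinate.
#' @param refs a `synthetic_reference`.
#' @param family_margin identity margin required for intra within a family
#'   (default 0.02).
#' @param ident_window bp of partner-side reference used for the family
#'   identity comparison.
#' @return one of "genomic", "intra", "inter".
#' @export
classify_fusion <- function(sa, bp_b, refs, family_margin = 0.02,
                            ident_window = 300L) {
  subtels <- refs$subtelomeres
  if (!(sa$b_ref %in% subtels$end_id)) return("genomic")
  fam_b <- subtels$family_id[subtels$end_id == sa$b_ref]
  fam_a <- subtels$family_id[subtels$end_id == sa$a_end]
  members <- subtels$end_id[subtels$family_id == fam_b]
  mapped <- sa$b_ref
  if (length(members) > 1L && fam_a == fam_b) {
    # family identity check: compare the mapped member's junction-proximal
    # window against each member at the same (homologously aligned) offsets
    win_lo <- max(1L, bp_b - ident_window %/% 2L)
    win_hi <- min(nchar(ref_sequence(refs, mapped)), win_lo + ident_window - 1L)
    probe <- substr(ref_sequence(refs, mapped), win_lo, win_hi)
    ident <- vapply(members, function(m) {
      seq_m <- ref_sequence(refs, m)
      hi <- min(nchar(seq_m), win_hi)
      seg <- substr(seq_m, win_lo, hi)
      w <- min(nchar(seg), nchar(probe))
      if (w < 50L) return(0)
      mean(strsplit(substr(probe, 1, w), "")[[1]] ==
             strsplit(substr(seg, 1, w), "")[[1]])
    }, numeric(1))
    arche <- subtels$end_id[subtels$family_id == fam_b & subtels$archetype]
    best_other <- max(ident[setdiff(members, arche)])
    if (ident[[arche]] - best_other >= family_margin) {
      mapped <- arche
    } else {
      return("inter")
    }
  }
  if (identical(mapped, sa$a_end)) "intra" else "inter"
}
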