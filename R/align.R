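#' @import data.table
NULL

# Exact k-mer position index over every reference sequence (plus strand).
# Positions are 0-based starts.
kmer_index <- function(ref, k = 21L) {
  seqs <- c(as.list(ref$subtel_seqs), as.list(ref$minigenome))
  dts <- lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    n <- nchar(s) - k + 1L
    if (n < 1L) return(NULL)
    data.table::data.table(kmer = substring(s, 1:n, k:(n + k - 1L)),
                           ref = nm, pos0 = 0:(n - 1L))
  })
  idx <- data.table::rbindlist(dts)
  data.table::setkey(idx, kmer)
  idx
}

# look up a vector of k-mers; returns data.table(qid, ref, pos0)
kmer_lookup <- function(idx, kmers, qid) {
  q <- data.table::data.table(kmer = kmers, qid = qid)
  hit <- idx[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  hit[, list(qid, ref, pos0)]
}

#' Split-align amplicon reads against subtelomere and genome references
#'
#' A seed-and-extend split aligner built for fusion amplicon reads: exact
#' k-mer seeds anchor the read prefix inside a primer-targeted subtelomere
#' (on the plus strand, downstream of the primer) and the read suffix at the
#' partner locus on either strand; ungapped extension with at most
#' `max_mismatch` substitutions per segment establishes that the read spans
#' a junction. Reads that map end-to-end to a single reference produce no
#' split alignment. Both read orientations are tried; the orientation and
#' anchor pair explaining the most read bases wins, and a read whose
#' partner anchor ties across two or more unrelated references is flagged
#' unclassifiable and excluded (counted in the `n_ambiguous` attribute).
#'
#' @param reads named character vector of read sequences (or a list with
#'   `r1`/`r2`, which is concatenated with mate suffixes).
#' @param ref a `synthetic_reference` (patched, when calling simulated data).
#' @param k seed length (>= 11).
#' @param max_mismatch substitutions tolerated per extended segment.
#' @param max_ins longest junction insertion considered.
#' @param min_seg minimum anchored bases on each side of the junction.
#' @param idx optional precomputed [kmer_index()] (rebuilt otherwise).
#' @return list of split alignments (fields `read_id`, `read`, `a_end`,
#'   `a_pos0`, `b_ref`, `b_strand`, `b_last0`), with attributes
#'   `mapped` (data.table: read_id, ref of end-to-end mapped reads) and
#'   `n_ambiguous`.
#' @export
split_align <- function(reads, ref, k = 21L, max_mismatch = 2L,
                        max_ins = 50L, min_seg = 21L, idx = NULL) {
  if (k < 11L) stop("seed length k must be >= 11")
  if (length(ref$subtel_seqs) == 0) stop("empty reference set")
  if (is.list(reads) && !is.null(reads$r1)) {
    v <- c(reads$r1, reads$r2)
    names(v) <- c(paste0(names(reads$r1), "/1"), paste0(names(reads$r2), "/2"))
    reads <- v
  }
  if (is.null(idx)) idx <- kmer_index(ref, k)
  seqs <- c(as.list(ref$subtel_seqs), as.list(ref$minigenome))
  subtels <- ref$subtelomeres
  targets <- targeted_ends(ref)

  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(unname(reads))))

  # ---- phase 1: drop reads that map end-to-end to one reference ----------
  mapped_ref <- rep(NA_character_, length(reads))
  for (ori in 1:2) {
    sq <- if (ori == 1) unname(reads) else rc
    todo <- which(is.na(mapped_ref))
    if (length(todo) == 0) break
    pre <- substr(sq[todo], 1L, k)
    hit <- kmer_lookup(idx, pre, todo)
    if (nrow(hit) == 0) next
    for (nm in unique(hit$ref)) {
      h <- hit[hit$ref == nm, ]
      s <- seqs[[nm]]
      cand <- substring(s, h$pos0 + 1L, h$pos0 + nchar(sq[h$qid]))
      full <- cand == sq[h$qid]
      ok <- h$qid[full]
      mapped_ref[ok] <- nm
    }
  }
  junction_idx <- which(is.na(mapped_ref))
  mapped <- data.table::data.table(read_id = names(reads)[!is.na(mapped_ref)],
                                   ref = mapped_ref[!is.na(mapped_ref)])

  # ---- phase 2: split-resolve the remaining reads ------------------------
  # seed lookups are batched across all junction reads (one keyed join per
  # offset round) and the hits are then walked per read
  sas <- list()
  n_ambiguous <- 0L
  seed_offsets <- c(0L, 7L, 14L)
  nj <- length(junction_idx)
  if (nj > 0) {
    acands <- vector("list", 2L * nj)
    bcands <- vector("list", 2L * nj)
    rc_cache <- new.env(parent = emptyenv())
    for (ori in 1:2) {
      sqv <- if (ori == 1) unname(reads)[junction_idx] else rc[junction_idx]
      nv <- nchar(sqv)
      slot <- function(j) (j - 1L) * 2L + ori
      # A anchors: prefix seeds in targeted subtelomeres, plus strand
      need <- rep(TRUE, nj)
      for (o in seed_offsets) {
        ids <- which(need & nv >= o + k)
        if (length(ids) == 0) break
        hit <- kmer_lookup(idx, substr(sqv[ids], o + 1L, o + k), ids)
        hit <- hit[hit$ref %in% targets & hit$pos0 >= o, ]
        if (nrow(hit) == 0) next
        hit$a_pos0 <- hit$pos0 - o
        hit <- hit[hit$a_pos0 >=
                     subtels$primer_offset[match(hit$ref, subtels$end_id)], ]
        if (nrow(hit) == 0) next
        hit$o <- o
        for (sp in split(as.data.frame(hit), hit$qid)) {
          j <- sp$qid[1]
          acands[[slot(j)]] <- sp
          need[j] <- FALSE
        }
      }
      # B anchors: suffix seeds, either strand, any reference
      need <- rep(TRUE, nj)
      for (o in seed_offsets) {
        ids <- which(need & nv >= o + k)
        if (length(ids) == 0) break
        kms <- substr(sqv[ids], nv[ids] - o - k + 1L, nv[ids] - o)
        kms_rc <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(kms)))
        hp <- kmer_lookup(idx, kms, ids)
        hm <- kmer_lookup(idx, kms_rc, ids)
        rows <- list()
        if (nrow(hp) > 0)
          rows$p <- data.table::data.table(
            qid = hp$qid, ref = hp$ref, strand = "+",
            b_last0 = hp$pos0 + k - 1L + o, o = o)
        if (nrow(hm) > 0)
          rows$m <- data.table::data.table(
            qid = hm$qid, ref = hm$ref, strand = "-",
            b_last0 = hm$pos0 - o, o = o)
        hit <- data.table::rbindlist(rows)
        if (nrow(hit) == 0) next
        for (sp in split(as.data.frame(hit), hit$qid)) {
          j <- sp$qid[1]
          bcands[[slot(j)]] <- sp
          need[j] <- FALSE
        }
      }
    }

    for (jj in seq_len(nj)) {
      ii <- junction_idx[jj]
      best <- NULL
      for (ori in 1:2) {
        sq <- if (ori == 1) reads[[ii]] else rc[[ii]]
        rcsq <- if (ori == 1) rc[[ii]] else reads[[ii]]
        n <- nchar(sq)
        if (n < 2L * min_seg) next
        a_cand <- acands[[(jj - 1L) * 2L + ori]]
        b_cand <- bcands[[(jj - 1L) * 2L + ori]]
        if (is.null(a_cand) || is.null(b_cand)) next
        for (ai in seq_len(nrow(a_cand))) {
          a_end <- a_cand$ref[ai]
          a_pos0 <- a_cand$a_pos0[ai]
          a_mm <- lcp_mm(sq, 1L, seqs[[a_end]], a_pos0 + 1L, max_mismatch)
          if (a_mm < min_seg) next
          # the exact prefix extension must reach through the anchor seed,
          # otherwise the anchor does not belong to the A segment
          a_ex <- lcp_len(sq, 1L, seqs[[a_end]], a_pos0 + 1L)
          if (a_ex < a_cand$o[ai] + k) next
          for (bi in seq_len(nrow(b_cand))) {
            b_ref <- b_cand$ref[bi]
            b_strand <- b_cand$strand[bi]
            b_last0 <- b_cand$b_last0[bi]
            if (b_strand == "+") {
              if (b_last0 + 1L > nchar(seqs[[b_ref]])) next
              s_mm <- lcs_mm(sq, n, seqs[[b_ref]], b_last0 + 1L,
                             max_mismatch)
              s_ex <- lcs_len(sq, n, seqs[[b_ref]], b_last0 + 1L)
            } else {
              if (b_last0 < 0L) next
              s_mm <- lcp_mm(rcsq, 1L, seqs[[b_ref]], b_last0 + 1L,
                             max_mismatch)
              s_ex <- lcp_len(rcsq, 1L, seqs[[b_ref]], b_last0 + 1L)
            }
            if (s_mm < min_seg) next
            # same consistency requirement for the B anchor: a read that
            # barely crosses a junction must not borrow its partner seed
            # from the A segment
            if (s_ex < b_cand$o[bi] + k) next
            if (a_mm + s_mm < n - max_ins) next
            score <- min(a_mm, n) + min(s_mm, n)
            cand <- list(read_id = names(reads)[ii], read = sq,
                         a_end = a_end, a_pos0 = a_pos0, b_ref = b_ref,
                         b_strand = b_strand, b_last0 = b_last0,
                         score = score)
            if (is.null(best) || score > best$score) {
              best <- cand
              best$tied <- FALSE
            } else if (score == best$score &&
                       same_family(subtels, b_ref, best$b_ref) &&
                       is_archetype(subtels, b_ref) &&
                       !is_archetype(subtels, best$b_ref)) {
              # family tie: resolve to the archetype member
              tied <- best$tied
              best <- cand
              best$tied <- tied
            } else if (score == best$score &&
                       !same_family(subtels, b_ref, best$b_ref) &&
                       !(a_end == best$b_ref && b_ref == best$a_end) &&
                       !(b_ref == best$b_ref && b_strand == best$b_strand &&
                           b_last0 == best$b_last0)) {
              # a genuine tie: the partner matches equally well at two
              # unrelated loci (the reversed reading of the same junction,
              # excluded above, is not ambiguity)
              best$tied <- TRUE
            }
          }
        }
      }
      if (!is.null(best)) {
        if (isTRUE(best$tied)) {
          n_ambiguous <- n_ambiguous + 1L
        } else {
          best$score <- NULL; best$tied <- NULL
          sas[[length(sas) + 1L]] <- best
        }
      }
    }
  }
  structure(sas, mapped = mapped, n_ambiguous = n_ambiguous)
}

is_archetype <- function(subtels, e) {
  i <- match(e, subtels$end_id)
  !is.na(i) && subtels$archetype[i]
}

same_family <- function(subtels, e1, e2) {
  f <- function(e) {
    i <- match(e, subtels$end_id)
    if (is.na(i)) e else subtels$family_id[i]
  }
  identical(f(e1), f(e2))
}
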