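#' Call fusion events from amplicon reads
#'
#' Runs the full calling path: split alignment of every read, closed-form
#' junction resolution (breakpoints, microhomology, insertion), insertion
#' templating classification, fusion category assignment (with the 21q
#' family archetype-identity rule), subtelomeric deletion metrics, and
#' per-sample deduplication into unique events. Mate pairs whose two reads
#' map end-to-end to a targeted subtelomere and a different reference —
#' with no base-resolution call nearby — are reported as interval-resolution
#' calls with `NA` junction metrics; these are excluded from MH/INS
#' summaries.
#'
#' @param reads list with `r1`, `r2` (see [generate_reads()]) or a named
#'   character vector of reads.
#' @param ref a `synthetic_reference` (use the patched reference from
#'   [simulate_fusions()] when calling simulated data).
#' @param sample,stage labels attached to every call.
#' @param k,max_mismatch,max_ins,min_seg see [split_align()].
#' @param tol deduplication breakpoint tolerance in bp.
#' @param family_margin identity margin for the 21q family rule.
#' @param ins_window templating search window in bp.
#' @param min_support discard events with fewer supporting reads.
#' @param idx optional precomputed [kmer_index()].
#' @return a `fusion_calls` data frame: one row per unique event with
#'   columns sample, stage, category, end_a, bp_a, chrom_b, strand_b, bp_b,
#'   mh_bp, ins_seq, ins_templated, del_a, del_b, delta_del, support,
#'   resolution; attributes `n_ambiguous` and `n_reads`.
#' @export
call_fusions <- function(reads, ref, sample = "S1", stage = "Deep",
                         k = 21L, max_mismatch = 2L, max_ins = 50L,
                         min_seg = 21L, tol = 5L, family_margin = 0.02,
                         ins_window = 100L, min_support = 1L, idx = NULL) {
  sas <- split_align(reads, ref, k = k, max_mismatch = max_mismatch,
                     max_ins = max_ins, min_seg = min_seg, idx = idx)
  subtels <- ref$subtelomeres
  rows <- lapply(sas, function(sa) {
    r <- resolve_junction(sa, ref)
    st <- subtel_zone(ref, sa$a_end)
    if (r$bp_a <= st$primer_offset || r$bp_a > st$telomere_boundary)
      return(NULL)
    category <- classify_fusion(sa, r$bp_b, ref,
                                family_margin = family_margin)
    tmpl <- classify_insertion(r$ins_seq, ref_sequence(ref, sa$a_end),
                               ref_sequence(ref, sa$b_ref),
                               r$bp_a, r$bp_b, window = ins_window)
    del_a <- compute_deletion(r$bp_a, st)
    del_b <- NA_integer_
    if (category != "genomic" && sa$b_ref %in% subtels$end_id) {
      stb <- subtel_zone(ref, sa$b_ref)
      if (r$bp_b > stb$primer_offset && r$bp_b <= stb$telomere_boundary)
        del_b <- compute_deletion(r$bp_b, stb)
    }
    data.frame(sample = sample, stage = stage, category = category,
               end_a = sa$a_end, bp_a = r$bp_a, chrom_b = sa$b_ref,
               strand_b = sa$b_strand, bp_b = r$bp_b, mh_bp = r$mh_bp,
               ins_seq = r$ins_seq, ins_templated = tmpl,
               del_a = del_a, del_b = del_b,
               delta_del = if (category == "intra" && !is.na(del_b))
                 abs(del_a - del_b) else NA_integer_,
               support = 1L, resolution = "base",
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  if (is.null(calls)) calls <- empty_calls()
  calls <- canonicalize_calls(calls, ref)
  calls <- dedupe_calls(calls, tol = tol)
  calls <- calls[calls$support >= min_support, , drop = FALSE]
  iv <- interval_calls(attr(sas, "mapped"), calls, ref, sample, stage)
  calls <- rbind(calls, iv)
  rownames(calls) <- NULL
  structure(calls, class = c("fusion_calls", class(calls)),
            n_ambiguous = attr(sas, "n_ambiguous"),
            n_reads = if (is.list(reads) && !is.null(reads$r1))
              length(reads$r1) * 2L else length(reads))
}

empty_calls <- function() {
  data.frame(sample = character(), stage = character(),
             category = character(), end_a = character(), bp_a = integer(),
             chrom_b = character(), strand_b = character(), bp_b = integer(),
             mh_bp = integer(), ins_seq = character(),
             ins_templated = character(), del_a = integer(),
             del_b = integer(), delta_del = integer(), support = integer(),
             resolution = character(), stringsAsFactors = FALSE)
}

# Intra/inter events are seen from either fused end depending on read
# orientation; put them in a canonical orientation (lexicographically
# smaller (end, breakpoint) as the A side) so duplicates collapse. The
# leftmost-placement convention is side-dependent: reading the junction
# from the other end reports the opposite edge of the MH window, so a
# swap also shifts both breakpoints by mh_bp to restore the leftmost
# placement in the canonical orientation. Deletions are recomputed from
# the shifted breakpoints.
canonicalize_calls <- function(calls, ref) {
  if (nrow(calls) == 0) return(calls)
  swap <- calls$category %in% c("intra", "inter") &
    calls$chrom_b %in% ref$subtelomeres$end_id &
    !is.na(calls$bp_a) & !is.na(calls$bp_b) &
    (calls$chrom_b < calls$end_a |
       (calls$chrom_b == calls$end_a & calls$bp_b < calls$bp_a))
  if (any(swap)) {
    mh <- ifelse(is.na(calls$mh_bp[swap]), 0L, calls$mh_bp[swap])
    new_a_end <- calls$chrom_b[swap]
    new_b_end <- calls$end_a[swap]
    new_bp_a <- calls$bp_b[swap] - mh
    new_bp_b <- calls$bp_a[swap] + mh
    calls$end_a[swap] <- new_a_end
    calls$bp_a[swap] <- new_bp_a
    calls$chrom_b[swap] <- new_b_end
    calls$bp_b[swap] <- new_bp_b
    bnd <- ref$subtelomeres$telomere_boundary[
      match(new_a_end, ref$subtelomeres$end_id)]
    calls$del_a[swap] <- as.integer(bnd - new_bp_a)
    bnd_b <- ref$subtelomeres$telomere_boundary[
      match(new_b_end, ref$subtelomeres$end_id)]
    calls$del_b[swap] <- as.integer(bnd_b - new_bp_b)
    if ("delta_del" %in% names(calls)) {
      intra <- swap & calls$category == "intra"
      calls$delta_del[intra] <- abs(calls$del_a[intra] - calls$del_b[intra])
    }
  }
  calls
}

#' Merge duplicate calls of the same event
#'
#' Calls from one sample agreeing in category, fused end, partner reference
#' and strand, with both breakpoints within `tol` bp, are merged: support is
#' summed and junction metrics are taken from the highest-support member.
#' Never increases the event count, and total support is conserved.
#'
#' @param calls a `fusion_calls` data frame.
#' @param tol breakpoint agreement tolerance in bp (default 5).
#' @return deduplicated calls.
#' @export
dedupe_calls <- function(calls, tol = 5L) {
  if (nrow(calls) == 0) return(calls)
  key <- paste(calls$sample, calls$category, calls$end_a, calls$chrom_b,
               calls$strand_b, calls$resolution, sep = "\r")
  out <- lapply(split(seq_len(nrow(calls)), key), function(ix) {
    sub <- calls[ix, , drop = FALSE]
    sub <- sub[order(sub$bp_a, sub$bp_b), , drop = FALSE]
    cl <- integer(nrow(sub))
    reps <- list()
    for (i in seq_len(nrow(sub))) {
      assigned <- FALSE
      for (ci in seq_along(reps)) {
        if (abs(sub$bp_a[i] - reps[[ci]][1]) <= tol &&
            abs(sub$bp_b[i] - reps[[ci]][2]) <= tol) {
          cl[i] <- ci; assigned <- TRUE; break
        }
      }
      if (!assigned) {
        reps[[length(reps) + 1L]] <- c(sub$bp_a[i], sub$bp_b[i])
        cl[i] <- length(reps)
      }
    }
    merged <- lapply(split(seq_len(nrow(sub)), cl), function(jx) {
      grp <- sub[jx, , drop = FALSE]
      # per-junction metrics from the most-supported variant of the event
      var_key <- paste(grp$bp_a, grp$bp_b, grp$mh_bp, grp$ins_seq)
      support_by <- tapply(grp$support, var_key, sum)
      top <- grp[var_key == names(which.max(support_by))[1], , drop = FALSE][1, ]
      top$support <- sum(grp$support)
      top
    })
    do.call(rbind, merged)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# mate-pair-only (discordant) evidence -> interval-resolution calls
interval_calls <- function(mapped, calls, ref, sample, stage,
                           cluster_bp = 1000L, near_bp = 2000L) {
  if (is.null(mapped) || nrow(mapped) == 0) return(empty_calls())
  targets <- targeted_ends(ref)
  m <- data.table::as.data.table(mapped)
  m[, `:=`(pair = sub("/[12]$", "", read_id))]
  pairs <- m[, if (.N == 2L) list(ref1 = ref[1], ref2 = ref[2]),
             by = "pair"]
  if (nrow(pairs) == 0) return(empty_calls())
  disc <- pairs[(ref1 %in% targets) != (ref2 %in% targets)]
  if (nrow(disc) == 0) return(empty_calls())
  disc[, `:=`(end_a = ifelse(ref1 %in% targets, ref1, ref2),
              partner = ifelse(ref1 %in% targets, ref2, ref1))]
  # drop evidence already explained by a base-resolution call on the
  # same (end, partner) pair
  explained <- unique(paste(calls$end_a, calls$chrom_b))
  disc <- disc[!(paste(end_a, partner) %in% explained)]
  if (nrow(disc) == 0) return(empty_calls())
  grp <- disc[, list(support = .N), by = c("end_a", "partner")]
  out <- data.frame(sample = sample, stage = stage, category = "genomic",
                    end_a = grp$end_a, bp_a = NA_integer_,
                    chrom_b = grp$partner, strand_b = NA_character_,
                    bp_b = NA_integer_, mh_bp = NA_integer_,
                    ins_seq = NA_character_, ins_templated = NA_character_,
                    del_a = NA_integer_, del_b = NA_integer_,
                    delta_del = NA_integer_, support = grp$support,
                    resolution = "interval", stringsAsFactors = FALSE)
  out$category <- ifelse(grp$partner %in% ref$subtelomeres$end_id,
                         "inter", "genomic")
  out
}

#' Subtelomeric deletion of a fused end
#'
#' The subtelomeric sequence lost relative to the telomere-repeat boundary:
#' `deletion_bp = telomere_boundary - breakpoint`.
#'
#' @param bp 0-based junction coordinate on the subtelomere.
#' @param subtel one row of `ref$subtelomeres` (needs `primer_offset`,
#'   `telomere_boundary`).
#' @return deletion in bp (0 when the breakpoint sits at the boundary).
#' @export
compute_deletion <- function(bp, subtel) {
  if (any(bp > subtel$telomere_boundary))
    stop("breakpoint beyond telomere boundary")
  if (any(bp <= subtel$primer_offset))
    stop("breakpoint not beyond primer")
  as.integer(subtel$telomere_boundary - bp)
}

#' Deletion asymmetry of a fused chromatid pair
#' @param d1,d2 deletions (bp) of the two fused ends of an intra call.
#' @return `|d1 - d2|` in bp.
#' @export
delta_deletion <- function(d1, d2) as.integer(abs(d1 - d2))

#' Junction frequency distribution along a subtelomere
#'
#' @param calls a `fusion_calls` data frame.
#' @param ref a `synthetic_reference`.
#' @param end_id subtelomere end.
#' @param bin bin width in bp (> 0).
#' @return data frame with `start`, `end` (0-based half-open bins covering
#'   primer to telomere boundary) and `count`; counts sum to the number of
#'   base-resolution calls on the end.
#' @export
junction_histogram <- function(calls, ref, end_id, bin = 100L) {
  if (bin <= 0) stop("bin must be > 0")
  st <- subtel_zone(ref, end_id)
  breaks <- seq(st$primer_offset, st$telomere_boundary + bin - 1L, by = bin)
  if (breaks[length(breaks)] < st$telomere_boundary)
    breaks <- c(breaks, breaks[length(breaks)] + bin)
  sel <- calls$end_a == end_id & calls$resolution == "base"
  bp <- calls$bp_a[sel]
  cnt <- if (length(bp) == 0) integer(length(breaks) - 1L) else
    as.integer(table(cut(bp, breaks, right = TRUE, include.lowest = FALSE)))
  data.frame(start = breaks[-length(breaks)], end = breaks[-1L],
             count = cnt)
}

#' Per-group junction summaries
#'
#' @param calls a `fusion_calls` data frame (base-resolution calls are
#'   summarised; interval calls are excluded).
#' @param group_by grouping column, default `"stage"`.
#' @return data frame with per-group event count, mean/median MH, fraction
#'   of junctions with MH, mean insertion length, fraction of insertions
#'   templated, and class proportions (which sum to 1 per group).
#' @export
summarize_junctions <- function(calls, group_by = "stage") {
  if (nrow(calls) == 0) stop("no calls to summarise")
  base <- calls[calls$resolution == "base", , drop = FALSE]
  if (nrow(base) == 0) stop("no base-resolution calls to summarise")
  grp <- split(seq_len(nrow(base)), base[[group_by]])
  empty <- setdiff(unique(calls[[group_by]]), names(grp))
  if (length(empty) > 0)
    warning("groups without base-resolution calls omitted: ",
            paste(empty, collapse = ", "))
  rows <- lapply(names(grp), function(g) {
    sub <- base[grp[[g]], , drop = FALSE]
    ins_len <- nchar(sub$ins_seq)
    has_ins <- !is.na(ins_len) & ins_len > 0
    data.frame(group = g, n = nrow(sub),
               mean_mh = mean(sub$mh_bp), median_mh = stats::median(sub$mh_bp),
               frac_mh = mean(sub$mh_bp > 0),
               mean_ins_len = if (any(has_ins)) mean(ins_len[has_ins]) else
                 NA_real_,
               frac_ins = mean(has_ins),
               frac_ins_templated = if (any(has_ins))
                 mean(sub$ins_templated[has_ins] == "templated") else NA_real_,
               prop_genomic = mean(sub$category == "genomic"),
               prop_intra = mean(sub$category == "intra"),
               prop_inter = mean(sub$category == "inter"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fusion frequency per diploid genome
#'
#' Converts a mean amplicon yield per reaction into a frequency per diploid
#' genome from the DNA input: `frequency = mean_amplicons /
#' (input_ng * 1000 / pg_per_diploid_genome)`, with 6.6 pg per diploid
#' human genome by default.
#'
#' @param mean_amplicons mean fusion amplicons per reaction.
#' @param input_ng DNA input per reaction in ng (> 0).
#' @param pg_per_diploid_genome genome mass in pg.
#' @return fusion frequency per diploid genome.
#' @export
fusion_frequency_per_genome <- function(mean_amplicons, input_ng,
                                        pg_per_diploid_genome = 6.6) {
  if (any(input_ng <= 0)) stop("input_ng must be > 0")
  mean_amplicons / (input_ng * 1000 / pg_per_diploid_genome)
}
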