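#' Normalise single-nucleus bin counts to a bulk baseline
#'
#' `r_i = log2((c_i / C) / (b_i / B))`: both profiles are scaled to their
#' totals, so a nucleus that is a scalar multiple of the bulk is flat at 0.
#' Bins with zero bulk counts are masked (`NA`) and counted in the
#' `n_masked` attribute.
#'
#' @param nucleus_counts,bulk_counts equal-length non-negative vectors.
#' @return log2-ratio vector with attribute `n_masked`.
#' @export
normalize_bins <- function(nucleus_counts, bulk_counts) {
  if (length(nucleus_counts) != length(bulk_counts))
    stop("nucleus and bulk bin vectors differ in length")
  C <- sum(nucleus_counts)
  B <- sum(bulk_counts)
  if (C == 0) stop("all-zero nucleus profile")
  if (B == 0) stop("all-zero bulk profile")
  mask <- bulk_counts == 0
  r <- rep(NA_real_, length(nucleus_counts))
  r[!mask] <- log2((nucleus_counts[!mask] / C) / (bulk_counts[!mask] / B))
  structure(r, n_masked = sum(mask))
}

rolling_median <- function(x, window) {
  n <- length(x)
  if (window > n) stop("window larger than profile")
  if (window %% 2L == 0L) window <- window + 1L
  h <- window %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    stats::median(x[lo:hi], na.rm = TRUE)
  }, numeric(1))
}

#' Segment a log2-ratio profile into copy-number calls
#'
#' Rolling-median smoothing followed by thresholding and run-merging:
#' smoothed bins above `gain_thr` (or below `loss_thr`) form candidate
#' runs, runs of the same call separated by at most `merge_gap` neutral
#' bins are merged, and runs shorter than `min_len` bins are dropped. The
#' default thresholds (+/- 0.25) sit between 0 and the single-chromatid 4N
#' changes log2(5/4) = 0.32 and log2(3/4) = -0.415.
#'
#' @param ratios log2-ratio vector (may contain `NA` for masked bins).
#' @param window rolling-median window in bins.
#' @param gain_thr,loss_thr call thresholds on the smoothed ratio.
#' @param min_len minimum run length in bins (use `Inf` to call nothing).
#' @param merge_gap largest neutral gap bridged between same-call runs.
#' @param nucleus id attached to the segments.
#' @param bins optional bin table (chrom/start/end) to attach genomic
#'   coordinates; segments never cross chromosome boundaries.
#' @return data frame of segments: nucleus, chrom, start, end (bp when
#'   `bins` given, else NA), start_bin, end_bin (1-based inclusive),
#'   mean_log2_ratio, call.
#' @export
segment_and_call <- function(ratios, window = 5L, gain_thr = 0.25,
                             loss_thr = -0.25, min_len = 5L,
                             merge_gap = 1L, nucleus = NA, bins = NULL) {
  if (window > length(ratios)) stop("window larger than profile")
  if (!is.null(bins) && nrow(bins) != length(ratios))
    stop("bins table does not match profile length")
  chrom_of <- if (is.null(bins)) rep("*", length(ratios)) else bins$chrom
  out <- list()
  for (ch in unique(chrom_of)) {
    ix <- which(chrom_of == ch)
    sm <- rolling_median(ratios[ix], min(window, length(ix)))
    state <- ifelse(is.na(sm), "neutral",
                    ifelse(sm >= gain_thr, "gain",
                           ifelse(sm <= loss_thr, "loss", "neutral")))
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(call = r$values, start = starts, end = ends,
                       stringsAsFactors = FALSE)
    runs <- runs[runs$call != "neutral", , drop = FALSE]
    # bridge short neutral gaps between same-call runs
    if (nrow(runs) > 1L) {
      merged <- runs[1, , drop = FALSE]
      for (i in 2:nrow(runs)) {
        last <- nrow(merged)
        if (runs$call[i] == merged$call[last] &&
            runs$start[i] - merged$end[last] - 1L <= merge_gap) {
          merged$end[last] <- runs$end[i]
        } else {
          merged <- rbind(merged, runs[i, ])
        }
      }
      runs <- merged
    }
    if (nrow(runs) > 0L) {
      runs <- runs[runs$end - runs$start + 1L >= min_len, , drop = FALSE]
    }
    if (nrow(runs) == 0L) next
    seg <- data.frame(
      nucleus = nucleus, chrom = ch,
      start = if (is.null(bins)) NA_integer_ else bins$start[ix[runs$start]],
      end = if (is.null(bins)) NA_integer_ else bins$end[ix[runs$end]],
      start_bin = ix[runs$start], end_bin = ix[runs$end],
      mean_log2_ratio = vapply(seq_len(nrow(runs)), function(i) {
        mean(ratios[ix[runs$start[i]:runs$end[i]]], na.rm = TRUE)
      }, numeric(1)),
      call = runs$call, stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- seg
  }
  if (length(out) == 0) return(empty_segments())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_segments <- function() {
  data.frame(nucleus = character(), chrom = character(), start = integer(),
             end = integer(), start_bin = integer(), end_bin = integer(),
             mean_log2_ratio = numeric(), call = character(),
             stringsAsFactors = FALSE)
}

#' Call copy-number segments for every nucleus of a bin profile
#'
#' @param profile a `bin_profile` from [simulate_nuclei_bins()] (or a list
#'   with `bins`, `counts`, `bulk`).
#' @param ... passed to [segment_and_call()].
#' @return data frame of segments across all nuclei.
#' @export
call_cna <- function(profile, ...) {
  segs <- lapply(rownames(profile$counts), function(nu) {
    r <- normalize_bins(profile$counts[nu, ], profile$bulk)
    segment_and_call(r, nucleus = nu, bins = profile$bins, ...)
  })
  out <- do.call(rbind, segs)
  if (is.null(out)) out <- empty_segments()
  out
}

#' Intersect copy-number segments with fusion junctions
#'
#' Counts fusion junction points inside gain/loss segments and tests the
#' in-CNA proportion against a control call set (matched simulants) with a
#' two-tailed Fisher's exact test; gains and losses are tallied separately.
#'
#' @param segments segment data frame (see [segment_and_call()]).
#' @param calls observed `fusion_calls`.
#' @param control control calls or simulant truth.
#' @param ref a `synthetic_reference`.
#' @return list: `overlap` (junctions inside any CNA), `n`, `control_overlap`,
#'   `control_n`, `p_value`, `tally` (per-call-class counts), `table`.
#' @export
intersect_cna_fusions <- function(segments, calls, control, ref) {
  pts <- junction_points(calls, ref, side = "partner")
  cpts <- junction_points(control, ref, side = "partner")
  if (nrow(segments) == 0) {
    return(list(overlap = 0L, n = length(pts),
                control_overlap = 0L, control_n = length(cpts),
                p_value = 1, tally = c(gain = 0L, loss = 0L),
                table = matrix(0L, 2, 2)))
  }
  seg_gr <- GenomicRanges::GRanges(
    segments$chrom, IRanges::IRanges(start = segments$start + 1L,
                                     end = pmax(segments$end,
                                                segments$start + 1L)))
  ov <- IRanges::overlapsAny(pts, seg_gr)
  cov <- IRanges::overlapsAny(cpts, seg_gr)
  tally <- vapply(c("gain", "loss"), function(cl) {
    sub <- seg_gr[segments$call == cl]
    if (length(sub) == 0) return(0L)
    sum(IRanges::overlapsAny(pts, sub))
  }, integer(1))
  tab <- rbind(c(sum(ov), sum(!ov)), c(sum(cov), sum(!cov)))
  list(overlap = sum(ov), n = length(pts),
       control_overlap = sum(cov), control_n = length(cpts),
       p_value = fisher_exact_2x2(tab), tally = tally, table = tab)
}

#' Per-chromosome CNA-fusion intersection rates
#'
#' @param counts named (by chromosome) intersection counts.
#' @param sizes named chromosome sizes in bp.
#' @param fusion_counts named per-chromosome fusion counts.
#' @return list with `table` (chrom, count, per_mb, fusion_adjusted) and
#'   `mean_rate`, `mean_per_mb`, `mean_fusion_adjusted`.
#' @export
per_chrom_intersections <- function(counts, sizes, fusion_counts) {
  if (length(counts) == 0) stop("no intersection results")
  chroms <- names(counts)
  if (!all(chroms %in% names(sizes)))
    stop("chromosome absent from sizes: ",
         paste(setdiff(chroms, names(sizes)), collapse = ", "))
  per_mb <- counts / (sizes[chroms] / 1e6)
  fadj <- counts / fusion_counts[chroms]
  tab <- data.frame(chrom = chroms, count = as.numeric(counts),
                    per_mb = as.numeric(per_mb),
                    fusion_adjusted = as.numeric(fadj),
                    stringsAsFactors = FALSE)
  list(table = tab, mean_rate = mean(tab$count),
       mean_per_mb = mean(tab$per_mb),
       mean_fusion_adjusted = mean(tab$fusion_adjusted, na.rm = TRUE))
}
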