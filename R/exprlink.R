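#' Median-of-ratios size factors and normalised counts
#'
#' The per-sample size factor is the median across genes of the ratio of a
#' sample's counts to the per-gene geometric-mean reference (genes with a
#' zero count in any sample are excluded from the reference); normalised
#' counts are raw counts divided by the factor.
#'
#' @param counts genes x samples matrix of non-negative counts (>= 2
#'   samples; at least one gene nonzero in every sample).
#' @return list with `factors` (named per-sample) and `normalized`.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need >= 2 samples")
  ok <- rowSums(counts == 0) == 0
  if (!any(ok)) stop("no gene with nonzero counts in all samples")
  logref <- rowMeans(log(counts[ok, , drop = FALSE]))
  factors <- apply(counts[ok, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - logref))
  })
  list(factors = factors,
       normalized = sweep(counts, 2, factors, "/"))
}

#' Three-way expression status of a gene at a crisis stage
#'
#' Mean normalised count over the stage's samples: at least `t_hi` is
#' expressed, below `t_lo` not expressed, in between ambiguous.
#'
#' @param gene gene id.
#' @param stage stage label.
#' @param normalized normalised counts (genes x samples).
#' @param stages per-sample stage labels (aligned with columns).
#' @param t_lo,t_hi thresholds in normalised counts.
#' @return `"expressed"`, `"not_expressed"` or `"ambiguous"`.
#' @export
expression_status <- function(gene, stage, normalized, stages,
                              t_lo = 1, t_hi = 5) {
  if (!(gene %in% rownames(normalized))) stop("gene not in matrix: ", gene)
  sel <- stages == stage
  if (!any(sel)) stop("stage absent: ", stage)
  m <- mean(normalized[gene, sel])
  if (m >= t_hi) "expressed" else if (m < t_lo) "not_expressed" else
    "ambiguous"
}

#' Link fused genes to stage-matched expression
#'
#' Fusions from one crisis stage are linked to expression at the same
#' stage: the fraction of fused genes actively expressed, the fold of the
#' mean normalised count of fused genes over the mean across all genes,
#' and a comparison-of-means test.
#'
#' @param calls `fusion_calls` (junctions from the chosen stage are used;
#'   pass all calls and the stage of interest).
#' @param em an `expression_matrix` (see [simulate_counts()]); any list
#'   with `counts`, `genes`, `samples` works.
#' @param stage stage label.
#' @param t_lo,t_hi thresholds for [expression_status()].
#' @return list: `fused_genes`, `frac_expressed`, `fold`, `compare`
#'   ([compare_means()] result), `mean_fused`, `mean_all`.
#' @export
fused_expression_link <- function(calls, em, stage, t_lo = 1, t_hi = 5) {
  sel_calls <- calls[is.na(calls$stage) | calls$stage == stage, ,
                     drop = FALSE]
  pts <- GenomicRanges::GRanges(
    sel_calls$chrom_b[!is.na(sel_calls$bp_b)],
    IRanges::IRanges(start = sel_calls$bp_b[!is.na(sel_calls$bp_b)] + 1L,
                     width = 1L))
  keep <- as.character(GenomicRanges::seqnames(pts)) %in%
    unique(as.character(GenomicRanges::seqnames(em$genes)))
  pts <- pts[keep]
  hits <- unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(em$genes, pts)))
  fused <- em$genes$gene_id[hits]
  fused <- intersect(fused, rownames(em$counts))
  if (length(fused) == 0) stop("no fused gene mappable to the matrix")
  sf <- size_factors(em$counts)
  norm <- sf$normalized
  stages <- em$samples$stage
  status <- vapply(fused, expression_status, character(1),
                   stage = stage, normalized = norm, stages = stages,
                   t_lo = t_lo, t_hi = t_hi)
  sel <- stages == stage
  if (!any(sel)) stop("stage absent: ", stage)
  gene_means <- rowMeans(norm[, sel, drop = FALSE])
  mean_fused <- mean(gene_means[fused])
  mean_all <- mean(gene_means)
  cmp <- compare_means(mean_fused, stats::sd(gene_means[fused]),
                       length(fused), mean_all, stats::sd(gene_means),
                       length(gene_means))
  list(fused_genes = fused,
       frac_expressed = mean(status == "expressed"),
       fold = mean_fused / mean_all, compare = cmp,
       mean_fused = mean_fused, mean_all = mean_all)
}

#' Per-gene fold changes between two crisis stages
#'
#' `FC = (meanB + pseudocount) / (meanA + pseudocount)` on normalised
#' counts; genes below `min_mean` in both stages are excluded; the top-k
#' list ranks the survivors by |log2 FC|.
#'
#' @param em an `expression_matrix`.
#' @param stageA,stageB stage labels (fold is B over A).
#' @param pseudocount added to both means.
#' @param min_mean exclusion threshold on normalised stage means.
#' @param top_k size of the ranked list.
#' @return list: `table` (gene, meanA, meanB, log2_fc, ranked by |log2 FC|)
#'   and `top` (first `top_k` gene ids; all survivors with a warning when
#'   fewer than `top_k`).
#' @export
stage_fold_changes <- function(em, stageA = "Early", stageB = "Late",
                               pseudocount = 1, min_mean = 10, top_k = 50L) {
  stages <- em$samples$stage
  if (!any(stages == stageA)) stop("stage absent: ", stageA)
  if (!any(stages == stageB)) stop("stage absent: ", stageB)
  norm <- size_factors(em$counts)$normalized
  mA <- rowMeans(norm[, stages == stageA, drop = FALSE])
  mB <- rowMeans(norm[, stages == stageB, drop = FALSE])
  keep <- mA >= min_mean | mB >= min_mean
  tab <- data.frame(gene = rownames(norm)[keep], meanA = mA[keep],
                    meanB = mB[keep],
                    log2_fc = log2((mB[keep] + pseudocount) /
                                     (mA[keep] + pseudocount)),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-abs(tab$log2_fc)), ]
  rownames(tab) <- NULL
  if (top_k > nrow(tab)) {
    warning("top_k exceeds surviving genes; returning all")
    top_k <- nrow(tab)
  }
  list(table = tab, top = tab$gene[seq_len(top_k)])
}

#' Overlap of top-gene lists across cell lines
#'
#' @param top_lists list of >= 2 character vectors of gene ids (no empty
#'   list allowed).
#' @return list: `shared_by` (named counts of genes on exactly 1, 2, ...
#'   lists; sums to the union size) and `intersection` (genes on every
#'   list).
#' @export
overlap_across_lines <- function(top_lists) {
  if (length(top_lists) < 2L) stop("need >= 2 lists")
  if (any(vapply(top_lists, length, integer(1)) == 0L))
    stop("empty gene list")
  u <- unique(unlist(top_lists))
  k <- vapply(u, function(g) {
    sum(vapply(top_lists, function(l) g %in% l, logical(1)))
  }, integer(1))
  shared <- vapply(seq_along(top_lists), function(i) sum(k == i), integer(1))
  names(shared) <- as.character(seq_along(top_lists))
  list(shared_by = shared, intersection = u[k == length(top_lists)])
}
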