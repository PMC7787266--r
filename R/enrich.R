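#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities, at
#' fixed margins, of every table at most as probable as the observed one.
#' For the table sizes this package meets, the hypergeometric weights
#' `choose(r1, x) * choose(r2, c1 - x)` are exact integers below 2^53, so
#' the "at most as probable" comparison is exact integer arithmetic; larger
#' tables fall back to log-space weights with a 1e-7 relative tie slack. A
#' table with a zero margin has probability 1 by convention.
#'
#' @param tab 2x2 matrix (or length-4 vector, row-major) of non-negative
#'   integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  x <- as.integer(round(as.vector(t(as.matrix(tab)))))
  if (length(x) != 4L || any(x < 0)) stop("need a 2x2 non-negative table")
  a <- x[1]; b <- x[2]; c_ <- x[3]; d <- x[4]
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  if (r1 == 0L || r2 == 0L || c1 == 0L || c2 == 0L) return(1)
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  xs <- lo:hi
  w <- choose(r1, xs) * choose(r2, c1 - xs)
  if (all(is.finite(w)) && max(w) < 2^53) {
    sum(w[w <= w[xs == a]]) / sum(w)
  } else {
    lw <- lchoose(r1, xs) + lchoose(r2, c1 - xs)
    lobs <- lw[xs == a]
    keep <- lw <= lobs + log(1 + 1e-7)
    exp(log(sum(exp(lw[keep] - max(lw)))) -
          log(sum(exp(lw - max(lw)))))
  }
}

pearson_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  r <- rowSums(tab); cc <- colSums(tab)
  if (n == 0 || any(r == 0) || any(cc == 0))
    return(list(statistic = 0, p_value = 1))
  stat <- n * (tab[1, 1] * tab[2, 2] - tab[1, 2] * tab[2, 1])^2 /
    (r[1] * r[2] * cc[1] * cc[2])
  list(statistic = unname(stat),
       p_value = stats::pchisq(unname(stat), df = 1, lower.tail = FALSE))
}

# chi-squared when all expected cells >= 5, else Fisher (counts rounded);
# no continuity correction. `method` forces one route.
test_2x2 <- function(tab, method = "auto") {
  tab <- as.matrix(tab)
  n <- sum(tab)
  exp_cells <- outer(rowSums(tab), colSums(tab)) / max(n, 1)
  if (method == "chisq" || (method == "auto" && all(exp_cells >= 5))) {
    c(pearson_2x2(tab), method = "chisq")
  } else {
    list(statistic = NA_real_, p_value = fisher_exact_2x2(round(tab)),
         method = "fisher")
  }
}

#' Junction points of a call set as genomic positions
#'
#' @param calls a `fusion_calls` data frame (or a simulation truth table).
#' @param ref a `synthetic_reference`.
#' @param side `"partner"` for the partner-locus coordinate of genomic
#'   fusions, `"subtel"` for subtelomere breakpoints of every
#'   base-resolution call (both fused ends of intra/inter events).
#' @return a `GRanges` of width-1 junction points.
#' @export
junction_points <- function(calls, ref, side = c("partner", "subtel")) {
  side <- match.arg(side)
  base <- calls
  if (side == "partner") {
    sel <- base$chrom_b %in% names(ref$minigenome) & !is.na(base$bp_b)
    sub <- base[sel, , drop = FALSE]
    if (nrow(sub) == 0) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(sub$chrom_b,
                           IRanges::IRanges(start = sub$bp_b + 1L, width = 1L))
  } else {
    ends <- ref$subtelomeres$end_id
    p1 <- base[!is.na(base$bp_a), c("end_a", "bp_a")]
    names(p1) <- c("end", "bp")
    p2 <- base[base$chrom_b %in% ends & !is.na(base$bp_b),
               c("chrom_b", "bp_b")]
    names(p2) <- c("end", "bp")
    pts <- rbind(p1, p2)
    if (nrow(pts) == 0) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(pts$end,
                           IRanges::IRanges(start = pts$bp + 1L, width = 1L))
  }
}

#' Per-chromosome fusion enrichment against size-predicted frequencies
#'
#' The predicted count per chromosome is the overall fusion frequency per
#' kb multiplied by the chromosome size (`expected_i = total * L_i / sum L`);
#' each chromosome is tested with a two-cell goodness-of-fit chi-squared
#' (observed on/off the chromosome against the expected split). Expected
#' counts sum exactly to the observed total.
#'
#' @param calls a `fusion_calls` data frame (genomic junctions are used).
#' @param sizes named chromosome sizes (bp).
#' @return data frame: chrom, observed, expected, statistic, p_value, fold.
#' @export
chrom_enrichment <- function(calls, sizes) {
  if (any(sizes <= 0)) stop("zero-length chromosome")
  obs_chr <- calls$chrom_b[calls$chrom_b %in% names(sizes) &
                             !is.na(calls$bp_b)]
  if (length(obs_chr) == 0) stop("no genomic calls")
  total <- length(obs_chr)
  o <- vapply(names(sizes), function(ch) sum(obs_chr == ch), numeric(1))
  e <- total * sizes / sum(sizes)
  stat <- p <- numeric(length(sizes))
  for (i in seq_along(sizes)) {
    e2 <- c(e[i], total - e[i])
    o2 <- c(o[i], total - o[i])
    if (any(e2 == 0)) { stat[i] <- 0; p[i] <- 1; next }
    stat[i] <- sum((o2 - e2)^2 / e2)
    p[i] <- stats::pchisq(stat[i], df = 1, lower.tail = FALSE)
  }
  data.frame(chrom = names(sizes), observed = unname(o),
             expected = unname(e), statistic = stat, p_value = p,
             fold = unname(o / e), stringsAsFactors = FALSE)
}

#' Coincidence of fusion junctions with an annotation track
#'
#' Tests the proportion of junction points falling inside a feature track
#' against a control: either the genome fraction the track covers (the
#' control row is the same number of junctions split by that fraction) or a
#' matched simulant call set. Chi-squared without continuity correction
#' when all expected cells are at least 5, Fisher's exact test otherwise.
#'
#' @param calls a `fusion_calls` data frame.
#' @param track a `GRanges` feature track.
#' @param ref a `synthetic_reference`.
#' @param control either a single numeric genome fraction or a simulant
#'   calls/truth data frame.
#' @param side which junction coordinate to use (see [junction_points()]).
#' @param method `"auto"` (the expected-cell rule), `"chisq"` or
#'   `"fisher"`.
#' @return one-row data frame: observed in/out, control in/out, proportions,
#'   fold, statistic, p_value, method, direction.
#' @export
feature_coincidence <- function(calls, track, ref, control,
                                side = "partner", method = "auto") {
  if (length(track) == 0) stop("empty feature track")
  pts <- junction_points(calls, ref, side = side)
  if (length(pts) == 0) stop("no junction points in call set")
  n_in <- sum(IRanges::overlapsAny(pts, track))
  n <- length(pts)
  if (is.numeric(control) && length(control) == 1L) {
    ctrl_in <- n * control
    ctrl_out <- n * (1 - control)
    ctrl_prop <- control
  } else {
    cpts <- junction_points(control, ref, side = side)
    if (length(cpts) == 0) stop("no junction points in control set")
    ctrl_in <- sum(IRanges::overlapsAny(cpts, track))
    ctrl_out <- length(cpts) - ctrl_in
    ctrl_prop <- ctrl_in / length(cpts)
  }
  tab <- rbind(c(n_in, n - n_in), c(ctrl_in, ctrl_out))
  tst <- test_2x2(tab, method = method)
  obs_prop <- n_in / n
  data.frame(observed_in = n_in, observed_out = n - n_in,
             control_in = ctrl_in, control_out = ctrl_out,
             observed_prop = obs_prop, control_prop = ctrl_prop,
             fold = obs_prop / ctrl_prop,
             statistic = tst$statistic, p_value = tst$p_value,
             method = tst$method,
             direction = if (obs_prop < ctrl_prop) "depleted" else
               if (obs_prop > ctrl_prop) "enriched" else "equal",
             stringsAsFactors = FALSE)
}

#' Length statistics of genes captured in fusions
#'
#' @param calls a `fusion_calls` data frame.
#' @param genes a `GRanges` gene track (with `gene_id` metadata).
#' @param ref a `synthetic_reference`.
#' @param simulants optional simulant calls/truth for a matched comparison.
#' @return list with `genes` (unique fused gene ids), `mean`, `sd`, `n`,
#'   `vs_all` and (when simulants given) `vs_simulant`, each a
#'   [compare_means()] result.
#' @export
fused_gene_stats <- function(calls, genes, ref, simulants = NULL) {
  pts <- junction_points(calls, ref, side = "partner")
  hits <- unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(genes, pts)))
  if (length(hits) == 0) {
    warning("no fused genes")
    return(list(genes = character(0), mean = NA_real_, sd = NA_real_,
                n = 0L, vs_all = NULL, vs_simulant = NULL))
  }
  w <- GenomicRanges::width(genes)
  fused_w <- w[hits]
  out <- list(genes = genes$gene_id[hits], mean = mean(fused_w),
              sd = if (length(fused_w) > 1) stats::sd(fused_w) else 0,
              n = length(fused_w))
  out$vs_all <- if (out$n >= 2)
    compare_means(out$mean, out$sd, out$n, mean(w), stats::sd(w),
                  length(w)) else NULL
  if (!is.null(simulants)) {
    spts <- junction_points(simulants, ref, side = "partner")
    sh <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(genes, spts)))
    if (length(sh) >= 2) {
      sw <- w[sh]
      out$vs_simulant <- compare_means(out$mean, out$sd, out$n,
                                       mean(sw), stats::sd(sw), length(sw))
    }
  }
  out
}

#' Comparison of two means from summary statistics
#'
#' `z = (m1 - m2) / sqrt(sd1^2/n1 + sd2^2/n2)` with a two-sided p-value
#' from the standard normal.
#'
#' @param m1,sd1,n1,m2,sd2,n2 group means, SDs and sizes (n >= 2, sd >= 0).
#' @return list with `z` and `p_value`.
#' @export
compare_means <- function(m1, sd1, n1, m2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be >= 2")
  if (sd1 < 0 || sd2 < 0) stop("sds must be >= 0")
  se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
  z <- if (se == 0) 0 else (m1 - m2) / se
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' LTR coincidence of fusion junctions versus matched simulants
#'
#' Compares the proportion of junctions falling inside LTR repeats between
#' an observed call set and its simulant null, either within the
#' subtelomeres (subtelomere breakpoints against each end's LTR interval)
#' or genome-wide (genomic partner points against the LTR annotation
#' track), with a 2x2 chi-squared and the direction of the difference.
#'
#' @param calls observed `fusion_calls`.
#' @param simulants simulant calls or truth table.
#' @param ref a `synthetic_reference`.
#' @param scope `"subtelomere"` or `"genome"`.
#' @return one-row data frame as in [feature_coincidence()].
#' @export
ltr_depletion <- function(calls, simulants, ref,
                          scope = c("subtelomere", "genome")) {
  scope <- match.arg(scope)
  if (nrow(calls) == 0 || nrow(simulants) == 0)
    stop("both call sets must be non-empty")
  if (scope == "subtelomere") {
    st <- ref$subtelomeres
    track <- GenomicRanges::GRanges(
      st$end_id, IRanges::IRanges(start = st$ltr_start + 1L,
                                  end = st$ltr_end))
    side <- "subtel"
  } else {
    track <- ref$annotation$ltr
    side <- "partner"
  }
  if (length(track) == 0) stop("no LTR intervals in scope")
  feature_coincidence(calls, track, ref, control = simulants, side = side)
}
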