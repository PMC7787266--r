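test_that("the exact 2x2 Fisher test enumerates hypergeometric tables", {
  expect_equal(fisher_exact_2x2(matrix(0, 2, 2)), 1)
  expect_equal(fisher_exact_2x2(rbind(c(3, 1), c(1, 3))), 34 / 70)
  # invariance under transposition and row/column swaps
  set.seed(77)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6), 2, 2)
    p <- fisher_exact_2x2(tab)
    expect_equal(fisher_exact_2x2(t(tab)), p)
    expect_equal(fisher_exact_2x2(tab[2:1, ]), p)
    expect_equal(fisher_exact_2x2(tab[, 2:1]), p)
    # independent log-space enumeration oracle
    expect_equal(p, oracle_fisher(tab), tolerance = 1e-12)
    # and the reference implementation in stats
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
  # exhaustive agreement with enumeration for all tables with margins <= 12
  for (r1 in 0:12) for (r2 in 0:12) {
    for (c1 in max(0, r1 + r2 - 12):min(12, r1 + r2)) {
      for (a in max(0, c1 - r2):min(r1, c1)) {
        tab <- rbind(c(a, r1 - a), c(c1 - a, r2 - (c1 - a)))
        expect_equal(fisher_exact_2x2(tab), oracle_fisher(tab),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("per-chromosome enrichment uses size-predicted expectations", {
  calls <- data.frame(chrom_b = c(rep("chr1", 6), rep("chr2", 2)),
                      bp_b = 1:8, stringsAsFactors = FALSE)
  sizes <- c(chr1 = 1000, chr2 = 3000)
  ce <- chrom_enrichment(calls, sizes)
  expect_equal(ce$expected, c(2, 6))
  expect_equal(sum(ce$expected), sum(ce$observed))
  # per-chromosome 2-cell statistic matches the chisq.test oracle
  o <- suppressWarnings(stats::chisq.test(c(6, 2), p = c(1000, 3000) / 4000))
  expect_equal(ce$statistic[1], unname(o$statistic))
  expect_equal(ce$p_value[1], o$p.value)
  # a single chromosome is its own expectation: p = 1
  ce1 <- chrom_enrichment(calls, c(chr1 = 1000))
  expect_equal(ce1$p_value, 1)
  expect_error(chrom_enrichment(calls, c(chr1 = 0, chr2 = 10)), "zero")
  expect_error(chrom_enrichment(calls[0, ], sizes), "no genomic calls")
})

test_that("feature coincidence tests junction points against fraction or
          simulant controls", {
  cfg <- small_cfg(seed = 71)
  ref <- build_reference(cfg)
  calls <- data.frame(chrom_b = rep("chr1", 10),
                      bp_b = as.integer(seq(1000, 50000, length.out = 10)),
                      stringsAsFactors = FALSE)
  whole <- GenomicRanges::GRanges(
    c("chr1", "chr2"), IRanges::IRanges(start = 1, end = 60000))
  fc <- feature_coincidence(calls, whole, ref, control = 0.5)
  expect_equal(fc$observed_prop, 1)
  # 9/10 inside vs fraction 0.5: identical to a direct 2x2 oracle
  track <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(start = 1, end = 30000))
  calls9 <- calls
  calls9$bp_b <- c(as.integer(seq(1000, 29000, length.out = 9)), 45000L)
  fc9 <- feature_coincidence(calls9, track, ref, control = 0.5,
                             method = "chisq")
  o <- telocrisis:::pearson_2x2(rbind(c(9, 1), c(5, 5)))
  expect_equal(fc9$statistic, o$statistic)
  expect_equal(fc9$p_value, o$p_value)
  # the automatic rule sends small expected cells to Fisher instead
  fc9f <- feature_coincidence(calls9, track, ref, control = 0.5)
  expect_equal(fc9f$method, "fisher")
  expect_equal(fc9f$p_value, fisher_exact_2x2(rbind(c(9, 1), c(5, 5))))
  # observed equal to control: fold 1 and p = 1
  fceq <- feature_coincidence(calls9, track, ref, control = 0.9)
  expect_equal(fceq$fold, 1)
  expect_gte(fceq$p_value, 0.99)
  # simulant-control route builds the table from the control's junctions
  ctrl <- data.frame(chrom_b = rep(c("chr1", "chr2"), each = 20),
                     bp_b = rep(as.integer(seq(2000, 58000,
                                               length.out = 20)), 2),
                     stringsAsFactors = FALSE)
  fcs <- feature_coincidence(calls9, track, ref, control = ctrl)
  in_ctrl <- sum(ctrl$chrom_b == "chr1" & ctrl$bp_b <= 30000)
  expect_equal(fcs$control_in, in_ctrl)
  expect_error(feature_coincidence(calls9[0, ], track, ref, 0.5), "no junction")
  expect_error(feature_coincidence(calls9, GenomicRanges::GRanges(), ref,
                                   0.5), "empty")
})

test_that("comparison of means matches the normal-theory closed form", {
  r <- compare_means(10, 2, 100, 10, 2, 100)
  expect_equal(r$z, 0)
  expect_equal(r$p_value, 1)
  r2 <- compare_means(10, 2, 100, 9, 2, 100)
  expect_equal(r2$z, 1 / sqrt(0.08))
  expect_equal(round(r2$z, 4), 3.5355)
  expect_equal(r2$p_value, 2 * pnorm(-abs(r2$z)))
  expect_lt(abs(r2$p_value - 4.07e-4), 5e-6)
  r3 <- compare_means(9, 2, 100, 10, 2, 100)
  expect_equal(r3$z, -r2$z)
  expect_equal(r3$p_value, r2$p_value)
  expect_error(compare_means(1, 1, 1, 2, 1, 10), "sizes")
})

test_that("fused-gene length statistics are calibrated against null draws", {
  cfg <- small_cfg(seed = 73)
  ref <- build_reference(cfg)
  genes <- ref$annotation$genes
  w <- GenomicRanges::width(genes)
  # one fused gene: its own mean, sd 0 (degenerate but defined)
  g1 <- genes[5]
  calls1 <- data.frame(
    chrom_b = as.character(GenomicRanges::seqnames(g1)),
    bp_b = GenomicRanges::start(g1) + 3L, stringsAsFactors = FALSE)
  fg1 <- fused_gene_stats(calls1, genes, ref)
  expect_equal(fg1$n, 1L)
  expect_equal(fg1$mean, w[5])
  # fused sets drawn uniformly from all genes: |z| < 3 in >= 95% of
  # seeded replicates
  set.seed(99)
  zs <- replicate(100, {
    idx <- sample(length(genes), 40)
    g <- genes[idx]
    cl <- data.frame(chrom_b = as.character(GenomicRanges::seqnames(g)),
                     bp_b = GenomicRanges::start(g) + 1L,
                     stringsAsFactors = FALSE)
    fused_gene_stats(cl, genes, ref)$vs_all$z
  })
  expect_gte(mean(abs(zs) < 3), 0.95)
  # restricting the fused set to genes above the median length forces z > 0
  long <- genes[w > stats::median(w)][1:30]
  cl <- data.frame(chrom_b = as.character(GenomicRanges::seqnames(long)),
                   bp_b = GenomicRanges::start(long) + 1L,
                   stringsAsFactors = FALSE)
  expect_gt(fused_gene_stats(cl, genes, ref)$vs_all$z, 0)
  # no fused genes: empty result with warning
  none <- data.frame(chrom_b = "chr1", bp_b = NA_integer_)
  expect_warning(fg0 <- fused_gene_stats(none, genes, ref), "no fused")
  expect_equal(fg0$n, 0L)
})

test_that("LTR depletion compares observed and simulant junction
          proportions with direction", {
  cfg <- small_cfg(seed = 79)
  ref <- build_reference(cfg)
  sim <- generate_simulants(ref, 3000, cfg, with_reads = FALSE)
  # observed == simulants: fold 1
  ld0 <- ltr_depletion(sim$truth, sim$truth, ref, scope = "subtelomere")
  expect_equal(ld0$fold, 1)
  # observed set constructed to avoid subtelomere LTR windows entirely
  st <- ref$subtelomeres
  obs <- sim$truth[1:800, ]
  for (i in seq_len(nrow(obs))) {
    r <- st[st$end_id == obs$end_a[i], ]
    if (obs$bp_a[i] > r$ltr_start && obs$bp_a[i] <= r$ltr_end)
      obs$bp_a[i] <- r$ltr_start - 5L
    if (obs$chrom_b[i] %in% st$end_id) {
      rb <- st[st$end_id == obs$chrom_b[i], ]
      if (obs$bp_b[i] > rb$ltr_start && obs$bp_b[i] <= rb$ltr_end)
        obs$bp_b[i] <- rb$ltr_start - 5L
    }
  }
  ld <- ltr_depletion(obs, sim$truth, ref, scope = "subtelomere")
  expect_equal(ld$direction, "depleted")
  expect_equal(ld$observed_in, 0L)
  # table counts reproduce an independent 2x2 oracle
  ltr_gr <- GenomicRanges::GRanges(
    st$end_id, IRanges::IRanges(st$ltr_start + 1L, st$ltr_end))
  n_in <- sum(IRanges::overlapsAny(
    junction_points(sim$truth, ref, side = "subtel"), ltr_gr))
  expect_equal(ld0$observed_in, n_in)
  # genome scope uses the genomic LTR track
  ldg <- ltr_depletion(sim$truth, sim$truth, ref, scope = "genome")
  expect_equal(ldg$fold, 1)
  expect_error(ltr_depletion(sim$truth[0, ], sim$truth, ref), "non-empty")
})
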