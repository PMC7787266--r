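test_that("reference construction is deterministic and validated", {
  cfg <- small_cfg(seed = 3)
  ref1 <- build_reference(cfg)
  ref2 <- build_reference(cfg)
  expect_identical(ref1$minigenome, ref2$minigenome)
  expect_identical(ref1$subtel_seqs, ref2$subtel_seqs)
  expect_identical(ref1$annotation$genes, ref2$annotation$genes)
  expect_equal(sum(chrom_sizes(ref1)), 120000)
  expect_equal(nrow(ref1$subtelomeres), 4L) # 17p, 21q1, 21q2, XpYp
  expect_equal(sum(ref1$subtelomeres$targeted), 3L)
  # sequences are uppercase ACGT and one LTR interval per end
  expect_true(all(grepl("^[ACGT]+$", ref1$minigenome)))
  expect_true(all(ref1$subtelomeres$ltr_end > ref1$subtelomeres$ltr_start))
  expect_error(sim_config(class_mix = c(0.5, 0.5, 0.5)), "class_mix")
  expect_error(sim_config(primer_offset = 5000, telomere_boundary = 4000),
               "primer_offset")
  expect_error(sim_config(read_len = 900), "read_len")
})

test_that("zero feature density yields an empty track", {
  cfg <- small_cfg(seed = 3,
                   feature_density = c(gene = 0, exon = 0, promoter = 0,
                                       enhancer = 0.5, fragile = 0.02,
                                       ltr = 0.3))
  ref <- build_reference(cfg)
  expect_length(ref$annotation$genes, 0)
  expect_gt(length(ref$annotation$enhancers), 0)
})

test_that("fusion simulation follows the configured class mix and MH law", {
  cfg <- small_cfg(seed = 5)
  ref <- build_reference(cfg)
  expect_equal(nrow(simulate_fusions(ref, cfg, 0)$truth), 0L)
  expect_error(simulate_fusions(ref, cfg, -1))
  # degenerate mix: everything genomic
  cfg1 <- small_cfg(seed = 5, class_mix = c(1, 0, 0))
  s1 <- simulate_fusions(ref, cfg1, 50)
  expect_equal(nrow(s1$truth), 50L)
  expect_true(all(s1$truth$category == "genomic"))
  # truncated-geometric MH: empirical mean within 3 SE of the closed form
  # (genomic-only cohort so the MH patches spread over the whole genome)
  cfg2 <- sim_config(seed = 6, n_chroms = 2L,
                     chrom_lengths = c(200000L, 200000L), mh_mean = 2,
                     ins_prob = 0, class_mix = c(1, 0, 0))
  ref2 <- build_reference(cfg2)
  s2 <- simulate_fusions(ref2, cfg2, 10000)
  p <- 1 / (1 + cfg2$mh_mean)
  kmax <- cfg2$mh_max
  expected <- sum((0:kmax) *
                    c(stats::dgeom(0:(kmax - 1), p),
                      stats::pgeom(kmax - 1, p, lower.tail = FALSE)))
  sd_geom <- sqrt((1 - p) / p^2)
  expect_lt(abs(mean(s2$truth$mh_bp) - expected),
            3 * sd_geom / sqrt(10000))
  # insertions and MH are mutually exclusive
  s3 <- simulate_fusions(ref, small_cfg(seed = 7, ins_prob = 0.5), 500)
  has_ins <- nchar(s3$truth$ins_seq) > 0
  expect_true(all(s3$truth$mh_bp[has_ins] == 0))
  expect_true(all(!is.na(s3$truth$ins_templated[has_ins])))
})

test_that("rendered amplicons realise the recorded junction structure", {
  cfg <- small_cfg(seed = 9)
  ref <- build_reference(cfg)
  sim <- simulate_fusions(ref, cfg, 150)
  # exact concatenation when MH = 0 and no insertion
  plain <- sim$truth[sim$truth$mh_bp == 0 & nchar(sim$truth$ins_seq) == 0, ]
  f <- plain[1, ]
  amp <- render_amplicon(f, sim$ref)
  st <- sim$ref$subtelomeres[sim$ref$subtelomeres$end_id == f$end_a, ]
  a_part <- substr(telocrisis:::ref_sequence(sim$ref, f$end_a),
                   st$primer_offset + 1, f$bp_a)
  expect_identical(substr(amp, 1, nchar(a_part)), a_part)
  # every truth junction resolves back to its recorded breakpoints, MH and
  # insertion against the patched reference
  chk <- telocrisis:::resolve_truth_junctions(sim$truth, sim$ref)
  expect_equal(chk$bp_a, sim$truth$bp_a)
  expect_equal(chk$bp_b, sim$truth$bp_b)
  expect_equal(chk$mh_bp, sim$truth$mh_bp)
  expect_equal(chk$ins_seq, sim$truth$ins_seq)
  # MH agrees with the brute-force enumeration oracle on rendered amplicons
  mh_rows <- which(sim$truth$mh_bp > 0)[1:10]
  for (i in mh_rows) {
    f <- sim$truth[i, ]
    amp <- render_amplicon(f, sim$ref)
    refA <- telocrisis:::ref_sequence(sim$ref, f$end_a)
    refB <- telocrisis:::ref_sequence(sim$ref, f$chrom_b)
    st <- sim$ref$subtelomeres[sim$ref$subtelomeres$end_id == f$end_a, ]
    if (f$strand_b == "-") refB <- revcomp(refB)
    b_end1 <- if (f$strand_b == "+") f$bp_b + f$len_b else
      nchar(refB) - (f$bp_b - f$len_b)
    o <- oracle_split(amp, refA, st$primer_offset + 1L, refB, b_end1)
    expect_equal(o$mh, f$mh_bp, info = f$id)
  }
  # templated insertions occur verbatim within +/-100 bp of a breakpoint
  tm <- sim$truth[which(sim$truth$ins_templated %in% TRUE), ]
  for (i in seq_len(min(nrow(tm), 10))) {
    f <- tm[i, ]
    flag <- classify_insertion(
      f$ins_seq, telocrisis:::ref_sequence(sim$ref, f$end_a),
      telocrisis:::ref_sequence(sim$ref, f$chrom_b), f$bp_a, f$bp_b)
    expect_equal(flag, "templated", info = f$id)
  }
  # out-of-zone breakpoints are rejected
  bad <- sim$truth[1, ]
  bad$bp_a <- cfg$telomere_boundary + 10L
  expect_error(render_amplicon(bad, sim$ref), "boundary")
})

test_that("read generation is seeded, exact at zero error rate, and hits
          its coverage expectation", {
  cfg <- small_cfg(seed = 13, coverage = 30)
  amp <- stats::setNames(
    telocrisis:::with_seed(1, random_dna_str(2000)), "amp1")
  r1 <- telocrisis:::with_seed(99, generate_reads(amp, cfg))
  r2 <- telocrisis:::with_seed(99, generate_reads(amp, cfg))
  expect_identical(r1, r2)
  # every read is an exact substring of the amplicon or its reverse
  # complement
  expect_true(all(vapply(r1$r1, grepl, logical(1), x = amp, fixed = TRUE)))
  rcamp <- revcomp(amp)
  expect_true(all(vapply(r1$r2, function(rd) {
    grepl(rd, amp, fixed = TRUE) || grepl(rd, rcamp, fixed = TRUE)
  }, logical(1))))
  # total sequenced bases near coverage * L * (2 * read_len / frag_mean)
  total <- sum(nchar(r1$r1)) + sum(nchar(r1$r2))
  expected <- 30 * 2000 * (2 * cfg$read_len / cfg$frag_mean)
  expect_lt(abs(total - expected) / expected, 0.15)
  # amplicons shorter than a read are skipped with a warning
  expect_warning(out <- generate_reads(c(amp, tiny = "ACGT"), cfg),
                 "skipped")
  expect_equal(attr(out, "n_skipped"), 1L)
  # byte-identical FASTQ under the same seed
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq_pair(r1, f1)
  write_fastq_pair(r2, f2)
  expect_identical(readLines(paste0(f1, "_R1.fastq")),
                   readLines(paste0(f2, "_R1.fastq")))
  rt <- read_fastq_pair(paste0(f1, "_R1.fastq"), paste0(f1, "_R2.fastq"))
  expect_identical(unname(rt$r1), unname(r1$r1))
})

test_that("simulant null sets are uniform, MH-free and size-exact", {
  cfg <- small_cfg(seed = 17)
  ref <- build_reference(cfg)
  expect_error(generate_simulants(ref, 0, cfg))
  sim <- generate_simulants(ref, 10000, cfg, with_reads = FALSE)
  expect_equal(nrow(sim$truth), 10000L)
  expect_true(all(sim$truth$mh_bp == 0))
  expect_true(all(nchar(sim$truth$ins_seq) == 0))
  # simulants never modify the reference
  expect_identical(sim$ref$minigenome, ref$minigenome)
  expect_identical(sim$ref$subtel_seqs, ref$subtel_seqs)
  # Kolmogorov distance of breakpoints from uniform < 0.02 at n = 10,000
  bp <- sort(sim$truth$bp_a)
  u <- (bp - cfg$primer_offset) / (cfg$telomere_boundary - cfg$primer_offset)
  ks <- max(abs(seq_along(u) / length(u) - u),
            abs((seq_along(u) - 1) / length(u) - u))
  expect_lt(ks, 0.02)
  # realised MH against the (unpatched) reference is exactly zero
  chk <- telocrisis:::resolve_truth_junctions(sim$truth[1:500, ], sim$ref)
  expect_true(all(chk$mh_bp == 0))
})

test_that("nuclei bin counts follow the programmed copy ratios", {
  cfg <- small_cfg(seed = 21)
  ref <- build_reference(cfg)
  expect_error(simulate_nuclei_bins(ref, depth = 0), "depth")
  expect_error(simulate_nuclei_bins(ref, n_bins = 0), "bin")
  prof <- simulate_nuclei_bins(ref, NULL, n_nuclei = 23, depth = 500,
                               n_bins = 1000, seed = 4)
  expect_equal(nrow(prof$counts), 23L)
  r <- normalize_bins(prof$counts[1, ], prof$bulk)
  expect_lt(abs(mean(r, na.rm = TRUE)), 0.02)
  # a 10-bin gain at ratio 5/4 sits near log2(1.25)
  bw <- prof$bins$end[1] - prof$bins$start[1]
  tr <- data.frame(nucleus = 1, chrom = prof$bins$chrom[1],
                   start = 20 * bw, end = 30 * bw, ratio = 1.25)
  prof2 <- simulate_nuclei_bins(ref, tr, n_nuclei = 2, depth = 2000,
                                n_bins = 1000, seed = 5)
  r2 <- normalize_bins(prof2$counts[1, ], prof2$bulk)
  expect_lt(abs(mean(r2[21:30]) - log2(1.25)), 0.05)
})

test_that("expression simulation recovers programmed fold changes", {
  cfg <- small_cfg(seed = 23)
  ref <- build_reference(cfg)
  expect_error(simulate_counts(ref, reps = 0, cfg = cfg), "reps")
  expect_error(simulate_counts(ref, list(Late = c(NOPE = 2)), cfg = cfg),
               "unknown gene")
  # all folds 1: Early->Late folds stay inside the sampling envelope the
  # generator's own parameters predict (per-sample CV^2 = 1/mu + 1/size,
  # two stage means of `reps` samples each), and the bulk of genes sit
  # within a tight interval around 1
  em <- simulate_counts(ref, reps = 3, cfg = cfg,
                        base_meanlog = log(100), base_sdlog = 0)
  fc <- stage_fold_changes(em, "Early", "Late", top_k = 10)
  ratio <- 2^fc$table$log2_fc
  sigma <- sqrt(2 * (1 / 100 + 1 / cfg$nb_size) / 3) / log(2)
  expect_lt(max(abs(fc$table$log2_fc)), 4.5 * sigma)
  expect_gte(mean(ratio > 0.8 & ratio < 1.25), 0.95)
  expect_lt(abs(mean(fc$table$log2_fc)), 3 * sigma / sqrt(nrow(fc$table)))
  # a programmed 8.6x gene ranks first by |log2 FC|
  g <- ref$annotation$genes$gene_id[7]
  em2 <- simulate_counts(ref, stats::setNames(list(stats::setNames(8.6, g)),
                                              "Late"),
                         reps = 3, cfg = cfg)
  fc2 <- stage_fold_changes(em2, "Early", "Late", top_k = 5)
  expect_equal(fc2$top[1], g)
})
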