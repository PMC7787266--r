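# shared small simulated dataset for caller tests (built once per run)
fc_env <- new.env()
fc_dataset <- function() {
  if (is.null(fc_env$data)) {
    cfg <- small_cfg(seed = 41, coverage = 12)
    ref <- build_reference(cfg)
    sim <- simulate_fusions(ref, cfg, 120)
    amps <- telocrisis:::render_amplicons(sim$truth, sim$ref)
    reads <- telocrisis:::with_seed(derive_seed(cfg$seed, "reads"),
                                    generate_reads(amps, cfg))
    fc_env$data <- list(cfg = cfg, ref = ref, sim = sim, reads = reads)
  }
  fc_env$data
}

test_that("reads mapping wholly inside one reference yield no call", {
  d <- fc_dataset()
  sub <- d$sim$ref$subtel_seqs[["17p"]]
  rd <- c(inside = substr(sub, 501, 750))
  sas <- split_align(rd, d$sim$ref)
  expect_length(sas, 0)
  expect_equal(attr(sas, "mapped")$ref, "17p")
  expect_error(split_align(rd, list(subtel_seqs = character(0))), "empty")
  expect_error(split_align(rd, d$sim$ref, k = 5), "k")
})

test_that("synthetic junction-spanning reads resolve at the true junction
          and tolerate substitutions up to max_mismatch", {
  d <- fc_dataset()
  f <- d$sim$truth[d$sim$truth$category == "genomic", ][1, ]
  amp <- render_amplicon(f, d$sim$ref)
  st <- d$sim$ref$subtelomeres[d$sim$ref$subtelomeres$end_id == f$end_a, ]
  jpos <- f$bp_a - st$primer_offset # junction offset inside the amplicon
  rd <- c(j1 = substr(amp, jpos - 119, jpos + 130))
  sas <- split_align(rd, d$sim$ref)
  expect_length(sas, 1)
  r <- resolve_junction(sas[[1]], d$sim$ref)
  expect_true(abs(r$bp_a - f$bp_a) <= f$mh_bp)
  expect_equal(sas[[1]]$b_ref, f$chrom_b)
  # one substitution mid-segment: still resolved with max_mismatch = 2
  rd_err <- rd
  substr(rd_err, 60, 60) <- setdiff(c("A", "C", "G", "T"),
                                    substr(rd_err, 60, 60))[1]
  sas2 <- split_align(rd_err, d$sim$ref, max_mismatch = 2L)
  expect_length(sas2, 1)
})

test_that("raising max_mismatch never loses recovered calls", {
  d <- fc_dataset()
  cfg_err <- small_cfg(seed = 41, coverage = 12, error_rate = 0.005)
  sub <- d$sim$truth[1:40, ]
  amps <- telocrisis:::render_amplicons(sub, d$sim$ref)
  reads <- telocrisis:::with_seed(7, generate_reads(amps, cfg_err))
  idx <- telocrisis:::kmer_index(d$sim$ref)
  n_events <- vapply(0:2, function(m) {
    calls <- call_fusions(reads, d$sim$ref, max_mismatch = m, idx = idx)
    nrow(calls[calls$resolution == "base", ])
  }, numeric(1))
  expect_true(all(diff(n_events) >= 0))
})

test_that("end-to-end calling recovers simulated events with exact
          junction metrics", {
  d <- fc_dataset()
  calls <- call_fusions(d$reads, d$sim$ref)
  base <- calls[calls$resolution == "base", ]
  rec <- recovery_rate(base, d$sim$truth, d$sim$ref)
  expect_gte(rec, 0.99)
  tr <- telocrisis:::canonicalize_calls(d$sim$truth, d$sim$ref)
  for (i in seq_len(nrow(tr))) {
    j <- which(base$end_a == tr$end_a[i] & base$chrom_b == tr$chrom_b[i] &
                 abs(base$bp_a - tr$bp_a[i]) <= 5 &
                 abs(base$bp_b - tr$bp_b[i]) <= 5)[1]
    if (is.na(j)) next
    expect_equal(base$category[j], tr$category[i], info = tr$id[i])
    expect_equal(base$mh_bp[j], tr$mh_bp[i], info = tr$id[i])
    expect_equal(nchar(base$ins_seq[j]), nchar(tr$ins_seq[i]),
                 info = tr$id[i])
  }
})

test_that("deletion metrics measure sequence lost to the telomere
          boundary", {
  d <- fc_dataset()
  st <- d$ref$subtelomeres[1, ]
  expect_equal(compute_deletion(st$telomere_boundary, st), 0L)
  expect_equal(compute_deletion(st$telomere_boundary - 1200L, st), 1200L)
  expect_error(compute_deletion(st$telomere_boundary + 1L, st), "boundary")
  expect_error(compute_deletion(st$primer_offset, st), "primer")
  expect_equal(delta_deletion(1200, 3400), 2200L)
  # symmetry over random pairs
  set.seed(2)
  d1 <- sample(0:5000, 50); d2 <- sample(0:5000, 50)
  expect_equal(delta_deletion(d1, d2), delta_deletion(d2, d1))
  # truth-level delta arithmetic
  intra <- d$sim$truth[d$sim$truth$category == "intra", ]
  expect_equal(intra$delta_del, abs(intra$del_a - intra$del_b))
})

test_that("deduplication merges events within tolerance and conserves
          support", {
  one <- data.frame(sample = "S1", stage = "Deep", category = "genomic",
                    end_a = "17p", bp_a = 1000L, chrom_b = "chr1",
                    strand_b = "+", bp_b = 5000L, mh_bp = 2L, ins_seq = "",
                    ins_templated = NA_character_, del_a = 100L,
                    del_b = NA_integer_, delta_del = NA_integer_,
                    support = 1L, resolution = "base",
                    stringsAsFactors = FALSE)
  two <- rbind(one, one)
  out <- dedupe_calls(two)
  expect_equal(nrow(out), 1L)
  expect_equal(out$support, 2L)
  # 3 bp apart with tol 5: merged; 8 bp apart: not
  shifted <- one; shifted$bp_a <- 1003L; shifted$bp_b <- 5003L
  expect_equal(nrow(dedupe_calls(rbind(one, shifted), tol = 5L)), 1L)
  far <- one; far$bp_a <- 1008L
  expect_equal(nrow(dedupe_calls(rbind(one, far), tol = 5L)), 2L)
  # different partner chromosomes never merge
  other <- one; other$chrom_b <- "chr2"
  expect_equal(nrow(dedupe_calls(rbind(one, other))), 2L)
  # event count never increases, support is conserved
  set.seed(9)
  many <- one[rep(1, 40), ]
  many$bp_a <- many$bp_a + sample(0:30, 40, replace = TRUE)
  many$bp_b <- many$bp_b + sample(0:30, 40, replace = TRUE)
  out <- dedupe_calls(many)
  expect_lte(nrow(out), 40)
  expect_equal(sum(out$support), 40L)
})

test_that("junction histograms conserve counts over subtelomere bins", {
  d <- fc_dataset()
  calls <- data.frame(end_a = "17p",
                      bp_a = c(450L, 455L, 1200L), resolution = "base",
                      stringsAsFactors = FALSE)
  h <- junction_histogram(calls, d$ref, "17p", bin = 100L)
  expect_equal(sum(h$count), 3L)
  expect_equal(h$start[1], d$ref$subtelomeres$primer_offset[1])
  h0 <- junction_histogram(calls[0, ], d$ref, "XpYp")
  expect_true(all(h0$count == 0))
  expect_error(junction_histogram(calls, d$ref, "17p", bin = 0), "bin")
  # all calls at one coordinate occupy a single bin
  calls1 <- data.frame(end_a = "17p", bp_a = rep(777L, 5),
                       resolution = "base", stringsAsFactors = FALSE)
  h1 <- junction_histogram(calls1, d$ref, "17p")
  expect_equal(sum(h1$count > 0), 1L)
})

test_that("junction summaries aggregate MH, INS and class proportions by
          group", {
  expect_error(summarize_junctions(telocrisis:::empty_calls()), "no calls")
  one <- data.frame(sample = "S1", stage = "Early", category = "intra",
                    end_a = "17p", bp_a = 1L, chrom_b = "17p",
                    strand_b = "-", bp_b = 2L, mh_bp = 4L, ins_seq = "",
                    ins_templated = NA_character_, del_a = 1L, del_b = 1L,
                    delta_del = 0L, support = 1L, resolution = "base",
                    stringsAsFactors = FALSE)
  s <- summarize_junctions(one)
  expect_equal(s$mean_mh, 4)
  expect_equal(s$prop_intra, 1)
  # cohorts with different programmed MH means: ratio recovered within 10%
  # (full-size subtelomeres so junction-window congestion stays low)
  cfg_e <- sim_config(seed = 61, n_chroms = 2L,
                      chrom_lengths = c(60000L, 60000L), mh_mean = 3,
                      ins_prob = 0)
  cfg_l <- sim_config(seed = 62, n_chroms = 2L,
                      chrom_lengths = c(60000L, 60000L), mh_mean = 2,
                      ins_prob = 0)
  ref <- build_reference(cfg_e)
  te <- simulate_fusions(ref, cfg_e, 2000)$truth
  tl <- simulate_fusions(ref, cfg_l, 2000)$truth
  te$stage <- "Early"; tl$stage <- "Late"
  both <- rbind(te, tl)
  both$sample <- "S1"; both$resolution <- "base"
  s2 <- summarize_junctions(both)
  ratio <- s2$mean_mh[s2$group == "Early"] / s2$mean_mh[s2$group == "Late"]
  p3 <- 1 / 4; p2 <- 1 / 3 # truncated-geometric means for mh_mean 3 and 2
  m3 <- sum((0:12) * c(stats::dgeom(0:11, p3),
                       stats::pgeom(11, p3, lower.tail = FALSE)))
  m2 <- sum((0:12) * c(stats::dgeom(0:11, p2),
                       stats::pgeom(11, p2, lower.tail = FALSE)))
  expect_lt(abs(ratio - m3 / m2) / (m3 / m2), 0.1)
  # class proportions sum to 1 per group
  expect_true(all(abs(s2$prop_genomic + s2$prop_intra + s2$prop_inter - 1)
                  < 1e-12))
  # groups without base-resolution calls are dropped with a warning
  iv <- one; iv$stage <- "Deep"; iv$resolution <- "interval"
  expect_warning(summarize_junctions(rbind(one, iv)), "Deep")
})

test_that("fusion frequency per diploid genome follows the input-mass
          conversion", {
  expect_equal(fusion_frequency_per_genome(0, 50), 0)
  expect_equal(fusion_frequency_per_genome(1, 0.0066), 1)
  expect_equal(fusion_frequency_per_genome(3, 50), 3 / (50 * 1000 / 6.6))
  expect_lt(abs(fusion_frequency_per_genome(3, 50) - 3.96e-4), 1e-6)
  expect_error(fusion_frequency_per_genome(3, 0), "input_ng")
})

test_that("discordant mate pairs alone produce interval-resolution calls", {
  d <- fc_dataset()
  f <- d$sim$truth[d$sim$truth$category == "genomic", ][2, ]
  amp <- render_amplicon(f, d$sim$ref)
  st <- d$sim$ref$subtelomeres[d$sim$ref$subtelomeres$end_id == f$end_a, ]
  jpos <- f$bp_a - st$primer_offset
  # r1 fully subtelomeric, r2 fully in the partner: junction never read
  reads <- list(r1 = stats::setNames(substr(amp, jpos - 260, jpos - 11),
                                     "pair1"),
                r2 = stats::setNames(revcomp(substr(amp, jpos + 11,
                                                    jpos + 260)), "pair1"))
  calls <- call_fusions(reads, d$sim$ref)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$resolution, "interval")
  expect_true(is.na(calls$mh_bp))
  expect_equal(calls$end_a, f$end_a)
  expect_equal(calls$chrom_b, f$chrom_b)
})
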