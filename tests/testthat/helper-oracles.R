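# Independent oracles used across the suite. These deliberately use naive
# enumeration / per-character loops, not the package's closed forms.

# internal utility used throughout the tests
revcomp <- function(x) telocrisis:::revcomp(x)

# Brute-force split-placement oracle: for every split position i of `read`,
# check that read[1..i] perfectly matches refA starting at a_start1 and
# read[(i+1)..n] perfectly matches refB ending at b_end1 (both 1-based).
# Returns the number of valid placements, the MH width (max - min valid
# split), the leftmost split, and for the no-placement case the maximal
# unexplained middle (per-character flank scan).
oracle_split <- function(read, refA, a_start1, refB, b_end1) {
  n <- nchar(read)
  rc <- strsplit(read, "")[[1]]
  ca <- strsplit(refA, "")[[1]]
  cb <- strsplit(refB, "")[[1]]
  valid <- integer(0)
  for (i in 0:n) {
    ok_a <- TRUE
    if (i > 0) {
      idx <- a_start1 + seq_len(i) - 1L
      if (max(idx) > length(ca) || any(rc[seq_len(i)] != ca[idx]))
        ok_a <- FALSE
    }
    ok_b <- TRUE
    if (ok_a && i < n) {
      m <- n - i
      idx <- b_end1 - m + seq_len(m)
      if (min(idx) < 1L || any(rc[(i + 1):n] != cb[idx])) ok_b <- FALSE
    }
    if (ok_a && ok_b) valid <- c(valid, i)
  }
  if (length(valid) > 0) {
    list(n_valid = length(valid), mh = max(valid) - min(valid),
         leftmost = min(valid), ins = "")
  } else {
    a <- 0L
    while (a < n && a_start1 + a <= length(ca) &&
           rc[a + 1] == ca[a_start1 + a]) a <- a + 1L
    s <- 0L
    while (s < n && b_end1 - s >= 1L && rc[n - s] == cb[b_end1 - s])
      s <- s + 1L
    list(n_valid = 0L, mh = 0L, leftmost = a,
         ins = paste(rc[(a + 1):(n - s)], collapse = ""))
  }
}

# random junction for oracle-equivalence tests: two unrelated flanks with a
# junction that may carry engineered microhomology or an insertion
random_junction_case <- function() {
  refA <- random_dna_str(280)
  refB <- random_dna_str(280)
  a_len <- sample(30:120, 1)
  b_len <- sample(30:120, 1)
  a_start1 <- sample(1:40, 1)
  b_end1 <- 280 - sample(0:40, 1)
  a_part <- substr(refA, a_start1, a_start1 + a_len - 1)
  b_part <- substr(refB, b_end1 - b_len + 1, b_end1)
  kind <- sample(c("plain", "mh", "ins"), 1)
  mid <- ""
  if (kind == "mh") {
    # copy a few bases of refA's continuation into refB's lead-in region;
    # the realised MH is whatever enumeration finds
    k <- sample(1:6, 1)
    substr(refB, b_end1 - b_len - k + 1, b_end1 - b_len) <-
      substr(refA, a_start1 + a_len, a_start1 + a_len + k - 1)
    b_part <- substr(refB, b_end1 - b_len + 1, b_end1)
  } else if (kind == "ins") {
    mid <- random_dna_str(sample(1:8, 1))
  }
  list(read = paste0(a_part, mid, b_part), refA = refA, refB = refB,
       a_start1 = a_start1, b_end1 = b_end1)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# wrap plain flank strings into the reference shape resolve_junction expects
toy_refs <- function(refA, refB) {
  list(subtel_seqs = c(A = refA), minigenome = c(B = refB),
       subtelomeres = data.frame(end_id = "A", family_id = "A",
                                 archetype = TRUE, targeted = TRUE,
                                 primer_offset = 0L,
                                 telomere_boundary = nchar(refA),
                                 ltr_start = 0L, ltr_end = 0L,
                                 stringsAsFactors = FALSE))
}

# resolve a junction-spanning sequence given perfect anchors
resolve_with_anchors <- function(read, refA, a_start1, refB, b_end1) {
  sa <- list(read = read, a_end = "A", a_pos0 = a_start1 - 1L,
             b_ref = "B", b_strand = "+", b_last0 = b_end1 - 1L)
  resolve_junction(sa, toy_refs(refA, refB))
}

# independent log-space Fisher oracle (strict enumeration with the classic
# relative tie slack); distinct code path from the package's integer route
oracle_fisher <- function(tab) {
  tab <- as.matrix(tab)
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  lw <- stats::dhyper(xs, r1, r2, c1, log = TRUE)
  lobs <- lw[xs == tab[1, 1]]
  sum(exp(lw[lw <= lobs + 1e-9])) / sum(exp(lw))
}

# shared small simulation config for fast tests
small_cfg <- function(seed = 11, ...) {
  sim_config(seed = seed, n_chroms = 2L, chrom_lengths = c(60000L, 60000L),
             subtel_length = 3000L, telomere_boundary = 2700L,
             deletion_range = c(0L, 2400L),
             partner_len_range = c(400L, 900L), ...)
}
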