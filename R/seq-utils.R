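DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' @importFrom Biostrings DNAString reverseComplement
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# a base different from each element of `not` (vectorised over positions)
other_base <- function(not) {
  vapply(not, function(b) {
    pool <- setdiff(DNA_BASES, b)
    pool[sample.int(3L, 1L)]
  }, character(1), USE.NAMES = FALSE)
}

comp_base <- function(b) unname(c(A = "T", C = "G", G = "C", T = "A")[b])

# longest common prefix of s1[i1...] and s2[i2...] (1-based), exact matching,
# compared block-wise so long extensions stay cheap.
lcp_len <- function(s1, i1, s2, i2, maxlen = .Machine$integer.max) {
  n1 <- nchar(s1); n2 <- nchar(s2)
  lim <- min(n1 - i1 + 1L, n2 - i2 + 1L, maxlen)
  if (lim <= 0L) return(0L)
  len <- 0L
  block <- 64L
  while (len < lim) {
    w <- min(block, lim - len)
    a <- substr(s1, i1 + len, i1 + len + w - 1L)
    b <- substr(s2, i2 + len, i2 + len + w - 1L)
    if (a == b) {
      len <- len + w
    } else {
      ca <- strsplit(a, "", fixed = TRUE)[[1]]
      cb <- strsplit(b, "", fixed = TRUE)[[1]]
      len <- len + (which(ca != cb)[1] - 1L)
      break
    }
  }
  as.integer(len)
}

# longest common suffix of s1[...j1] and s2[...j2] (1-based inclusive ends)
lcs_len <- function(s1, j1, s2, j2, maxlen = .Machine$integer.max) {
  lim <- min(j1, j2, maxlen)
  if (lim <= 0L) return(0L)
  len <- 0L
  block <- 64L
  while (len < lim) {
    w <- min(block, lim - len)
    a <- substr(s1, j1 - len - w + 1L, j1 - len)
    b <- substr(s2, j2 - len - w + 1L, j2 - len)
    if (a == b) {
      len <- len + w
    } else {
      ca <- rev(strsplit(a, "", fixed = TRUE)[[1]])
      cb <- rev(strsplit(b, "", fixed = TRUE)[[1]])
      len <- len + (which(ca != cb)[1] - 1L)
      break
    }
  }
  as.integer(len)
}

# forward extension allowing up to max_mm mismatches; returns matched length
lcp_mm <- function(s1, i1, s2, i2, max_mm = 0L, maxlen = .Machine$integer.max) {
  len <- 0L
  mm <- 0L
  repeat {
    step <- lcp_len(s1, i1 + len, s2, i2 + len, maxlen - len)
    len <- len + step
    n1 <- nchar(s1); n2 <- nchar(s2)
    if (len >= maxlen || i1 + len > n1 || i2 + len > n2) break
    if (mm >= max_mm) break
    mm <- mm + 1L
    len <- len + 1L # absorb one mismatch
  }
  as.integer(min(len, maxlen))
}

lcs_mm <- function(s1, j1, s2, j2, max_mm = 0L, maxlen = .Machine$integer.max) {
  len <- 0L
  mm <- 0L
  repeat {
    step <- lcs_len(s1, j1 - len, s2, j2 - len, maxlen - len)
    len <- len + step
    if (len >= maxlen || j1 - len < 1L || j2 - len < 1L) break
    if (mm >= max_mm) break
    mm <- mm + 1L
    len <- len + 1L
  }
  as.integer(min(len, maxlen))
}
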