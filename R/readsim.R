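#' Simulate paired-end reads from fusion amplicons
#'
#' Fragments are drawn per amplicon at a mean depth of `cfg$coverage`
#' (`n_pairs = round(coverage * L / frag_mean)`, at least one), with lengths
#' Normal(`frag_mean`, `frag_sd`) truncated to `[read_len, L]` and uniform
#' start positions; mate 1 is the fragment 5' end, mate 2 the reverse
#' complement of its 3' end. Substitution errors are applied per base at
#' `cfg$error_rate`. Amplicons shorter than `read_len` are skipped with a
#' warning and their count is reported in the `n_skipped` attribute.
#'
#' @param amplicons named character vector of amplicon sequences.
#' @param cfg a [sim_config()].
#' @return list with `r1` and `r2`, named character vectors of read
#'   sequences (names are `ampliconid:p<i>`), plus attribute `n_skipped`.
#' @export
generate_reads <- function(amplicons, cfg) {
  if (length(amplicons) == 0) stop("amplicons must be non-empty")
  lens <- nchar(amplicons)
  skip <- lens < cfg$read_len
  if (any(skip)) {
    warning(sum(skip), " amplicon(s) shorter than read_len skipped")
  }
  keep <- which(!skip)
  r1 <- list(); r2 <- list(); ids <- list()
  for (j in seq_along(keep)) {
    i <- keep[j]
    L <- lens[i]
    amp <- amplicons[[i]]
    n_pairs <- max(1L, as.integer(round(cfg$coverage * L / cfg$frag_mean)))
    fl <- as.integer(round(stats::rnorm(n_pairs, cfg$frag_mean, cfg$frag_sd)))
    fl <- pmin(pmax(fl, cfg$read_len), L)
    st <- vapply(L - fl + 1L, function(m) sample.int(m, 1L), integer(1))
    r1[[j]] <- substring(amp, st, st + cfg$read_len - 1L)
    r2[[j]] <- substring(amp, st + fl - cfg$read_len, st + fl - 1L)
    ids[[j]] <- sprintf("%s:p%04d", names(amplicons)[i], seq_len(n_pairs))
  }
  r1 <- unlist(r1); r2 <- unlist(r2); ids <- unlist(ids)
  # mate 2 is sequenced off the opposite strand
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(r2)))
  if (cfg$error_rate > 0) {
    r1 <- apply_errors(r1, cfg$error_rate)
    r2 <- apply_errors(r2, cfg$error_rate)
  }
  names(r1) <- ids
  names(r2) <- ids
  structure(list(r1 = r1, r2 = r2), n_skipped = sum(skip))
}

apply_errors <- function(reads, rate) {
  n_err <- stats::rbinom(length(reads), nchar(reads), rate)
  hit <- which(n_err > 0)
  for (i in hit) {
    pos <- sample.int(nchar(reads[i]), n_err[i])
    s <- reads[i]
    for (p in pos) {
      substr(s, p, p) <- other_base(substr(s, p, p))
    }
    reads[i] <- s
  }
  reads
}

#' Write a paired read set as FASTQ files
#'
#' @param reads list with `r1`, `r2` from [generate_reads()].
#' @param prefix output path prefix; writes `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq`.
#' @return invisibly, the two file paths.
#' @export
write_fastq_pair <- function(reads, prefix) {
  paths <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  for (m in 1:2) {
    v <- reads[[m]]
    dss <- Biostrings::DNAStringSet(v)
    names(dss) <- names(v)
    qual <- Biostrings::PhredQuality(
      vapply(nchar(v), function(n) strrep("I", n), character(1)))
    q <- Biostrings::QualityScaledDNAStringSet(dss, qual)
    Biostrings::writeQualityScaledXStringSet(q, paths[m])
  }
  invisible(paths)
}

#' Read a paired FASTQ read set
#' @param r1_path,r2_path FASTQ paths.
#' @return list with `r1`, `r2` named character vectors.
#' @export
read_fastq_pair <- function(r1_path, r2_path) {
  rd <- function(p) {
    x <- Biostrings::readDNAStringSet(p, format = "fastq")
    out <- as.character(x)
    names(out) <- sub(" .*", "", names(x))
    out
  }
  list(r1 = rd(r1_path), r2 = rd(r2_path))
}
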