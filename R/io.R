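#' Read an annotation track from BED or GFF3
#'
#' BED is parsed as 0-based half-open, GFF3 as 1-based closed; both are
#' returned on the package's internal convention (a `GRanges`, 1-based
#' closed as usual for Bioconductor containers) with strand preserved.
#' Malformed lines raise an error naming the line number; an empty file
#' returns an empty track with a warning.
#'
#' @param path file path.
#' @param format `"BED"` or `"GFF3"` (default guessed from the extension).
#' @return a `GRanges` (with `name` metadata when present).
#' @export
read_annotation <- function(path, format = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "GFF3" else
      "BED"
  }
  format <- match.arg(toupper(format), c("BED", "GFF3"))
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty annotation file: ", path)
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "BED") {
    bad <- which(vapply(fields, length, integer(1)) < 3L)
    if (length(bad) > 0)
      stop("malformed BED line ", bad[1], " in ", path)
    chrom <- vapply(fields, `[`, character(1), 1L)
    start <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2L)))
    end <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3L)))
    bad <- which(is.na(start) | is.na(end) | start < 0 | end < start)
    if (length(bad) > 0)
      stop("malformed BED line ", bad[1], " in ", path)
    nm <- vapply(fields, function(f) if (length(f) >= 4L) f[4L] else NA_character_,
                 character(1))
    strand <- vapply(fields, function(f) if (length(f) >= 6L) f[6L] else "*",
                     character(1))
    strand[!strand %in% c("+", "-")] <- "*"
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(start = start + 1L,
                                                  end = pmax(end, start + 1L)),
                                 strand = strand)
    if (any(!is.na(nm))) gr$name <- nm
    gr
  } else {
    bad <- which(vapply(fields, length, integer(1)) < 9L)
    if (length(bad) > 0)
      stop("malformed GFF3 line ", bad[1], " in ", path)
    chrom <- vapply(fields, `[`, character(1), 1L)
    type <- vapply(fields, `[`, character(1), 3L)
    start <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 4L)))
    end <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 5L)))
    bad <- which(is.na(start) | is.na(end) | start < 1 | end < start)
    if (length(bad) > 0)
      stop("malformed GFF3 line ", bad[1], " in ", path)
    strand <- vapply(fields, `[`, character(1), 7L)
    strand[!strand %in% c("+", "-")] <- "*"
    gr <- GenomicRanges::GRanges(chrom,
                                 IRanges::IRanges(start = start, end = end),
                                 strand = strand)
    gr$name <- type
    gr
  }
}

#' Write fusion calls as TSV or BED
#'
#' TSV carries every call column and round-trips through [read_calls()];
#' BED carries one width-1 junction-point interval per base-resolution
#' call (0-based half-open), named by event, for karyotype display.
#'
#' @param calls a `fusion_calls` data frame.
#' @param path output path.
#' @param format `"TSV"` or `"BED"`.
#' @return invisibly, `path`.
#' @export
write_calls <- function(calls, path, format = c("TSV", "BED")) {
  format <- match.arg(format)
  if (format == "TSV") {
    utils::write.table(calls, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    sel <- !is.na(calls$bp_b) & calls$chrom_b != ""
    sub <- calls[sel, , drop = FALSE]
    bed <- data.frame(chrom = sub$chrom_b, start = sub$bp_b,
                      end = sub$bp_b + 1L,
                      name = sprintf("%s_%s_%06d", sub$sample, sub$category,
                                     seq_len(nrow(sub))))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read fusion calls written by [write_calls()]
#' @param path TSV path.
#' @return a `fusion_calls` data frame.
#' @export
read_calls <- function(path) {
  classes <- c(sample = "character", stage = "character",
               category = "character", end_a = "character",
               bp_a = "integer", chrom_b = "character",
               strand_b = "character", bp_b = "integer",
               mh_bp = "integer", ins_seq = "character",
               ins_templated = "character", del_a = "integer",
               del_b = "integer", delta_del = "integer",
               support = "integer", resolution = "character")
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA",
                          colClasses = classes)
  df$ins_seq[is.na(df$ins_seq)] <- ""
  df
}

#' Write a reference as FASTA plus a subtelomere metadata sidecar
#'
#' @param ref a `synthetic_reference`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- Biostrings::DNAStringSet(ref$minigenome)
  Biostrings::writeXStringSet(g, file.path(dir, "genome.fa"))
  s <- Biostrings::DNAStringSet(ref$subtel_seqs)
  Biostrings::writeXStringSet(s, file.path(dir, "subtel.fa"))
  utils::write.table(ref$subtelomeres, file.path(dir, "subtel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(ref$annotation)) {
    gr <- ref$annotation[[nm]]
    if (length(gr) == 0) next
    bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr))
    if (!is.null(gr$gene_id)) bed$name <- gr$gene_id
    utils::write.table(bed, file.path(dir, paste0(nm, ".bed")), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Load a reference written by [write_reference()]
#' @param dir directory holding `genome.fa`, `subtel.fa`, `subtel.tsv` and
#'   track BED files.
#' @return a `synthetic_reference`.
#' @export
read_reference <- function(dir) {
  g <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  s <- Biostrings::readDNAStringSet(file.path(dir, "subtel.fa"))
  ends <- utils::read.table(file.path(dir, "subtel.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  ann <- list()
  for (nm in c("genes", "exons", "promoters", "enhancers", "fragile",
               "ltr")) {
    p <- file.path(dir, paste0(nm, ".bed"))
    ann[[nm]] <- if (file.exists(p)) read_annotation(p, "BED") else
      GenomicRanges::GRanges()
    if (nm == "genes" && length(ann[[nm]]) > 0 && !is.null(ann[[nm]]$name)) {
      ann[[nm]]$gene_id <- ann[[nm]]$name
    }
  }
  ref <- list(minigenome = stats::setNames(as.character(g), names(g)),
              subtelomeres = ends,
              subtel_seqs = stats::setNames(as.character(s), names(s)),
              annotation = ann, seed = NA_integer_)
  class(ref) <- "synthetic_reference"
  ref
}
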