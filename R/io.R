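# Standard-format I/O. FASTA goes through Biostrings; FASTQ uses a small
# vectorised reader so malformed records can be reported by record index
# (the quality filter's error contract). All tabular outputs are TSV with
# headers, written/read with readr.

#' Read a FASTQ file into a tibble
#'
#' Expects Sanger PHRED+33 encoding. Malformed records (missing `@`/`+`
#' markers, sequence/quality length disagreement, truncated final record)
#' raise an error naming the 1-based record index.
#'
#' @param path FASTQ file path (may be gzipped).
#' @return A tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) {
    stop(sprintf("malformed FASTQ '%s': truncated record %d", path,
                 length(lines) %/% 4L + 1L), call. = FALSE)
  }
  n <- length(lines) %/% 4L
  if (n == 0L) return(tibble(id = character(), seq = character(), qual = character()))
  hd <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- lines[seq(2L, by = 4L, length.out = n)]
  pl <- lines[seq(3L, by = 4L, length.out = n)]
  ql <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hd, "@") | !startsWith(pl, "+") | nchar(sq) != nchar(ql))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ '%s': record %d", path, bad[1]), call. = FALSE)
  }
  tibble(id = sub("^@", "", hd), seq = toupper(sq), qual = ql)
}

#' Write a read tibble as FASTQ
#'
#' @param reads Tibble with `id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  out <- character(4L * nrow(reads))
  out[seq(1L, by = 4L, length.out = nrow(reads))] <- paste0("@", reads$id)
  out[seq(2L, by = 4L, length.out = nrow(reads))] <- reads$seq
  out[seq(3L, by = 4L, length.out = nrow(reads))] <- "+"
  out[seq(4L, by = 4L, length.out = nrow(reads))] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

#' Read/write FASTA as a tibble
#'
#' Thin wrappers around Biostrings; sequences are returned upper case.
#'
#' @param path File path.
#' @return `read_fasta()`: tibble with `name`, `seq`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  tibble(name = names(x), seq = toupper(as.character(x)))
}

#' @rdname read_fasta
#' @param seqs Tibble with `name`, `seq` (or a named character vector).
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- tibble(name = names(seqs), seq = unname(seqs))
  x <- Biostrings::BStringSet(setNames(seqs$seq, seqs$name))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write collapsed tags as FASTA with `>id_xCOUNT` headers
#'
#' The header convention (`>t000001_x532`) carries the copy number of each
#' unique tag, as used by common miRNA-discovery tools.
#'
#' @param tags Tibble with `tag_id`, `seq`, `count`.
#' @param path Output path.
#' @export
write_tags_fasta <- function(tags, path) {
  write_fasta(tibble(name = sprintf("%s_x%d", tags$tag_id, tags$count),
                     seq = tags$seq), path)
}

#' Write genome hits as BED6
#'
#' 0-based half-open intervals; `score` holds the tag copy number; strand in
#' column 6.
#'
#' @param hits Tibble with `contig`, `start`, `end`, `tag_id`, `count`
#'   (optional), `strand`.
#' @param path Output path.
#' @export
write_bed <- function(hits, path) {
  bed <- tibble(
    chrom = hits$contig, start = hits$start, end = hits$end,
    name = hits$tag_id,
    score = if ("count" %in% names(hits)) hits$count else 0L,
    strand = hits$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  readr::read_tsv(path,
                  col_names = c("contig", "start", "end", "tag_id", "count",
                                "strand"),
                  col_types = "ciicic", progress = FALSE)
}
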