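# Small sequence utilities shared across modules. Sequences are plain upper-case
# character vectors; DNA on disk, RNA inside the folding/targeting code.

#' Convert between DNA and RNA alphabets
#'
#' Sequencers emit DNA; thermodynamic models work on RNA. These helpers map
#' T<->U (case-insensitively, returning upper case) and leave other letters
#' untouched.
#'
#' @param x Character vector of sequences.
#' @return Character vector of the same length.
#' @export
dna_to_rna <- function(x) chartr("tT", "uU", toupper(x))

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("uU", "tT", toupper(x))

#' Reverse complement
#'
#' Works for DNA or RNA input; the output alphabet follows the input (a
#' sequence containing U is complemented in RNA space).
#'
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  is_rna <- stringr::str_detect(x, "[Uu]")
  out <- chartr("ACGTUacgtu", "TGCAATGCAA", x)
  out[is_rna] <- chartr("ACGUacgu", "UGCAugca", x[is_rna])
  vapply(out, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Hamming distance between equal-length sequence vectors
#'
#' Vectorised position-by-position comparison; `x` and `y` are recycled to a
#' common length and every compared pair must have equal nchar.
#'
#' @param x,y Character vectors of sequences.
#' @return Integer vector of mismatch counts.
#' @export
hamming <- function(x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n)
  y <- rep_len(y, n)
  w <- unique(nchar(x))
  stopifnot(length(w) <= 1L, all(nchar(y) == nchar(x)))
  if (n == 0L) return(integer(0))
  mm <- integer(n)
  for (p in seq_len(w)) {
    mm <- mm + (substr(x, p, p) != substr(y, p, p))
  }
  mm
}

#' Random sequences over a given alphabet
#'
#' @param n Number of sequences.
#' @param len Length (scalar or vector recycled to `n`).
#' @param alphabet Character vector of letters to draw from.
#' @return Character vector of `n` sequences.
#' @export
random_seq <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  len <- rep_len(len, n)
  vapply(len, function(l) {
    paste(sample(alphabet, l, replace = TRUE), collapse = "")
  }, character(1))
}

assert_alphabet <- function(x, letters, what = "sequence") {
  bad <- stringr::str_detect(x, paste0("[^", paste(letters, collapse = ""), "]"))
  if (any(bad)) {
    stop(sprintf("invalid %s alphabet (expected only %s): %s",
                 what, paste(letters, collapse = ""),
                 paste(head(x[bad], 3), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# PHRED+33 mean quality per read (vectorised by grouping reads of equal length)
phred_mean <- function(qual) {
  out <- numeric(length(qual))
  w <- nchar(qual)
  for (len in unique(w)) {
    idx <- which(w == len)
    if (len == 0L) { out[idx] <- NA_real_; next }
    ints <- utf8ToInt(paste(qual[idx], collapse = "")) - 33L
    out[idx] <- colMeans(matrix(ints, nrow = len))
  }
  out
}
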