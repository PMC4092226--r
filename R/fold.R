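# Intramolecular folding: MFE structure prediction, hairpin diagnostics, and
# genomic context extension for precursor calling.

#' Minimum-free-energy RNA folding
#'
#' Computes the minimum-free-energy nested secondary structure of a sequence
#' under the bundled nearest-neighbour model ([energy_params()]): helix
#' stacking energies, affine hairpin/bulge/internal-loop penalties and a
#' linear multiloop score. G:U wobbles are allowed by default, pseudoknots and
#' dangling ends are not, and hairpin loops have at least 3 unpaired bases.
#' DNA input is converted to RNA (T to U) before folding. Ties between
#' co-optimal structures are broken by a fixed deterministic traceback order
#' (helix continuations before multiloops before hairpins).
#'
#' @param seq A single sequence (ACGU; T accepted and converted).
#' @param par Parameter list from [energy_params()].
#' @return An object of class `fold_result`: list with `seq` (RNA), `energy`
#'   (kcal/mol), `pairs` (two-column 0-based integer matrix, i < j) and
#'   `dotbracket`.
#' @seealso [fold_exhaustive()] for the enumeration reference, [hairpin_check()]
#' @examples
#' mfe_fold("GGGAAAACCC")
#' @export
mfe_fold <- function(seq, par = energy_params()) {
  stopifnot(length(seq) == 1L, nchar(seq) >= 1L)
  rna <- dna_to_rna(seq)
  assert_alphabet(rna, c("A", "C", "G", "U"), "RNA")
  if (nchar(rna) > 500L) stop("sequence longer than 500 nt; fold windows, not contigs")
  res <- fold_mfe_cpp(rna, par_to_engine(par))
  pairs <- res$pairs
  if (NROW(pairs) > 0L) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  structure(
    list(seq = rna, energy = res$energy, pairs = pairs,
         dotbracket = dotbracket(pairs, nchar(rna))),
    class = "fold_result"
  )
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$seq, "\n", sep = "")
  cat(sprintf("%s (%6.2f)\n", x$dotbracket, x$energy))
  invisible(x)
}

#' @export
format.fold_result <- function(x, ...) {
  sprintf("%s\n%s (%.2f)", x$seq, x$dotbracket, x$energy)
}

#' Dot-bracket string from a pair list
#'
#' @param pairs Two-column 0-based pair matrix.
#' @param n Sequence length.
#' @return A string of `(`, `)` and `.` of length `n`.
#' @export
dotbracket <- function(pairs, n) {
  db <- rep(".", n)
  if (NROW(pairs) > 0L) {
    db[pairs[, 1] + 1L] <- "("
    db[pairs[, 2] + 1L] <- ")"
  }
  paste(db, collapse = "")
}

# parent/children decomposition of a nested pair set; used by the hairpin
# diagnostics and the reference scorer
pair_children <- function(pairs) {
  if (NROW(pairs) == 0L) return(integer(0))
  o <- pairs[, 1]; cl <- pairs[, 2]
  vapply(seq_along(o), function(k) {
    cand <- which(o < o[k] & cl > cl[k])
    if (!length(cand)) 0L else cand[which.max(o[cand])]
  }, integer(1))
}

n_terminal_loops <- function(pairs) {
  if (NROW(pairs) == 0L) return(0L)
  parent <- pair_children(pairs)
  sum(!(seq_len(NROW(pairs)) %in% parent))
}

#' Stem-loop (hairpin) diagnostics for a folded precursor candidate
#'
#' Applies the precursor-calling criteria used for novel-miRNA prediction: the
#' structure must consist of exactly one stem-loop (a single terminal loop;
#' bulges and internal loops are allowed, multiloops and independent stems are
#' not), be at least as stable as `energy_max`, and carry the putative mature
#' sequence entirely on one arm (not spanning the terminal loop) with at least
#' `pair_min` of its bases paired.
#'
#' @param fold A `fold_result` from [mfe_fold()].
#' @param mature_span Integer length-2 vector: 1-based inclusive start/end of
#'   the mature sequence within `fold$seq`.
#' @param energy_max Maximum (most positive) admissible energy, kcal/mol
#'   (default -18).
#' @param pair_min Minimum fraction of mature bases paired (default 0.6).
#' @return A one-row tibble (`hairpin_verdict`): `is_hairpin`, `n_stems`,
#'   `mature_arm` ("5p"/"3p"/"none"), `mature_paired_frac`, `energy`.
#' @export
hairpin_check <- function(fold, mature_span, energy_max = -18, pair_min = 0.6) {
  stopifnot(inherits(fold, "fold_result"), length(mature_span) == 2L)
  n <- nchar(fold$seq)
  s0 <- as.integer(mature_span[1]) - 1L
  e0 <- as.integer(mature_span[2]) - 1L
  if (s0 < 0L || e0 >= n || s0 > e0) stop("mature_span outside sequence")
  pairs <- fold$pairs
  stems <- n_terminal_loops(pairs)

  arm <- "none"
  if (stems == 1L && NROW(pairs) > 0L) {
    inner <- which(!(seq_len(NROW(pairs)) %in% pair_children(pairs)))
    a <- pairs[inner, 1]; b <- pairs[inner, 2]
    if (e0 <= a) arm <- "5p" else if (s0 >= b) arm <- "3p"
  }
  paired_pos <- c(pairs[, 1], pairs[, 2])
  frac <- mean((s0:e0) %in% paired_pos)

  tibble(
    is_hairpin = stems == 1L && fold$energy <= energy_max &&
      arm %in% c("5p", "3p") && frac >= pair_min,
    n_stems = stems,
    mature_arm = arm,
    mature_paired_frac = frac,
    energy = fold$energy
  )
}

#' Extend a genome hit into precursor fold candidates
#'
#' Returns the mapped interval extended by `flank` nt in both directions plus
#' the two single-sided extensions, as strand-oriented candidate sequences for
#' precursor folding. Windows are truncated (and flagged) at contig ends.
#' Coordinates are 0-based half-open on the plus strand of the contig; for
#' minus-strand hits the returned sequence is reverse-complemented so the
#' mature read is always a forward substring.
#'
#' @param genome Named character vector of contig sequences (or a single
#'   unnamed sequence).
#' @param hit A list/one-row data frame with `contig`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`). `contig` may be omitted for a single-contig
#'   genome.
#' @param flank Extension width, nt (default 60).
#' @return A tibble with one row per candidate (`full`, `left`, `right`):
#'   window coordinates, oriented sequence, the 1-based `mature_start`/
#'   `mature_end` of the hit within the oriented window, and `truncated`.
#' @export
extend_context <- function(genome, hit, flank = 60L) {
  if (is.null(names(genome)) && length(genome) == 1L) names(genome) <- "contig"
  contig <- if (!is.null(hit$contig)) as.character(hit$contig) else names(genome)[1]
  if (!contig %in% names(genome)) stop("contig not found in genome: ", contig)
  cs <- genome[[contig]]
  clen <- nchar(cs)
  start <- as.integer(hit$start); end <- as.integer(hit$end)
  strand <- if (!is.null(hit$strand)) as.character(hit$strand) else "+"
  if (start < 0L || end > clen || start >= end) stop("hit outside genome bounds")

  win <- tibble(
    candidate = c("full", "left", "right"),
    wstart = c(start - flank, start - flank, start),
    wend   = c(end + flank, end, end + flank)
  )
  win <- win |>
    mutate(
      truncated = .data$wstart < 0L | .data$wend > clen,
      wstart = pmax(.data$wstart, 0L),
      wend = pmin(.data$wend, clen),
      seq = substr(rep(cs, 3L), .data$wstart + 1L, .data$wend),
      mature_start = start - .data$wstart + 1L,
      mature_end = end - .data$wstart
    )
  if (strand == "-") {
    win <- win |>
      mutate(
        seq = revcomp(.data$seq),
        ms = .data$wend - end + 1L,
        mature_end = .data$wend - start,
        mature_start = .data$ms
      ) |>
      select(-"ms")
  }
  win |> mutate(contig = contig, strand = strand)
}

# Excise, from a (possibly multi-stem) fold of an extended window, the
# stem-loop branch containing the mature span, refold it in isolation and
# apply the hairpin criteria. This mirrors how hairpin-based novel-miRNA
# predictors excise the candidate precursor from a larger folded context.
hairpin_in_context <- function(fold, mature_span, energy_max = -18,
                               pair_min = 0.6, par = energy_params()) {
  direct <- hairpin_check(fold, mature_span, energy_max, pair_min)
  if (direct$is_hairpin) {
    return(direct |> mutate(precursor_start = 1L,
                            precursor_end = nchar(fold$seq)))
  }
  pairs <- fold$pairs
  if (NROW(pairs) == 0L) {
    return(direct |> mutate(precursor_start = NA_integer_,
                            precursor_end = NA_integer_))
  }
  parent <- pair_children(pairs)
  # terminal loops per subtree
  kids <- split(seq_len(NROW(pairs)), parent[seq_len(NROW(pairs))])
  subtree_loops <- function(k) {
    ch <- which(parent == k)
    if (!length(ch)) return(1L)
    sum(vapply(ch, subtree_loops, integer(1)))
  }
  s0 <- mature_span[1] - 1L; e0 <- mature_span[2] - 1L
  cand <- which(pairs[, 1] <= s0 + 2L & pairs[, 2] >= e0 - 2L)
  cand <- cand[vapply(cand, subtree_loops, integer(1)) == 1L]
  if (!length(cand)) {
    return(direct |> mutate(precursor_start = NA_integer_,
                            precursor_end = NA_integer_))
  }
  k <- cand[which.max(pairs[cand, 2] - pairs[cand, 1])]
  i <- pairs[k, 1]; j <- pairs[k, 2]
  sub <- substr(fold$seq, i + 1L, j + 1L)
  subfold <- mfe_fold(sub, par)
  span <- c(max(mature_span[1] - i, 1L), min(mature_span[2] - i, nchar(sub)))
  hairpin_check(subfold, span, energy_max, pair_min) |>
    mutate(precursor_start = i + 1L, precursor_end = j + 1L)
}

#' Hairpin propensity of a genome locus
#'
#' Folds the flank-extended window around a genome hit (all three candidates
#' from [extend_context()]), excising the stem-loop branch that carries the
#' mapped sequence when the whole window folds into more than one stem, and
#' reports whether any candidate satisfies the precursor criteria.
#'
#' @inheritParams extend_context
#' @inheritParams hairpin_check
#' @param par Energy parameters.
#' @return A one-row tibble: `is_hairpin` plus the diagnostics of the best
#'   candidate (by passing, then lowest energy).
#' @export
hairpin_at_locus <- function(genome, hit, flank = 60L, energy_max = -18,
                             pair_min = 0.6, par = energy_params()) {
  cands <- extend_context(genome, hit, flank)
  verdicts <- list()
  for (r in seq_len(nrow(cands))) {
    if (cands$mature_end[r] - cands$mature_start[r] < 5L) next
    f <- mfe_fold(cands$seq[r], par)
    v <- hairpin_in_context(f, c(cands$mature_start[r], cands$mature_end[r]),
                            energy_max, pair_min, par) |>
      mutate(candidate = cands$candidate[r])
    if (v$is_hairpin) {
      return(v |> select("is_hairpin", "n_stems", "mature_arm",
                         "mature_paired_frac", "energy", "candidate"))
    }
    verdicts[[length(verdicts) + 1L]] <- v
  }
  if (!length(verdicts)) {
    return(tibble(is_hairpin = FALSE, n_stems = 0L, mature_arm = "none",
                  mature_paired_frac = 0, energy = 0, candidate = NA_character_))
  }
  bind_rows(verdicts) |>
    arrange(.data$energy) |>
    slice(1) |>
    select("is_hairpin", "n_stems", "mature_arm", "mature_paired_frac",
           "energy", "candidate")
}

#' Write folds as Vienna dot-bracket text
#'
#' @param folds A `fold_result` or list of them; names become record ids.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(folds, path) {
  if (inherits(folds, "fold_result")) folds <- list(fold = folds)
  ids <- names(folds) %||% paste0("fold", seq_along(folds))
  lines <- unlist(purrr::map2(folds, ids, function(f, id) {
    c(paste0(">", id), f$seq, sprintf("%s (%.2f)", f$dotbracket, f$energy))
  }))
  writeLines(lines, path)
  invisible(path)
}
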