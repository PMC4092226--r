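# Thermodynamic model used by the folding engine and the duplex scorer.
#
# The model is a deliberately compact nearest-neighbour scheme: a symmetric
# 6x6 helix stacking table over the canonical pair types (AU, UA, GC, CG, GU,
# UG) plus affine loop penalties (hairpin, bulge, internal, multiloop). There
# are no dangling ends, no coaxial stacks and no pseudoknots. All constants
# live in this file so the exhaustive reference scorer and the dynamic
# programs consume the identical parameterisation.

PAIR_TYPES <- c("AU", "UA", "GC", "CG", "GU", "UG")

# Stacking free energies (kcal/mol) for an outer pair (rows) directly enclosing
# an inner pair (columns). The matrix is symmetric, which makes the optimal
# energy of a Watson-Crick-only structure invariant under reverse complement.
.STACK <- matrix(c(
  # AU    UA    GC    CG    GU    UG
  -0.9, -1.1, -2.1, -2.2, -0.6, -1.4,  # AU
  -1.1, -1.3, -2.4, -2.1, -1.0, -1.3,  # UA
  -2.1, -2.4, -3.3, -3.4, -1.5, -2.5,  # GC
  -2.2, -2.1, -3.4, -2.4, -1.4, -2.1,  # CG
  -0.6, -1.0, -1.5, -1.4, -0.5, -1.3,  # GU
  -1.4, -1.3, -2.5, -2.1, -1.3, -0.5   # UG
), nrow = 6, byrow = TRUE, dimnames = list(PAIR_TYPES, PAIR_TYPES))

#' Folding energy parameters
#'
#' Returns the bundled nearest-neighbour parameter set: a symmetric stacking
#' table over the six canonical pair types and affine loop penalties, all in
#' kcal/mol. Pass a modified copy to [mfe_fold()], [duplex_mfe()] or the
#' exhaustive reference scorers to experiment with the model.
#'
#' @param gu Logical; allow G:U wobble pairs (default `TRUE`).
#' @return A named list with elements `stack` (6x6 matrix), `hairpin_a/b`,
#'   `bulge_a/b`, `internal_a/b` (affine loop penalties: `a + b * unpaired`),
#'   `ml_init`, `ml_branch`, `ml_unpaired` (multiloop), `min_loop` (minimum
#'   hairpin loop, nt), `max_interior` (largest bulge/internal loop considered),
#'   and `gu`.
#' @export
energy_params <- function(gu = TRUE) {
  list(
    stack       = .STACK,
    hairpin_a   = 4.5,  hairpin_b  = 0.35,
    bulge_a     = 3.6,  bulge_b    = 0.35,
    internal_a  = 3.0,  internal_b = 0.35,
    ml_init     = 3.4,  ml_branch  = 0.4, ml_unpaired = 0.1,
    min_loop    = 3L,
    max_interior = 30L,
    gu          = isTRUE(gu)
  )
}

pair_type <- function(a, b) {
  key <- paste0(a, b)
  ifelse(key %in% PAIR_TYPES, key, NA_character_)
}

pair_ok <- function(a, b, par) {
  pt <- pair_type(a, b)
  ok <- !is.na(pt)
  if (!par$gu) ok <- ok & !(pt %in% c("GU", "UG"))
  ok
}

# --- reference scorer -------------------------------------------------------
#
# Energy of a fixed nested structure, computed by explicit loop decomposition.
# This is the definition of the model; the C++ dynamic program must agree with
# it, and the exhaustive oracles rank structures with it.

#' Score a fixed secondary structure
#'
#' Computes the free energy of a given nested structure on `seq` by explicit
#' loop decomposition (hairpin / stack / bulge / internal / multiloop), using
#' the same constants as the folding engine. External (unenclosed) bases are
#' free. Used as the independent reference when validating [mfe_fold()].
#'
#' @param seq RNA sequence (A/C/G/U).
#' @param pairs Two-column integer matrix of 0-based pair indices `(i, j)`,
#'   `i < j`, non-crossing; may have zero rows.
#' @param par Parameter list from [energy_params()].
#' @return Energy in kcal/mol (0 for the empty structure).
#' @export
structure_energy <- function(seq, pairs, par = energy_params()) {
  bases <- strsplit(seq, "")[[1]]
  if (is.null(pairs) || NROW(pairs) == 0L) return(0)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  o <- pairs[, 1]; c_ <- pairs[, 2]
  # children of each pair = pairs directly enclosed (no intermediate pair)
  enclosing <- function(k) {
    # index of the innermost pair strictly enclosing pair k, or 0
    cand <- which(o < o[k] & c_ > c_[k])
    if (!length(cand)) return(0L)
    cand[which.max(o[cand])]
  }
  parent <- vapply(seq_along(o), enclosing, integer(1))
  e <- 0
  for (k in seq_along(o)) {
    kids <- which(parent == k)
    i <- o[k]; j <- c_[k]
    if (!length(kids)) {
      L <- j - i - 1L
      e <- e + par$hairpin_a + par$hairpin_b * (L - par$min_loop)
    } else if (length(kids) == 1L) {
      ki <- o[kids]; kj <- c_[kids]
      l1 <- ki - i - 1L
      l2 <- j - kj - 1L
      if (l1 == 0L && l2 == 0L) {
        e <- e + par$stack[pair_type(bases[i + 1L], bases[j + 1L]),
                           pair_type(bases[ki + 1L], bases[kj + 1L])]
      } else if (l1 == 0L || l2 == 0L) {
        e <- e + par$bulge_a + par$bulge_b * (l1 + l2)
      } else {
        e <- e + par$internal_a + par$internal_b * (l1 + l2)
      }
    } else {
      enclosed <- sum((c_[kids] - o[kids]) + 1L)
      unpaired <- (j - i - 1L) - enclosed
      e <- e + par$ml_init + par$ml_branch * (length(kids) + 1L) +
        par$ml_unpaired * unpaired
    }
  }
  e
}

par_to_engine <- function(par) {
  # flat numeric vector handed to the C++ engine; keep order in sync with src/
  c(as.numeric(par$stack),             # 36 values, column-major
    par$hairpin_a, par$hairpin_b,
    par$bulge_a, par$bulge_b,
    par$internal_a, par$internal_b,
    par$ml_init, par$ml_branch, par$ml_unpaired,
    as.numeric(par$min_loop), as.numeric(par$max_interior),
    as.numeric(par$gu))
}
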