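# Exhaustive reference implementations. These enumerate every admissible
# structure and score it with structure_energy(), providing ground truth that
# is algorithmically independent of the dynamic programs in src/.

#' Exhaustive minimum-free-energy folding (reference implementation)
#'
#' Enumerates every nested structure of `seq` (canonical pairs, hairpin loops
#' of at least `par$min_loop` nt, no pseudoknots), scores each with
#' [structure_energy()], and returns the optimum. Exponential in sequence
#' length; intended for sequences of roughly 20 nt or fewer, as a ground-truth
#' check of [mfe_fold()].
#'
#' @inheritParams mfe_fold
#' @return List with `energy` (minimum), `pairs` (one optimal structure),
#'   `n_structures` (number of admissible structures including the empty one),
#'   and `n_optimal` (number of co-optimal structures).
#' @export
fold_exhaustive <- function(seq, par = energy_params()) {
  rna <- dna_to_rna(seq)
  assert_alphabet(rna, c("A", "C", "G", "U"), "RNA")
  n <- nchar(rna)
  if (n > 22L) stop("fold_exhaustive is for short sequences (<= 22 nt)")
  bases <- strsplit(rna, "")[[1]]
  minl <- par$min_loop
  memo <- new.env(parent = emptyenv())

  structs <- function(i, j) {
    # all pair sets on 0-based region [i, j]
    if (j - i < minl + 1L) return(list(NULL))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- structs(i + 1L, j) # i unpaired
    if (i + minl + 1L <= j) {
      for (k in (i + minl + 1L):j) {
        if (!pair_ok(bases[i + 1L], bases[k + 1L], par)) next
        inner <- structs(i + 1L, k - 1L)
        rest <- structs(k + 1L, j)
        for (a in inner) for (b in rest) {
          out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
        }
      }
    }
    memo[[key]] <- out
    out
  }

  all_structs <- structs(0L, n - 1L)
  energies <- vapply(all_structs, function(p) structure_energy(rna, p, par),
                     numeric(1))
  best <- min(energies)
  list(
    energy = best,
    pairs = all_structs[[which.min(energies)]],
    n_structures = length(all_structs),
    n_optimal = sum(abs(energies - best) < 1e-9)
  )
}

# energy of a fixed intermolecular chain of pairs (sorted by x ascending);
# consecutive pairs contribute stacking or affine loop terms, matching the
# duplex DP's model. Chains with a gap beyond par$max_interior are invalid.
duplex_chain_energy <- function(x, y, chain, par) {
  if (NROW(chain) <= 1L) return(0)
  bx <- strsplit(x, "")[[1]]; by <- strsplit(y, "")[[1]]
  e <- 0
  for (r in 2:NROW(chain)) {
    k <- chain[r - 1L, 1]; l <- chain[r - 1L, 2]
    i <- chain[r, 1]; j <- chain[r, 2]
    a <- i - k - 1L; b <- l - j - 1L
    if (a > par$max_interior || b > par$max_interior) return(NA_real_)
    if (a == 0L && b == 0L) {
      e <- e + par$stack[pair_type(bx[k + 1L], by[l + 1L]),
                         pair_type(bx[i + 1L], by[j + 1L])]
    } else if (a == 0L || b == 0L) {
      e <- e + par$bulge_a + par$bulge_b * (a + b)
    } else {
      e <- e + par$internal_a + par$internal_b * (a + b)
    }
  }
  e
}

#' Exhaustive intermolecular duplex energy (reference implementation)
#'
#' Enumerates every antiparallel chain of intermolecular pairs between `x` and
#' `y` (x positions increasing, y positions decreasing, consecutive pairs
#' separated by at most `par$max_interior` unpaired bases on either strand),
#' scores each chain with the duplex model, and returns the minimum (0 for the
#' empty duplex). Ground truth for [duplex_mfe()]; exponential, use strands of
#' about 12 nt or fewer.
#'
#' @param x,y RNA sequences (T converted to U).
#' @param par Parameter list from [energy_params()].
#' @return List with `energy` and `pairs` (an optimal chain, 0-based).
#' @export
duplex_exhaustive <- function(x, y, par = energy_params()) {
  x <- dna_to_rna(x); y <- dna_to_rna(y)
  assert_alphabet(c(x, y), c("A", "C", "G", "U"), "RNA")
  bx <- strsplit(x, "")[[1]]; by <- strsplit(y, "")[[1]]
  n <- length(bx); m <- length(by)
  if (n > 14L || m > 14L) stop("duplex_exhaustive is for strands <= 14 nt")

  best <- list(energy = 0, pairs = matrix(integer(0), 0, 2))
  # depth-first over chains; (i,j) = last pair added
  extend <- function(chain, e, i, j) {
    if (e < best$energy) best <<- list(energy = e, pairs = chain)
    if (i >= n || j <= 1L) return(invisible())
    for (ii in (i + 1L):n) {
      if (ii - i - 1L > par$max_interior) break
      for (jj in (j - 1L):1L) {
        if (j - jj - 1L > par$max_interior) break
        if (!pair_ok(bx[ii], by[jj], par)) next
        a <- ii - i - 1L; b <- j - jj - 1L
        cost <- if (a == 0L && b == 0L) {
          par$stack[pair_type(bx[i], by[j]), pair_type(bx[ii], by[jj])]
        } else if (a == 0L || b == 0L) {
          par$bulge_a + par$bulge_b * (a + b)
        } else {
          par$internal_a + par$internal_b * (a + b)
        }
        extend(rbind(chain, c(ii - 1L, jj - 1L)), e + cost, ii, jj)
      }
    }
  }
  for (i in seq_len(n)) for (j in rev(seq_len(m))) {
    if (pair_ok(bx[i], by[j], par)) {
      extend(matrix(c(i - 1L, j - 1L), 1, 2), 0, i, j)
    }
  }
  best
}
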