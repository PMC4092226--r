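# miRNA target-site discovery in a 3'-UTR: exact seed complementarity
# (positions 2-8, Watson-Crick only), box-motif labelling, and duplex
# minimum-free-energy scoring of each site in its local context.

#' Default 3'-UTR box motifs
#'
#' The GY-box, Brd-box and K-box are UTR-strand motifs known from the
#' Drosophila E(spl)/Brd literature to pair with specific miRNA seeds. Their
#' sequences are literature-derived configuration, not package constants of
#' any particular study; edit or extend the returned tibble to taste. Labels
#' are decorative: sites are never filtered by motif class.
#'
#' @return Tibble with `box`, `motif` (RNA, UTR strand).
#' @export
box_motifs <- function() {
  tibble(box = c("GY-box", "Brd-box", "K-box"),
         motif = c("GUCUUCC", "AGCUUUA", "UGUGAU"))
}

#' Example mature miRNA set
#'
#' Representative arthropod mature sequences for the four miRNAs whose seeds
#' pair with the GY-/Brd-/K-box region of the crab cyclin B 3'-UTR (miR-2,
#' miR-7, miR-79, miR-133). Seeds are conserved across the family members, so
#' these are suitable defaults for seed-site scans in examples and reruns.
#'
#' @return Named character vector of RNA sequences.
#' @export
example_mirnas <- function() {
  c("miR-2"   = "UAUCACAGCCAGCUUUGAUGAGC",
    "miR-7"   = "UGGAAGACUAGUGAUUUUGUUGU",
    "miR-79"  = "UAAAGCUAGAUUACCAAAGCAU",
    "miR-133" = "UUGGUCCCCUUCAACCAGCUG")
}

normalize_utr <- function(utr) {
  if (is.character(utr)) {
    utr <- tibble(id = names(utr) %||% "utr", seq = unname(utr))
  }
  stopifnot(all(c("id", "seq") %in% names(utr)))
  utr$seq <- dna_to_rna(utr$seq)
  assert_alphabet(utr$seq, c("A", "C", "G", "U"), "UTR")
  utr
}

#' Scan a 3'-UTR for seed-complementary sites
#'
#' Reports every UTR span that is the exact reverse complement (Watson-Crick
#' only, no G:U) of miRNA positions `seed[1]`-`seed[2]` (default 2-8). Spans
#' matching an enabled box motif (either contains the other) are labelled with
#' the box name, otherwise `generic`.
#'
#' @param mirnas Named character vector of mature miRNA sequences (RNA or
#'   DNA; at least 9 nt).
#' @param utr A UTR record: tibble with `id`, `seq`, or a (named) character
#'   vector.
#' @param seed 1-based seed positions within the miRNA.
#' @param motifs Motif tibble as from [box_motifs()]; NULL disables labelling.
#' @return Tibble with `mirna`, `utr_id`, `start`, `end` (0-based half-open on
#'   the UTR), `site_seq`, `seed_class`.
#' @export
scan_seed_sites <- function(mirnas, utr, seed = c(2L, 8L),
                            motifs = box_motifs()) {
  utr <- normalize_utr(utr)
  mir <- dna_to_rna(mirnas)
  stopifnot(all(nchar(mir) >= 9L), !is.null(names(mir)))
  out <- list()
  for (u in seq_len(nrow(utr))) {
    subject <- Biostrings::RNAString(utr$seq[u])
    for (m in seq_along(mir)) {
      pat <- dna_to_rna(revcomp(substr(mir[m], seed[1], seed[2])))
      hits <- Biostrings::matchPattern(Biostrings::RNAString(pat), subject)
      if (!length(hits)) next
      st <- Biostrings::start(hits)
      out[[length(out) + 1L]] <- tibble(
        mirna = names(mir)[m], utr_id = utr$id[u],
        start = st - 1L, end = st - 1L + nchar(pat),
        site_seq = as.character(hits)
      )
    }
  }
  if (!length(out)) {
    return(tibble(mirna = character(), utr_id = character(),
                  start = integer(), end = integer(), site_seq = character(),
                  seed_class = character()))
  }
  sites <- bind_rows(out)
  sites$seed_class <- "generic"
  if (!is.null(motifs)) {
    for (b in seq_len(nrow(motifs))) {
      hit <- stringr::str_detect(sites$site_seq,
                                 stringr::fixed(motifs$motif[b])) |
        stringr::str_detect(motifs$motif[b], stringr::fixed(sites$site_seq))
      sites$seed_class[hit & sites$seed_class == "generic"] <- motifs$box[b]
    }
  }
  sites
}

#' Intermolecular duplex minimum free energy
#'
#' Computes the minimum-energy hybridisation of a miRNA against a target-site
#' context by dynamic programming over the two strands: intramolecular pairs
#' are forbidden, bulges/internal loops carry affine penalties, and helix
#' stacks use the same bundled table as the folding engine. There is no
#' initiation term, so the empty duplex scores 0 and the reported energy is
#' never positive.
#'
#' @param mirna,site_context Sequences (RNA or DNA), each at most 40 nt.
#' @param par Energy parameters.
#' @return An object of class `duplex_result`: list with `energy` (kcal/mol),
#'   `pairs` (0-based: miRNA position, context position), and `alignment`
#'   (three-line pairing rendering, miRNA 5'->3' on top).
#' @seealso [duplex_exhaustive()] for the enumeration reference.
#' @export
duplex_mfe <- function(mirna, site_context, par = energy_params()) {
  x <- dna_to_rna(mirna); y <- dna_to_rna(site_context)
  assert_alphabet(c(x, y), c("A", "C", "G", "U"), "RNA")
  if (nchar(x) > 40L || nchar(y) > 40L) {
    stop("duplex strands must be at most 40 nt", call. = FALSE)
  }
  r <- duplex_mfe_cpp(x, y, par_to_engine(par))
  structure(list(energy = r$energy, pairs = r$pairs,
                 alignment = render_duplex(x, y, r$pairs)),
            class = "duplex_result")
}

#' @export
print.duplex_result <- function(x, ...) {
  cat(x$alignment, sep = "\n")
  cat(sprintf("mfe: %.2f kcal/mol\n", x$energy))
  invisible(x)
}

# three-line rendering: miRNA 5'->3' over pairing bars over the target 3'->5'
render_duplex <- function(x, y, pairs) {
  bx <- strsplit(x, "")[[1]]; by <- strsplit(y, "")[[1]]
  if (NROW(pairs) == 0L) {
    return(c(paste0("miRNA  5' ", x, " 3'"), "",
             paste0("target 3' ", paste(rev(by), collapse = ""), " 5'")))
  }
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  top <- character(0); mid <- character(0); bot <- character(0)
  emit <- function(a, b, bar) {
    wd <- max(length(a), length(b))
    top <<- c(top, c(a, rep("-", wd - length(a))))
    bot <<- c(bot, c(b, rep("-", wd - length(b))))
    mid <<- c(mid, rep(if (bar) "|" else " ", wd))
  }
  # leading unpaired flanks
  emit(bx[seq_len(pairs[1, 1])],
       if (pairs[1, 2] + 2L <= length(by)) by[length(by):(pairs[1, 2] + 2L)]
       else character(0), FALSE)
  for (r in seq_len(NROW(pairs))) {
    i <- pairs[r, 1] + 1L; j <- pairs[r, 2] + 1L
    emit(bx[i], by[j], TRUE)
    if (r < NROW(pairs)) {
      ii <- pairs[r + 1L, 1] + 1L; jj <- pairs[r + 1L, 2] + 1L
      a <- if (ii - i > 1L) bx[(i + 1L):(ii - 1L)] else character(0)
      b <- if (j - jj > 1L) by[(j - 1L):(jj + 1L)] else character(0)
      if (length(a) || length(b)) emit(a, b, FALSE)
    }
  }
  i_last <- pairs[NROW(pairs), 1] + 1L
  j_last <- pairs[NROW(pairs), 2] + 1L
  emit(if (i_last < length(bx)) bx[(i_last + 1L):length(bx)] else character(0),
       if (j_last > 1L) by[(j_last - 1L):1L] else character(0), FALSE)
  c(paste0("miRNA  5' ", paste(top, collapse = ""), " 3'"),
    paste0("          ", paste(mid, collapse = "")),
    paste0("target 3' ", paste(bot, collapse = ""), " 5'"))
}

#' Scan and score target sites
#'
#' Runs [scan_seed_sites()] and scores each site by hybridising the full
#' miRNA against the site plus `flank` nt of UTR context on each side.
#'
#' @inheritParams scan_seed_sites
#' @param flank Context flank for duplex scoring, nt (default 15).
#' @param mfe_max Keep sites with duplex energy at or below this value
#'   (default 0).
#' @param par Energy parameters.
#' @return Tibble of duplex sites: `mirna`, `utr_id`, `start`, `end`,
#'   `seed_class`, `duplex_mfe`, `pairing` (newline-joined rendering).
#' @export
scan_targets <- function(mirnas, utr, seed = c(2L, 8L), flank = 15L,
                         mfe_max = 0, motifs = box_motifs(),
                         par = energy_params()) {
  utr <- normalize_utr(utr)
  sites <- scan_seed_sites(mirnas, utr, seed, motifs)
  if (!nrow(sites)) {
    return(sites |> mutate(duplex_mfe = numeric(0), pairing = character(0)))
  }
  mir <- dna_to_rna(mirnas)
  scored <- purrr::pmap(sites, function(mirna, utr_id, start, end, ...) {
    useq <- utr$seq[utr$id == utr_id][1]
    ctx <- substr(useq, max(1L, start + 1L - flank),
                  min(nchar(useq), end + flank))
    d <- duplex_mfe(mir[[mirna]], ctx, par)
    tibble(duplex_mfe = d$energy,
           pairing = paste(d$alignment, collapse = "\n"))
  }) |> bind_rows()
  bind_cols(sites, scored) |> filter(.data$duplex_mfe <= mfe_max)
}

#' Rank miRNAs by their best target site
#'
#' For each miRNA the best site is the one with the smallest duplex energy
#' (ties broken by UTR coordinate); the report is sorted by best energy
#' ascending, ties again by coordinate.
#'
#' @param sites Duplex-site tibble from [scan_targets()].
#' @return Tibble with one row per miRNA: best site coordinates, class,
#'   `best_mfe`, `n_sites`.
#' @export
rank_targets <- function(sites) {
  stopifnot(nrow(sites) > 0L)
  sites |>
    group_by(.data$mirna) |>
    arrange(.data$duplex_mfe, .data$start, .by_group = TRUE) |>
    summarise(utr_id = first(.data$utr_id), start = first(.data$start),
              end = first(.data$end), seed_class = first(.data$seed_class),
              best_mfe = first(.data$duplex_mfe), n_sites = n(),
              .groups = "drop") |>
    arrange(.data$best_mfe, .data$start)
}

#' In-silico PCR
#'
#' Locates a forward primer on the template sense strand and a reverse primer
#' on the antisense strand and reports every amplicon they would produce
#' (forward-primer start through the reverse-primer binding site, inclusive).
#'
#' @param template Template sequence (DNA).
#' @param fwd,rev Primer sequences, 5'->3' (tails must be removed by the
#'   caller).
#' @param max_mismatch Allowed mismatches per primer (default 0).
#' @return Tibble with `start`, `end` (0-based half-open on the template),
#'   `length`, `seq`.
#' @export
pcr_product <- function(template, fwd, rev, max_mismatch = 0L) {
  template <- rna_to_dna(template)
  subj <- Biostrings::DNAString(template)
  fhits <- Biostrings::matchPattern(Biostrings::DNAString(rna_to_dna(fwd)),
                                    subj, max.mismatch = max_mismatch)
  rhits <- Biostrings::matchPattern(
    Biostrings::DNAString(revcomp(rna_to_dna(rev))), subj,
    max.mismatch = max_mismatch)
  out <- list()
  for (fs in Biostrings::start(fhits)) {
    for (re in Biostrings::end(rhits)) {
      if (re > fs) {
        out[[length(out) + 1L]] <- tibble(
          start = fs - 1L, end = re, length = re - fs + 1L,
          seq = substr(template, fs, re)
        )
      }
    }
  }
  if (!length(out)) {
    return(tibble(start = integer(), end = integer(), length = integer(),
                  seq = character()))
  }
  bind_rows(out) |> arrange(.data$start, .data$end)
}
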