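# Mapping of unique tags to miRNA references and the genome, five-group
# classification, seed-family assignment and star-strand detection.

#' Bundle the mapping references
#'
#' @param species_mature,species_precursor Tibbles (`name`, `seq`) of the
#'   primary (species-level) mature and precursor references.
#' @param clade_mature,clade_precursor Optional broader-clade references.
#' @param genome Named character vector of contig sequences.
#' @param secondary_genome Optional second genome (named character vector)
#'   used by classification group 3.
#' @return A `reference_set` list.
#' @export
reference_set <- function(species_mature, species_precursor,
                          clade_mature = NULL, clade_precursor = NULL,
                          genome = NULL, secondary_genome = NULL) {
  stopifnot(all(c("name", "seq") %in% names(species_mature)))
  structure(list(
    species_mature = species_mature,
    species_precursor = species_precursor,
    clade_mature = clade_mature,
    clade_precursor = clade_precursor,
    genome = genome,
    secondary_genome = secondary_genome
  ), class = "reference_set")
}

# all ungapped occurrences of each tag inside each reference sequence with at
# most `mm` mismatches outside the exact-match seed band (1-based positions
# seed[1]..seed[2] of the tag); returns one row per hit
match_in_refs <- function(tags, refs, mm = 2L, seed = c(2L, 8L)) {
  empty <- tibble(tag_id = character(), ref_name = character(),
                  offset = integer(), mismatches = integer())
  if (is.null(refs) || nrow(refs) == 0L || nrow(tags) == 0L) return(empty)
  bw <- seed[2] - seed[1] + 1L
  # hashed join on the exact-match seed band, then full-window verification
  band_ix <- purrr::map(seq_len(nrow(refs)), function(r) {
    window_index(refs$seq[r], bw) |> mutate(ref = r)
  }) |> bind_rows()
  if (!nrow(band_ix)) return(empty)
  hits <- list()
  w <- nchar(tags$seq)
  for (len in unique(w)) {
    idx <- which(w == len)
    cand <- tibble(t_ix = idx,
                   key = substr(tags$seq[idx], seed[1], seed[2])) |>
      inner_join(band_ix, by = "key", relationship = "many-to-many") |>
      mutate(wstart = .data$pos - seed[1] + 1L) |>
      filter(.data$wstart >= 1L,
             .data$wstart + len - 1L <= nchar(refs$seq[.data$ref]))
    if (!nrow(cand)) next
    win <- substr(refs$seq[cand$ref], cand$wstart, cand$wstart + len - 1L)
    d <- hamming_var(tags$seq[cand$t_ix], win)
    keep <- d <= mm
    if (!any(keep)) next
    hits[[length(hits) + 1L]] <- tibble(
      tag_id = tags$tag_id[cand$t_ix[keep]],
      ref_name = refs$name[cand$ref[keep]],
      offset = cand$wstart[keep] - 1L,
      mismatches = d[keep]
    )
  }
  if (!length(hits)) return(empty)
  bind_rows(hits)
}

# hamming over pairs that share a length (vectorised within length groups)
hamming_var <- function(x, y) {
  out <- integer(length(x))
  w <- nchar(x)
  for (len in unique(w)) {
    idx <- which(w == len)
    mm <- integer(length(idx))
    for (p in seq_len(len)) {
      mm <- mm + (substr(x[idx], p, p) != substr(y[idx], p, p))
    }
    out[idx] <- mm
  }
  out
}

# exact occurrences of tags in a genome, both strands; 0-based half-open
# plus-strand coordinates
match_in_genome <- function(tags, genome, mm = 0L) {
  empty <- tibble(tag_id = character(), contig = character(),
                  start = integer(), end = integer(), strand = character(),
                  mismatches = integer())
  if (is.null(genome) || nrow(tags) == 0L) return(empty)
  stopifnot(mm %in% c(0L, 1L))
  hits <- list()
  w <- nchar(tags$seq)
  for (cn in names(genome)) {
    fwd <- genome[[cn]]
    rev <- revcomp(fwd)
    clen <- nchar(fwd)
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") fwd else rev
      for (len in unique(w)) {
        idx <- which(w == len)
        parts <- if (mm == 0L) list(c(1L, len)) else {
          h <- len %/% 2L
          list(c(1L, h), c(h + 1L, len))
        }
        cand <- purrr::map(parts, function(pt) {
          tibble(t_ix = idx,
                 key = substr(tags$seq[idx], pt[1], pt[2])) |>
            inner_join(window_index(subject, pt[2] - pt[1] + 1L), by = "key",
                       relationship = "many-to-many") |>
            mutate(wstart = .data$pos - (pt[1] - 1L)) |>
            filter(.data$wstart >= 1L, .data$wstart + len - 1L <= clen)
        }) |> bind_rows() |> distinct(.data$t_ix, .data$wstart)
        if (!nrow(cand)) next
        d <- if (mm == 0L) rep(0L, nrow(cand)) else {
          hamming_var(tags$seq[cand$t_ix],
                      substr(rep(subject, nrow(cand)), cand$wstart,
                             cand$wstart + len - 1L))
        }
        keep <- d <= mm
        if (!any(keep)) next
        st <- cand$wstart[keep] # 1-based on scanned strand
        s0 <- if (strand == "+") st - 1L else clen - (st - 1L) - len
        hits[[length(hits) + 1L]] <- tibble(
          tag_id = tags$tag_id[cand$t_ix[keep]], contig = cn,
          start = s0, end = s0 + len, strand = strand,
          mismatches = d[keep]
        )
      }
    }
  }
  if (!length(hits)) return(empty)
  bind_rows(hits) |> arrange(.data$tag_id, .data$contig, .data$start)
}

#' Map unique tags to the references and the genome
#'
#' Reports all ungapped hits of each tag against the species and clade
#' mature/precursor references (at most `max_mismatch_ref` mismatches, with
#' tag positions `seed[1]`-`seed[2]` required exact) and against the genome
#' (exact by default, both strands). Genome hits are flagged when they overlap
#' a known precursor locus (the species precursors located in the genome).
#'
#' @param tags Tag tibble (`tag_id`, `seq`, `count`).
#' @param refset A [reference_set()].
#' @param max_mismatch_ref Mismatch ceiling against miRNA references
#'   (default 2).
#' @param max_mismatch_genome Mismatch ceiling against the genome (default 0).
#' @param seed Seed band (1-based tag positions) required to match exactly.
#' @return A `mapping_profiles` list: `ref_hits` (tag_id, ref_class species/
#'   clade, ref_type mature/precursor, ref_name, offset, mismatches),
#'   `genome_hits` (BED-like tibble with `known_overlap` flag), and
#'   `known_loci`.
#' @export
map_tags <- function(tags, refset, max_mismatch_ref = 2L,
                     max_mismatch_genome = 0L, seed = c(2L, 8L)) {
  stopifnot(inherits(refset, "reference_set"))
  ref_tbls <- list(
    species_mature = list(refset$species_mature, "species", "mature"),
    species_precursor = list(refset$species_precursor, "species", "precursor"),
    clade_mature = list(refset$clade_mature, "clade", "mature"),
    clade_precursor = list(refset$clade_precursor, "clade", "precursor")
  )
  ref_hits <- purrr::map(ref_tbls, function(rt) {
    match_in_refs(tags, rt[[1]], max_mismatch_ref, seed) |>
      mutate(ref_class = rt[[2]], ref_type = rt[[3]])
  }) |> bind_rows()

  known_loci <- locate_known_loci(refset)
  genome_hits <- match_in_genome(tags, refset$genome, max_mismatch_genome)
  if (nrow(genome_hits)) {
    genome_hits <- genome_hits |>
      mutate(known_overlap = purrr::map2_lgl(.data$contig, seq_len(n()),
        function(cn, i) {
          any(known_loci$contig == cn &
                known_loci$start < genome_hits$end[i] &
                known_loci$end > genome_hits$start[i])
        }))
  } else {
    genome_hits$known_overlap <- logical(0)
  }
  secondary_hits <- match_in_genome(tags, refset$secondary_genome,
                                    max_mismatch_genome)
  structure(list(ref_hits = ref_hits, genome_hits = genome_hits,
                 secondary_hits = secondary_hits, known_loci = known_loci),
            class = "mapping_profiles")
}

# locate species precursors in the genome (exact, both strands)
locate_known_loci <- function(refset) {
  empty <- tibble(name = character(), contig = character(), start = integer(),
                  end = integer(), strand = character())
  pre <- refset$species_precursor
  if (is.null(refset$genome) || is.null(pre) || nrow(pre) == 0L) return(empty)
  h <- match_in_genome(
    tibble(tag_id = pre$name, seq = pre$seq), refset$genome, 0L)
  if (!nrow(h)) return(empty)
  h |> select(name = "tag_id", "contig", "start", "end", "strand")
}

#' Five-group classification of mapped tags
#'
#' Applies the reference/genome decision rules in fixed order, first match
#' winning: (1) known miRNA hit and a genome hit at a known precursor locus;
#' (2) known miRNA hit plus an additional genome locus whose flank-extended
#' sequence folds into a hairpin; (3) clade miRNA hit with a secondary-genome
#' hit but no primary-genome hit; (4) miRNA hit with no genome hit; (5) no
#' miRNA hit but a genome hit whose extended locus has hairpin propensity.
#' Tags hitting nothing, and genome-only tags whose loci do not fold into
#' hairpins (the piRNA-like bulk), stay unclassified (`group = NA`).
#'
#' @param tags Tag tibble.
#' @param profiles A `mapping_profiles` from [map_tags()].
#' @param refset The [reference_set()] (for the genome used in hairpin
#'   checks).
#' @param flank Flank extension for hairpin checks, nt (default 60).
#' @param energy_max,pair_min Hairpin criteria (see [hairpin_check()]).
#' @param par Energy parameters.
#' @param max_loci_checked Genome loci folded per tag before giving up
#'   (default 5).
#' @return Tibble of calls: `tag_id`, `seq`, `count`, `group` (1-5 or NA),
#'   `status` (`known`, `novel-candidate`, `unclassified`), `assigned_name`.
#' @export
classify_tags <- function(tags, profiles, refset, flank = 60L,
                          energy_max = -18, pair_min = 0.6,
                          par = energy_params(), max_loci_checked = 5L) {
  rh <- profiles$ref_hits
  gh <- profiles$genome_hits
  sh <- profiles$secondary_hits

  mir_tags <- unique(rh$tag_id)
  secondary_tags <- unique(sh$tag_id)
  gh_rows <- split(seq_len(nrow(gh)), gh$tag_id)
  best_names <- rh |>
    arrange(.data$tag_id, .data$ref_type != "mature",
            .data$ref_class != "species", .data$mismatches, .data$ref_name) |>
    distinct(.data$tag_id, .keep_all = TRUE)
  best_name_of <- setNames(sub("-pre$", "", best_names$ref_name),
                           best_names$tag_id)

  hp_cache <- new.env(parent = emptyenv())
  locus_hairpin <- function(contig, start, end, strand) {
    key <- paste(contig, start, end, strand)
    if (!is.null(hp_cache[[key]])) return(hp_cache[[key]])
    v <- hairpin_at_locus(refset$genome,
                          list(contig = contig, start = start, end = end,
                               strand = strand),
                          flank = flank, energy_max = energy_max,
                          pair_min = pair_min, par = par)
    hp_cache[[key]] <- v$is_hairpin
    v$is_hairpin
  }
  any_hairpin <- function(hits) {
    hits <- head(hits, max_loci_checked)
    for (i in seq_len(nrow(hits))) {
      if (locus_hairpin(hits$contig[i], hits$start[i], hits$end[i],
                        hits$strand[i])) return(TRUE)
    }
    FALSE
  }

  n <- nrow(tags)
  group <- rep(NA_integer_, n)
  status <- rep("unclassified", n)
  name <- rep(NA_character_, n)
  tag_has_mir <- tags$tag_id %in% mir_tags
  for (i in seq_len(n)) {
    tid <- tags$tag_id[i]
    g <- gh[gh_rows[[tid]] %||% integer(0), , drop = FALSE]
    has_genome <- nrow(g) > 0L
    if (tag_has_mir[i] && has_genome) {
      novel <- g[!g$known_overlap, , drop = FALSE]
      group[i] <- if (nrow(novel) > 0L && any_hairpin(novel)) 2L else 1L
      status[i] <- "known"; name[i] <- best_name_of[[tid]]
    } else if (tag_has_mir[i]) {
      group[i] <- if (tid %in% secondary_tags) 3L else 4L
      status[i] <- "known"; name[i] <- best_name_of[[tid]]
    } else if (has_genome) {
      if (any_hairpin(g)) {
        group[i] <- 5L
        status[i] <- "novel-candidate"
      }
    }
  }
  res <- tibble(tag_id = tags$tag_id, seq = tags$seq, count = tags$count,
                group = group, status = status, assigned_name = name)

  novel <- which(res$status == "novel-candidate")
  novel <- novel[order(res$tag_id[novel])] # input-order invariant numbering
  res$assigned_name[novel] <- sprintf("novel-%03d", seq_along(novel))
  res
}

#' Seed-family assignment
#'
#' The family key is the seed: nucleotides `seed[1]`-`seed[2]` (default 2-8)
#' of the observed mature sequence, in RNA space. Tags shorter than the seed
#' window are left unassigned.
#'
#' @param calls Call tibble from [classify_tags()].
#' @param seed 1-based inclusive seed positions.
#' @return `calls` with a `family` column (NA for unclassified tags).
#' @export
assign_family <- function(calls, seed = c(2L, 8L)) {
  calls |>
    mutate(family = ifelse(
      .data$status %in% c("known", "novel-candidate", "star") &
        nchar(.data$seq) >= seed[2],
      dna_to_rna(substr(.data$seq, seed[1], seed[2])),
      NA_character_
    ))
}

#' Star-strand (miRNA*) detection
#'
#' A tag is called a star when it maps inside a known precursor on the arm
#' opposite the annotated mature, with at least `pair_min` of its bases paired
#' to positions on the mature arm in the precursor's MFE fold. Precursors that
#' fold into more than one stem leave star status undetermined.
#'
#' @param calls Call tibble.
#' @param profiles `mapping_profiles` from [map_tags()].
#' @param refset The [reference_set()].
#' @param pair_min Minimum fraction of tag bases paired to the mature arm
#'   (default 0.6).
#' @param par Energy parameters.
#' @return `calls` with `status` set to `"star"` (and `arm` filled) where the
#'   criteria hold; an `arm` column (`5p`/`3p`/NA) is added for all calls.
#' @export
detect_star <- function(calls, profiles, refset, pair_min = 0.6,
                        par = energy_params()) {
  calls$arm <- NA_character_
  pre <- refset$species_precursor
  mat <- refset$species_mature
  if (is.null(pre) || nrow(pre) == 0L) return(calls)
  pre_hits <- profiles$ref_hits |>
    filter(.data$ref_class == "species", .data$ref_type == "precursor")
  if (!nrow(pre_hits)) return(calls)

  folds <- new.env(parent = emptyenv())
  get_fold <- function(nm) {
    if (is.null(folds[[nm]])) {
      folds[[nm]] <- mfe_fold(pre$seq[pre$name == nm][1], par)
    }
    folds[[nm]]
  }

  for (r in seq_len(nrow(pre_hits))) {
    tid <- pre_hits$tag_id[r]
    i <- match(tid, calls$tag_id)
    if (is.na(i)) next
    pre_name <- pre_hits$ref_name[r]
    pre_seq <- pre$seq[pre$name == pre_name][1]
    f <- get_fold(pre_name)
    if (NROW(f$pairs) == 0L || n_terminal_loops(f$pairs) != 1L) next
    # terminal-loop boundaries: innermost pair
    inner <- which(!(seq_len(NROW(f$pairs)) %in% pair_children(f$pairs)))
    loop5 <- f$pairs[inner, 1]; loop3 <- f$pairs[inner, 2]
    # annotated mature position inside this precursor
    mat_name <- sub("-pre$", "", pre_name)
    mseq <- mat$seq[mat$name == mat_name]
    if (!length(mseq)) next
    mpos <- as.integer(regexpr(mseq, pre_seq, fixed = TRUE))
    if (mpos < 1L) next
    m0 <- mpos - 1L; m1 <- m0 + nchar(mseq) - 1L
    mature_arm <- if (m1 <= loop5) "5p" else if (m0 >= loop3) "3p" else NA
    t0 <- pre_hits$offset[r]; t1 <- t0 + nchar(calls$seq[i]) - 1L
    tag_arm <- if (t1 <= loop5) "5p" else if (t0 >= loop3) "3p" else NA
    calls$arm[i] <- tag_arm
    if (is.na(mature_arm) || is.na(tag_arm) || tag_arm == mature_arm) next
    # fraction of tag bases paired to the mature arm
    arm_rng <- if (mature_arm == "5p") c(0L, loop5) else c(loop3, nchar(pre_seq) - 1L)
    partner <- rep(NA_integer_, nchar(pre_seq))
    partner[f$pairs[, 1] + 1L] <- f$pairs[, 2]
    partner[f$pairs[, 2] + 1L] <- f$pairs[, 1]
    p <- partner[(t0:t1) + 1L]
    frac <- mean(!is.na(p) & p >= arm_rng[1] & p <= arm_rng[2])
    if (frac >= pair_min) {
      calls$status[i] <- "star"
      calls$assigned_name[i] <- paste0(mat_name, "*")
    }
  }
  calls
}

#' Annotation stage: map, classify, name, family, star
#'
#' @inheritParams classify_tags
#' @inheritParams map_tags
#' @return List with `calls` (final call tibble), `profiles`, and
#'   `group_counts` (reads and unique tags per group).
#' @export
annotate_tags <- function(tags, refset, max_mismatch_ref = 2L,
                          max_mismatch_genome = 0L, seed = c(2L, 8L),
                          flank = 60L, energy_max = -18, pair_min = 0.6,
                          par = energy_params()) {
  profiles <- map_tags(tags, refset, max_mismatch_ref, max_mismatch_genome,
                       seed)
  calls <- classify_tags(tags, profiles, refset, flank, energy_max, pair_min,
                         par)
  calls <- detect_star(calls, profiles, refset, pair_min, par)
  calls <- assign_family(calls, seed)
  group_counts <- calls |>
    filter(!is.na(.data$group)) |>
    group_by(.data$group) |>
    summarise(reads = sum(.data$count), unique = n(), .groups = "drop")
  list(calls = calls, profiles = profiles, group_counts = group_counts)
}
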