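# Synthetic-data generator. Emulates the structure of an ovarian small-RNA
# library: a bimodal 15-30 nt length distribution (a 21-23 nt miRNA-like mode
# from planted hairpin loci and a taller 24-27 nt piRNA-like mode), heavily
# skewed per-miRNA abundances, adaptor-adaptor ligation artifacts, contaminant
# reads from mRNA/structural-RNA/repeat references, and a configurable share
# of low-quality reads. Every read carries a ground-truth origin label so
# downstream stages can be scored exactly.

#' Simulation configuration
#'
#' Defaults describe the study conditions the package is tested under: a 20 kb
#' surrogate genome with 30 planted miRNA hairpins (20 of which are placed in
#' the "known" reference set) and 30 piRNA-like loci, 200,000 reads, log-normal
#' expression skew, 5% contaminants, 2% adaptor-adaptor artifacts and 10%
#' low-quality reads.
#'
#' @param genome_length Genome size, nt.
#' @param n_mirs Number of planted miRNA hairpin loci.
#' @param n_known How many planted miRNAs the species reference set contains
#'   (the rest are reference-absent, i.e. discoverable only as novel).
#' @param n_pirna_loci Number of piRNA-like loci.
#' @param read_total Total reads to simulate.
#' @param read_len Sequencing read length, nt.
#' @param adaptor 3' adaptor (DNA) appended to every insert.
#' @param error_rate Per-base substitution probability.
#' @param contaminant_fraction,artifact_fraction Fractions of reads drawn from
#'   contaminant references / adaptor-adaptor ligations.
#' @param pirna_share Share of the remaining (small-RNA) reads drawn from
#'   piRNA-like loci; the rest come from planted miRNAs.
#' @param star_fraction Fraction of each miRNA's reads taken from the star
#'   (passenger) arm.
#' @param lowq_fraction Fraction of reads emitted with mean quality below Q20.
#' @param expr_sigma Log-normal sigma of per-miRNA expression weights.
#' @param mirna_lengths,pirna_lengths Inclusive length ranges of the two modes
#'   (must lie within 15-30 nt).
#' @param seed Integer seed; identical configs give byte-identical output.
#' @return A validated named list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 20000L, n_mirs = 30L, n_known = 20L,
                       n_pirna_loci = 30L, read_total = 200000L,
                       read_len = 36L,
                       adaptor = "TGGAATTCTCGGGTGCCAAGG",
                       error_rate = 0.01,
                       contaminant_fraction = 0.05,
                       artifact_fraction = 0.02,
                       pirna_share = 0.6,
                       star_fraction = 0.1,
                       lowq_fraction = 0.1,
                       expr_sigma = 1.5,
                       mirna_lengths = c(21L, 23L),
                       pirna_lengths = c(24L, 27L),
                       seed = 42L) {
  cfg <- as.list(environment())
  stopifnot(
    genome_length > 0, read_total > 0, read_len >= 31, n_mirs >= 0,
    n_known >= 0, n_known <= n_mirs, n_pirna_loci >= 0,
    error_rate >= 0, error_rate <= 1,
    contaminant_fraction >= 0, contaminant_fraction <= 1,
    artifact_fraction >= 0, artifact_fraction <= 1,
    pirna_share >= 0, pirna_share <= 1,
    star_fraction >= 0, star_fraction <= 1,
    lowq_fraction >= 0, lowq_fraction <= 1,
    all(mirna_lengths >= 15), all(mirna_lengths <= 30),
    all(pirna_lengths >= 15), all(pirna_lengths <= 30),
    nchar(adaptor) >= 6
  )
  if (n_mirs > 0 && genome_length < 50 * n_mirs) {
    stop("genome_length must be at least 50 * n_mirs", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# place n non-overlapping intervals of the given widths on [0, L); explicit
# failure when packing is infeasible
place_loci <- function(L, widths, occupied = NULL, max_tries = 2000L) {
  starts <- integer(0)
  ends <- integer(0)
  occ_s <- occupied$start %||% integer(0)
  occ_e <- occupied$end %||% integer(0)
  for (w in widths) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      s <- sample.int(L - w + 1L, 1L) - 1L
      e <- s + w
      if (!any(s < c(ends, occ_e) & e > c(starts, occ_s))) {
        starts <- c(starts, s); ends <- c(ends, e); ok <- TRUE; break
      }
    }
    if (!ok) {
      stop("infeasible packing: cannot place loci without overlap; ",
           "increase genome_length or reduce locus counts", call. = FALSE)
    }
  }
  tibble(start = starts, end = ends)
}

mutate_bases <- function(seq, n_mut, interior = FALSE) {
  ch <- strsplit(seq, "")[[1]]
  # interior mutations keep both stem ends intact so the designed terminal
  # loop is not widened by broken closing pairs
  cand <- if (interior) 5:(length(ch) - 4L) else seq_along(ch)
  pos <- sample(cand, n_mut)
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Generate the synthetic genome with planted miRNA hairpins
#'
#' Builds a random genome and overwrites non-overlapping windows with designed
#' pre-miRNA hairpins: a 6-nt closing stem, the mature arm (5'), a 9-13 nt
#' terminal loop, and a star arm that is the reverse complement of the mature
#' with 0-2 designed mismatches. Construction guarantees each precursor folds
#' into a single stem-loop that passes [hairpin_check()]. piRNA-like loci are
#' plain genome windows. Contaminant reference sets (mRNA-like, structural-RNA-
#' like, repeat-like; random sequences disjoint from the genome) are generated
#' alongside.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (named character vector), `planted` (tibble of
#'   planted miRNAs: name, mature/star sequence and genome coordinates,
#'   0-based half-open, `known` flag, expression weight), `pirna_loci`
#'   (tibble), `contaminants` (named list of `name`/`seq` tibbles).
#' @export
sim_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  genome <- random_seq(1, L)

  planted <- tibble(
    name = character(), mature_seq = character(), star_seq = character(),
    contig = character(), start = integer(), end = integer(),
    strand = character(), mature_start = integer(), mature_end = integer(),
    star_start = integer(), star_end = integer(),
    known = logical(), expression_weight = numeric()
  )
  pre_loci <- NULL
  if (config$n_mirs > 0L) {
    pad <- 6L
    mature_len <- sample(seq(config$mirna_lengths[1], config$mirna_lengths[2]),
                         config$n_mirs, replace = TRUE)
    loop_len <- sample(9:13, config$n_mirs, replace = TRUE)
    widths <- 2L * pad + 2L * mature_len + loop_len
    pre_loci <- place_loci(L, widths)
    rows <- purrr::map(seq_len(config$n_mirs), function(i) {
      mat <- random_seq(1, mature_len[i])
      loop <- random_seq(1, loop_len[i], c("A", "C"))
      star <- revcomp(mat)
      n_mm <- sample(0:2, 1L)
      if (n_mm > 0L) star <- mutate_bases(star, n_mm, interior = TRUE)
      p5 <- random_seq(1, pad)
      pre <- paste0(p5, mat, loop, star, revcomp(p5))
      s <- pre_loci$start[i]
      tibble(
        name = sprintf("esi-miR-sim%02d", i),
        mature_seq = mat, star_seq = star,
        contig = "chr1", start = s, end = s + nchar(pre), strand = "+",
        mature_start = s + pad, mature_end = s + pad + mature_len[i],
        star_start = s + pad + mature_len[i] + loop_len[i],
        star_end = s + pad + 2L * mature_len[i] + loop_len[i],
        known = i <= config$n_known,
        expression_weight = rlnorm(1, 0, config$expr_sigma),
        precursor_seq = pre
      )
    })
    planted <- bind_rows(rows)
    # splice precursors into the genome
    for (i in seq_len(nrow(planted))) {
      substr(genome, planted$start[i] + 1L, planted$end[i]) <-
        planted$precursor_seq[i]
    }
  }

  pirna_loci <- tibble(name = character(), contig = character(),
                       start = integer(), end = integer())
  if (config$n_pirna_loci > 0L) {
    pl <- place_loci(L, rep(30L, config$n_pirna_loci),
                     occupied = if (config$n_mirs > 0)
                       list(start = planted$start, end = planted$end))
    pirna_loci <- tibble(
      name = sprintf("pirna-locus%02d", seq_len(config$n_pirna_loci)),
      contig = "chr1", start = pl$start, end = pl$end
    )
  }

  contaminants <- list(
    mRNA = tibble(name = paste0("mrna", 1:2), seq = random_seq(2, 500)),
    Rfam = tibble(name = paste0("rfam", 1:2), seq = random_seq(2, 300)),
    Repbase = tibble(name = paste0("repeat", 1:2), seq = random_seq(2, 300))
  )

  list(genome = c(chr1 = genome), planted = planted, pirna_loci = pirna_loci,
       contaminants = contaminants)
}

#' Simulate a small-RNA FASTQ library with ground truth
#'
#' Reads are drawn from the planted miRNA matures (counts proportional to
#' expression weight, with a star-arm share), from piRNA-like loci (24-27 nt
#' windows), from the contaminant references, and as adaptor-adaptor ligation
#' artifacts (insert length 0). The 3' adaptor is appended to every insert and
#' the read truncated to `read_len`; substitution errors are applied at
#' `error_rate`; a `lowq_fraction` of reads receive sub-Q20 qualities.
#'
#' @param sim Output of [sim_genome()].
#' @param config The same [sim_config()].
#' @return List with `reads` (tibble: id, seq, qual) and `truth` (tibble:
#'   id, origin label among mir-mature / mir-star / pirna-like / contaminant /
#'   adaptor-artifact, `source`, true `insert`, `n_errors`,
#'   `errors_in_insert`, `low_quality`).
#' @export
sim_reads <- function(sim, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  N <- config$read_total
  n_art <- round(N * config$artifact_fraction)
  n_con <- round(N * config$contaminant_fraction)
  n_pir <- round((N - n_art - n_con) * config$pirna_share)
  n_mir <- N - n_art - n_con - n_pir
  if (nrow(sim$planted) == 0L && n_mir > 0L) { n_pir <- n_pir + n_mir; n_mir <- 0L }
  if (nrow(sim$pirna_loci) == 0L && n_pir > 0L) { n_mir <- n_mir + n_pir; n_pir <- 0L }

  origin <- character(0); src <- character(0); insert <- character(0)

  if (n_mir > 0L) {
    idx <- sample(nrow(sim$planted), n_mir, replace = TRUE,
                  prob = sim$planted$expression_weight)
    star <- runif(n_mir) < config$star_fraction
    origin <- c(origin, ifelse(star, "mir-star", "mir-mature"))
    src <- c(src, sim$planted$name[idx])
    insert <- c(insert, ifelse(star, sim$planted$star_seq[idx],
                               sim$planted$mature_seq[idx]))
  }
  if (n_pir > 0L) {
    idx <- sample(nrow(sim$pirna_loci), n_pir, replace = TRUE)
    len <- sample(seq(config$pirna_lengths[1], config$pirna_lengths[2]),
                  n_pir, replace = TRUE)
    width <- sim$pirna_loci$end[idx] - sim$pirna_loci$start[idx]
    off <- floor(runif(n_pir) * (width - len + 1L))
    s <- sim$pirna_loci$start[idx] + off
    origin <- c(origin, rep("pirna-like", n_pir))
    src <- c(src, sim$pirna_loci$name[idx])
    insert <- c(insert, substr(rep(sim$genome[[1]], n_pir), s + 1L, s + len))
  }
  if (n_con > 0L) {
    refs <- bind_rows(sim$contaminants, .id = "class")
    idx <- sample(nrow(refs), n_con, replace = TRUE)
    len <- sample(15:30, n_con, replace = TRUE)
    off <- floor(runif(n_con) * (nchar(refs$seq[idx]) - len + 1L))
    origin <- c(origin, rep("contaminant", n_con))
    src <- c(src, refs$name[idx])
    insert <- c(insert, substr(refs$seq[idx], off + 1L, off + len))
  }
  if (n_art > 0L) {
    origin <- c(origin, rep("adaptor-artifact", n_art))
    src <- c(src, rep("adaptor", n_art))
    insert <- c(insert, rep("", n_art))
  }

  # assemble reads: insert + adaptor (repeated to fill), truncated to read_len
  fill <- strrep(config$adaptor,
                 ceiling((config$read_len) / nchar(config$adaptor)) + 1L)
  seq <- substr(paste0(insert, fill), 1L, config$read_len)

  # substitution errors
  n_err <- stats::rbinom(N, config$read_len, config$error_rate)
  err_in_insert <- rep(FALSE, N)
  to_mutate <- which(n_err > 0L)
  for (i in to_mutate) {
    ch <- strsplit(seq[i], "")[[1]]
    pos <- sample(config$read_len, n_err[i])
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    seq[i] <- paste(ch, collapse = "")
    err_in_insert[i] <- any(pos <= nchar(insert[i]))
  }

  lowq <- runif(N) < config$lowq_fraction
  qual <- ifelse(lowq, strrep(intToUtf8(12L + 33L), config$read_len),
                 strrep(intToUtf8(35L + 33L), config$read_len))

  ord <- sample(N)
  id <- sprintf("read%07d", seq_len(N))
  reads <- tibble(id = id, seq = seq[ord], qual = qual[ord])
  truth <- tibble(id = id, origin = origin[ord], source = src[ord],
                  insert = insert[ord], n_errors = n_err[ord],
                  errors_in_insert = err_in_insert[ord],
                  low_quality = lowq[ord])
  list(reads = reads, truth = truth)
}

#' Reference sets derived from the planted miRNAs
#'
#' The species reference holds the matures and precursors of the planted
#' miRNAs flagged `known`; the clade reference adds `clade_extra` invented
#' mature sequences absent from the genome (standing in for a broader-clade
#' miRNA catalogue).
#'
#' @param sim Output of [sim_genome()].
#' @param clade_extra Number of extra clade-only matures.
#' @param seed Seed for the invented clade sequences.
#' @return A `reference_set` (see [reference_set()]).
#' @export
sim_reference_sets <- function(sim, clade_extra = 5L, seed = 99L) {
  set.seed(seed)
  known <- sim$planted |> filter(.data$known)
  extra <- tibble(
    name = sprintf("cla-miR-x%02d", seq_len(clade_extra)),
    seq = random_seq(clade_extra, sample(21:23, clade_extra, replace = TRUE))
  )
  reference_set(
    species_mature = tibble(name = known$name, seq = known$mature_seq),
    species_precursor = tibble(name = paste0(known$name, "-pre"),
                               seq = substr(rep(sim$genome[[1]], nrow(known)),
                                            known$start + 1L, known$end)),
    clade_mature = bind_rows(
      tibble(name = sub("^esi", "cla", known$name), seq = known$mature_seq),
      extra),
    genome = sim$genome
  )
}

#' Simulate a qPCR Ct table
#'
#' Generates technical-triplicate Ct values for each miRNA and the U6
#' normaliser across matched individuals at two stages: Ct = baseline -
#' log2(expression) + individual effect + Gaussian noise, with stage-dependent
#' expression only for the miRNAs (U6 is stage-independent).
#'
#' @param fold_changes Named numeric vector: true MI/GV expression fold change
#'   per miRNA (must be > 0).
#' @param n_individuals Matched individuals per stage (>= 2).
#' @param noise_sd Technical Gaussian noise on Ct, cycles.
#' @param indiv_sd Between-individual baseline SD, cycles.
#' @param stages Two stage labels, reference first.
#' @param n_tech Technical replicates.
#' @param baseline_ct,u6_ct Mean Ct of each miRNA at the reference stage and
#'   of U6.
#' @param seed Integer seed.
#' @return Tibble with `individual`, `stage`, `target`, `rep`, `ct`.
#' @export
sim_qpcr <- function(fold_changes, n_individuals = 4L, noise_sd = 0.25,
                     indiv_sd = 0.3, stages = c("GV", "MI"), n_tech = 3L,
                     baseline_ct = 24, u6_ct = 15, seed = 1L) {
  if (any(fold_changes <= 0)) stop("fold changes must be positive", call. = FALSE)
  stopifnot(n_individuals >= 2L, noise_sd >= 0, length(stages) == 2L)
  set.seed(seed)
  grid <- tidyr::expand_grid(
    individual = sprintf("ind%02d", seq_len(n_individuals)),
    stage = stages,
    target = c(names(fold_changes), "U6"),
    rep = seq_len(n_tech)
  )
  ind_eff <- setNames(rnorm(n_individuals, 0, indiv_sd),
                      sprintf("ind%02d", seq_len(n_individuals)))
  expr <- function(target, stage) {
    ifelse(target == "U6", 1,
           ifelse(stage == stages[2], fold_changes[target], 1))
  }
  grid |>
    mutate(
      base = ifelse(.data$target == "U6", u6_ct, baseline_ct),
      ct = .data$base - log2(expr(.data$target, .data$stage)) +
        ind_eff[.data$individual] + rnorm(n(), 0, noise_sd)
    ) |>
    select(-"base")
}

#' Simulate a dual-luciferase plate
#'
#' Firefly and renilla signals share a per-well transfection-efficiency
#' factor; the knockdown acts multiplicatively on firefly only.
#'
#' @param knockdown Named numeric vector of fractional knockdowns per mimic in
#'   `[0, 1)`; include the negative control with value 0.
#' @param n_rep Wells per mimic.
#' @param cv Log-normal coefficient of variation of the signals.
#' @param construct Construct label.
#' @param base_firefly,base_renilla Mean signals.
#' @param seed Integer seed.
#' @return Tibble with `construct`, `mimic`, `rep`, `firefly`, `renilla`.
#' @export
sim_luciferase <- function(knockdown = c(NC = 0, `miR-2` = 0.4, `miR-7` = 0,
                                         `miR-79` = 0, `miR-133` = 0.4),
                           n_rep = 3L, cv = 0.05, construct = "wt-utr",
                           base_firefly = 10000, base_renilla = 5000,
                           seed = 1L) {
  stopifnot(all(knockdown >= 0), all(knockdown < 1), n_rep >= 2L)
  set.seed(seed)
  tidyr::expand_grid(construct = construct,
                     mimic = names(knockdown), rep = seq_len(n_rep)) |>
    mutate(
      eff = rlnorm(n(), 0, 0.1),
      firefly = base_firefly * (1 - knockdown[.data$mimic]) * .data$eff *
        rlnorm(n(), 0, cv),
      renilla = base_renilla * .data$eff * rlnorm(n(), 0, cv)
    ) |>
    select(-"eff")
}

#' Synthetic 3'-UTR with planted miRNA seed sites
#'
#' Builds a random UTR and plants, for each miRNA, one perfect seed-
#' complementary site (the reverse complement of miRNA positions 2-8) at
#' evenly spaced positions.
#'
#' @param mirnas Named character vector of mature miRNA sequences (RNA or DNA).
#' @param utr_len UTR length, nt.
#' @param seed Integer seed.
#' @return Tibble with `id`, `seq` (RNA), `note`, and an attribute
#'   `planted_sites` (tibble of 0-based site spans).
#' @export
sim_utr <- function(mirnas, utr_len = 600L, seed = 7L) {
  set.seed(seed)
  utr <- dna_to_rna(random_seq(1, utr_len, c("A", "C", "G", "U")))
  k <- length(mirnas)
  sites <- dna_to_rna(revcomp(substr(dna_to_rna(mirnas), 2L, 8L)))
  pos <- floor(seq(50L, utr_len - 60L, length.out = k))
  for (i in seq_len(k)) {
    substr(utr, pos[i] + 1L, pos[i] + 7L) <- sites[i]
  }
  out <- tibble(id = "synthetic_utr", seq = utr,
                note = "synthetic UTR with planted seed sites")
  attr(out, "planted_sites") <- tibble(mirna = names(mirnas), start = pos,
                                       end = pos + 7L)
  out
}
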