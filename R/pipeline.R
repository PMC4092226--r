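# End-to-end orchestration: preprocess -> annotate (+fold) -> optional target
# scan, with a reproducible run summary and standard-format outputs.

#' Pipeline configuration
#'
#' Collects every stage threshold in one validated list that round-trips
#' through JSON losslessly.
#'
#' @param min_mean_q,min_overlap,max_mismatch_adaptor,contaminant_mm,lo,hi,min_copy
#'   Preprocessing thresholds (see the preprocess functions).
#' @param max_mismatch_ref,max_mismatch_genome,seed_region Mapping ceilings
#'   and the exact-match seed band.
#' @param flank,energy_max,pair_min Hairpin-call parameters.
#' @param target_flank,mfe_max Target-scan parameters.
#' @param alpha Significance level for the quant stages.
#' @param seed Integer seed recorded in the provenance block.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_mean_q = 20, min_overlap = 6L,
                            max_mismatch_adaptor = 1L, contaminant_mm = 1L,
                            lo = 15L, hi = 30L, min_copy = 3L,
                            max_mismatch_ref = 2L, max_mismatch_genome = 0L,
                            seed_region = c(2L, 8L), flank = 60L,
                            energy_max = -18, pair_min = 0.6,
                            target_flank = 15L, mfe_max = 0,
                            alpha = 0.05, seed = 42L) {
  cfg <- as.list(environment())
  stopifnot(
    min_mean_q >= 0, min_overlap >= 1, max_mismatch_adaptor >= 0,
    contaminant_mm %in% c(0L, 1L), lo <= hi, lo >= 1, min_copy >= 1,
    max_mismatch_ref >= 0, max_mismatch_genome >= 0,
    length(seed_region) == 2L, seed_region[1] >= 1,
    seed_region[1] <= seed_region[2], flank >= 0, pair_min >= 0, pair_min <= 1,
    alpha > 0, alpha < 1
  )
  structure(cfg, class = "pipeline_config")
}

#' Run the small-RNA pipeline
#'
#' Preprocesses raw reads into unique tags, maps and classifies them against
#' the references and genome (folding candidate precursor loci), and, when a
#' UTR and miRNA set are supplied, scans the UTR for target sites of the
#' called known miRNAs.
#'
#' @param reads Raw read tibble (`id`, `seq`, `qual`).
#' @param adaptor 3' adaptor sequence.
#' @param refset A [reference_set()] (with genome).
#' @param contaminants Optional contaminant reference list.
#' @param utr Optional UTR record for the target stage.
#' @param target_mirnas Optional named character vector of mature miRNAs to
#'   scan against `utr` (defaults to the called known miRNA tag sequences).
#' @param config A [pipeline_config()].
#' @return Object of class `ovamir_run`: `report`, `calls`, `profiles`,
#'   `group_counts`, `n_families`, `histogram`, `targets` (or NULL),
#'   `contaminants_removed`, `provenance`.
#' @export
run_pipeline <- function(reads, adaptor, refset, contaminants = NULL,
                         utr = NULL, target_mirnas = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  message("[preprocess] ", nrow(reads), " raw reads")
  pp <- preprocess_reads(reads, adaptor, contaminants,
                         min_mean_q = config$min_mean_q,
                         min_overlap = config$min_overlap,
                         max_mismatch_adaptor = config$max_mismatch_adaptor,
                         contaminant_mm = config$contaminant_mm,
                         lo = config$lo, hi = config$hi,
                         min_copy = config$min_copy)
  message("[preprocess] ", nrow(pp$tags), " unique tags after filtering")
  hist <- length_histogram(pp$tags, config$lo, config$hi)

  ann <- annotate_tags(pp$tags, refset,
                       max_mismatch_ref = config$max_mismatch_ref,
                       max_mismatch_genome = config$max_mismatch_genome,
                       seed = config$seed_region, flank = config$flank,
                       energy_max = config$energy_max,
                       pair_min = config$pair_min)
  message("[annotate] ", sum(!is.na(ann$calls$group)), " classified tags")

  targets <- NULL
  if (!is.null(utr)) {
    if (is.null(target_mirnas)) {
      known <- ann$calls |> filter(.data$status == "known")
      target_mirnas <- setNames(known$seq, known$assigned_name)
      target_mirnas <- target_mirnas[!duplicated(names(target_mirnas))]
    }
    if (length(target_mirnas)) {
      targets <- scan_targets(target_mirnas, utr, seed = config$seed_region,
                              flank = config$target_flank,
                              mfe_max = config$mfe_max)
      message("[target] ", nrow(targets), " duplex sites")
    }
  }

  n_families <- ann$calls |>
    filter(.data$status == "known", !is.na(.data$family)) |>
    pull("family") |> dplyr::n_distinct()

  structure(list(
    report = pp$report,
    contaminants_removed = pp$contaminants_removed,
    histogram = hist,
    calls = ann$calls,
    profiles = ann$profiles,
    group_counts = ann$group_counts,
    n_families = n_families,
    targets = targets,
    provenance = list(
      package = "ovamir",
      version = as.character(utils::packageVersion("ovamir")),
      seed = config$seed,
      config_hash = rlang::hash(unclass(config))
    )
  ), class = "ovamir_run")
}

#' @export
print.ovamir_run <- function(x, ...) {
  cat("ovamir run\n")
  cat("  reads:", x$report$reads[x$report$stage == "raw"], "raw ->",
      x$report$reads[x$report$stage == "copy"], "surviving\n")
  cat("  unique tags:", x$report$unique[x$report$stage == "copy"], "\n")
  counts <- setNames(x$group_counts$unique, x$group_counts$group)
  cat("  groups:", paste(sprintf("g%s=%d", names(counts), counts),
                         collapse = " "), "\n")
  st <- table(x$calls$status)
  cat("  status:", paste(sprintf("%s=%d", names(st), st), collapse = " "), "\n")
  cat("  known seed families:", x$n_families, "\n")
  if (!is.null(x$targets)) cat("  target sites:", nrow(x$targets), "\n")
  invisible(x)
}

#' Write all pipeline artifacts
#'
#' Emits the standard outputs of a run into `outdir`: the filter report,
#' call table and per-class contaminant counts as TSV, known/novel/star tag
#' FASTA (headers `name_xCOUNT`), genome hits as BED6, the target report as
#' TSV, and a single JSON run summary.
#'
#' @param run An `ovamir_run`.
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_outputs <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  w <- function(name, writer) {
    p <- file.path(outdir, name)
    writer(p)
    paths[[name]] <<- p
  }
  w("filter_report.tsv", \(p) readr::write_tsv(run$report, p))
  w("calls.tsv", \(p) readr::write_tsv(run$calls, p))
  if (!is.null(run$contaminants_removed)) {
    w("contaminants_removed.tsv",
      \(p) readr::write_tsv(run$contaminants_removed, p))
  }
  w("length_histogram.tsv", \(p) readr::write_tsv(run$histogram, p))

  fasta_of <- function(status) {
    run$calls |>
      filter(.data$status == !!status) |>
      mutate(name = sprintf("%s|%s_x%d", .data$assigned_name, .data$tag_id,
                            .data$count)) |>
      select("name", "seq")
  }
  w("known.fasta", \(p) write_fasta(fasta_of("known"), p))
  w("novel.fasta", \(p) write_fasta(fasta_of("novel-candidate"), p))
  w("star.fasta", \(p) write_fasta(fasta_of("star"), p))

  gh <- run$profiles$genome_hits |>
    left_join(run$calls |> select("tag_id", "count"), by = "tag_id")
  w("genome_hits.bed", \(p) write_bed(gh, p))

  if (!is.null(run$targets)) {
    w("targets.tsv",
      \(p) readr::write_tsv(run$targets |> select(-"pairing"), p))
  }
  summary <- list(
    report = run$report,
    group_counts = run$group_counts,
    status_counts = as.list(table(run$calls$status)),
    n_families = run$n_families,
    provenance = run$provenance
  )
  w("summary.json", \(p) jsonlite::write_json(summary, p, auto_unbox = TRUE,
                                              digits = NA, pretty = TRUE))
  invisible(unlist(paths))
}

#' Length-distribution plot
#'
#' The classic two-panel small-RNA figure: per-length totals of all reads and
#' of unique tags over the 15-30 nt window.
#'
#' @param histogram Tibble from [length_histogram()] (or a tag tibble, which
#'   is histogrammed first).
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(histogram) {
  if (!"reads" %in% names(histogram)) histogram <- length_histogram(histogram)
  long <- histogram |>
    tidyr::pivot_longer(c("reads", "unique"), names_to = "panel",
                        values_to = "count") |>
    mutate(panel = dplyr::recode(.data$panel, reads = "total reads",
                                 unique = "unique tags"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$length, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "read length (nt)", y = NULL) +
    ggplot2::theme_minimal()
}
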