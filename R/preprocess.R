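# Read cleanup: quality filtering, 3' adaptor trimming, contaminant removal,
# length window, collapsing to unique tags and the copy-number filter.
# The fixed stage order is quality -> adaptor -> contaminant -> length ->
# collapse -> copy; contaminant matching runs at the read level so the
# per-class removal counts are in reads as well as tags.

#' Quality filter
#'
#' Retains reads whose mean PHRED+33 quality is at least `min_mean_q`; reads
#' containing `N` are removed at this stage as unresolvable.
#'
#' @param reads Tibble with `id`, `seq`, `qual`.
#' @param min_mean_q Minimum mean quality (default 20).
#' @return The filtered read tibble.
#' @export
quality_filter <- function(reads, min_mean_q = 20) {
  keep <- phred_mean(reads$qual) >= min_mean_q &
    !stringr::str_detect(reads$seq, "N")
  reads[keep, , drop = FALSE]
}

#' 3' adaptor trimming
#'
#' Locates the best adaptor occurrence as the prefix of the adaptor aligned to
#' a suffix of the read: overlap of at least `min_overlap` bases with at most
#' `max_mismatch` mismatches, preferring fewer mismatches and then the longest
#' overlap. A best overlap covering the whole read (insert length 0) is an
#' adaptor-adaptor ligation artifact; a read with no detectable adaptor has no
#' insert evidence. Neither survives downstream, but both are labelled rather
#' than silently dropped.
#'
#' @param reads Tibble with `id`, `seq` and optionally `qual`.
#' @param adaptor 3' adaptor sequence (DNA).
#' @param min_overlap Minimum adaptor overlap, nt (default 6).
#' @param max_mismatch Maximum mismatches within the overlap (default 1).
#' @return The input tibble with `seq`/`qual` replaced by the trimmed insert
#'   and a `trim_status` column: `trimmed`, `adaptor_artifact` or
#'   `no_adaptor`.
#' @export
trim_adaptor <- function(reads, adaptor, min_overlap = 6L, max_mismatch = 1L) {
  stopifnot(nchar(adaptor) >= 1L)
  adaptor <- toupper(adaptor)
  n <- nrow(reads)
  best_mm <- rep(Inf, n)
  best_k <- rep(NA_integer_, n)
  w <- nchar(reads$seq)
  for (len in unique(w)) {
    idx <- which(w == len)
    sq <- reads$seq[idx]
    bm <- rep(Inf, length(idx)); bk <- rep(NA_integer_, length(idx))
    for (k in 0:max(0L, len - min_overlap)) {
      s <- min(nchar(adaptor), len - k)
      if (s < min_overlap) break
      mm <- integer(length(idx))
      for (p in seq_len(s)) {
        mm <- mm + (substr(sq, k + p, k + p) != substr(adaptor, p, p))
      }
      upd <- mm < bm
      bm[upd] <- mm[upd]; bk[upd] <- k
    }
    best_mm[idx] <- bm; best_k[idx] <- bk
  }
  ok <- best_mm <= max_mismatch & !is.na(best_k)
  status <- dplyr::case_when(
    ok & best_k == 0L ~ "adaptor_artifact",
    ok ~ "trimmed",
    TRUE ~ "no_adaptor"
  )
  out <- reads
  ins_k <- ifelse(status == "trimmed", best_k, 0L)
  out$seq <- substr(reads$seq, 1L, ins_k)
  if ("qual" %in% names(out)) out$qual <- substr(reads$qual, 1L, ins_k)
  out$trim_status <- status
  out
}

#' Length window filter
#'
#' Retains sequences with `lo <= length <= hi` (inclusive; defaults 15-30 nt).
#'
#' @param x Tibble with a `seq` column (reads or tags).
#' @param lo,hi Inclusive bounds, nt.
#' @return The filtered tibble.
#' @export
length_filter <- function(x, lo = 15L, hi = 30L) {
  stopifnot(lo <= hi)
  x[nchar(x$seq) >= lo & nchar(x$seq) <= hi, , drop = FALSE]
}

#' Collapse reads into unique tags
#'
#' One tag per distinct sequence, with its copy number. Ordering is
#' deterministic: count descending, then sequence lexicographically; stable
#' ids `t000001, ...` are assigned after sorting.
#'
#' @param reads Tibble with a `seq` column (already trimmed).
#' @return Tibble with `tag_id`, `seq`, `count`.
#' @export
collapse_reads <- function(reads) {
  if (nrow(reads) == 0L) {
    return(tibble(tag_id = character(), seq = character(), count = integer()))
  }
  reads |>
    count(.data$seq, name = "count") |>
    arrange(desc(.data$count), .data$seq) |>
    mutate(tag_id = sprintf("t%06d", row_number())) |>
    select("tag_id", "seq", "count")
}

#' Copy-number filter
#'
#' Retains tags sequenced at least `min_copy` times (default 3, i.e. tags with
#' more than two copies).
#'
#' @param tags Tibble with `count`.
#' @param min_copy Minimum copy number (>= 1).
#' @return The filtered tag tibble.
#' @export
copy_filter <- function(tags, min_copy = 3L) {
  stopifnot(min_copy >= 1L)
  tags[tags$count >= min_copy, , drop = FALSE]
}

# all substrings of `subject` of width `len`, as a (pos, key) tibble;
# `pos` is 1-based
window_index <- function(subject, len) {
  L <- nchar(subject)
  if (L < len) return(tibble(pos = integer(), key = character()))
  pos <- seq_len(L - len + 1L)
  tibble(pos = pos, key = substring(subject, pos, pos + len - 1L))
}

# does each of `seqs` occur full-length in any of `refs` with at most `mm`
# mismatches? mm in {0, 1}; mm = 1 uses the split-in-half pigeonhole (one
# half must match exactly), with hashed substring joins and vectorised
# hamming verification of the candidate windows.
match_full_length <- function(seqs, refs, mm = 1L) {
  stopifnot(mm %in% c(0L, 1L))
  hit <- logical(length(seqs))
  if (!length(seqs) || !length(refs)) return(hit)
  w <- nchar(seqs)
  for (len in unique(w)) {
    idx <- which(w == len)
    parts <- if (mm == 0L) {
      list(c(1L, len))
    } else {
      h <- len %/% 2L
      list(c(1L, h), c(h + 1L, len))
    }
    found <- logical(length(idx))
    for (pt in parts) {
      pw <- pt[2] - pt[1] + 1L
      pat <- substr(seqs[idx], pt[1], pt[2])
      for (r in seq_along(refs)) {
        wi <- window_index(refs[r], pw)
        cand <- tibble(t_ix = seq_along(idx), key = pat) |>
          inner_join(wi, by = "key", relationship = "many-to-many") |>
          mutate(wstart = .data$pos - (pt[1] - 1L)) |>
          filter(.data$wstart >= 1L,
                 .data$wstart + len - 1L <= nchar(refs[r]),
                 !found[.data$t_ix])
        if (!nrow(cand)) next
        win <- substr(rep(refs[r], nrow(cand)), cand$wstart,
                      cand$wstart + len - 1L)
        ok <- hamming_var(seqs[idx][cand$t_ix], win) <= mm
        found[unique(cand$t_ix[ok])] <- TRUE
      }
    }
    hit[idx] <- found
  }
  hit
}

#' Contaminant removal
#'
#' Removes reads/tags whose sequence occurs full-length in any contaminant
#' reference (mRNA-like, structural-RNA-like, repeat-like, ...) with at most
#' `mm` mismatches. Empty reference classes are skipped with a message.
#'
#' @param x Tibble with a `seq` column.
#' @param contaminants Named list of reference tibbles (`name`, `seq`), one
#'   per class.
#' @param mm Maximum mismatches over the full tag length (0 or 1; default 1).
#' @return List with `data` (retained rows) and `removed` (tibble: class,
#'   n_reads, n_unique removed per class; a row per class).
#' @export
contaminant_filter <- function(x, contaminants, mm = 1L) {
  uniq <- unique(x$seq)
  removed_class <- rep(NA_character_, length(uniq))
  for (cls in names(contaminants)) {
    refs <- contaminants[[cls]]
    if (is.null(refs) || nrow(refs) == 0L) {
      message("contaminant class '", cls, "' is empty; skipped")
      next
    }
    open <- is.na(removed_class)
    if (!any(open)) break
    hits <- match_full_length(uniq[open], refs$seq, mm)
    removed_class[open][hits] <- cls
  }
  cls_of <- setNames(removed_class, uniq)
  x_cls <- cls_of[x$seq]
  removed <- tibble(class = names(contaminants)) |>
    mutate(
      n_reads = vapply(.data$class, function(cl)
        sum(x_cls == cl, na.rm = TRUE), integer(1), USE.NAMES = FALSE),
      n_unique = vapply(.data$class, function(cl)
        sum(removed_class == cl, na.rm = TRUE), integer(1),
        USE.NAMES = FALSE)
    )
  list(data = x[is.na(x_cls), , drop = FALSE], removed = removed)
}

#' Per-length totals of reads and unique tags
#'
#' The two histograms behind the classic small-RNA length-distribution figure:
#' total read counts and unique tag counts per length over the 15-30 nt
#' window.
#'
#' @param tags Tibble with `seq`, `count` (all lengths within 15-30 nt).
#' @param lo,hi Histogram range (defaults 15, 30).
#' @return Tibble with `length`, `reads`, `unique`.
#' @export
length_histogram <- function(tags, lo = 15L, hi = 30L) {
  w <- nchar(tags$seq)
  if (nrow(tags) > 0L && (min(w) < lo || max(w) > hi)) {
    stop("tags outside the ", lo, "-", hi, " nt window", call. = FALSE)
  }
  tibble(length = lo:hi) |>
    mutate(
      reads = vapply(.data$length, function(l)
        sum(tags$count[w == l]), numeric(1)),
      unique = vapply(.data$length, function(l)
        sum(w == l), numeric(1))
    )
}

#' Full preprocessing stage
#'
#' Runs quality -> adaptor -> contaminant -> length -> collapse -> copy and
#' assembles the per-stage accounting (reads and unique sequences at each
#' stage).
#'
#' @param reads Raw read tibble (`id`, `seq`, `qual`).
#' @param adaptor 3' adaptor sequence.
#' @param contaminants Optional named list of contaminant reference tibbles.
#' @param min_mean_q,min_overlap,max_mismatch_adaptor,contaminant_mm,lo,hi,min_copy
#'   Stage thresholds; see the individual filters.
#' @return List with `tags` (final unique tags), `report` (tibble: stage,
#'   reads, unique), and `contaminants_removed` (per-class counts).
#' @export
preprocess_reads <- function(reads, adaptor, contaminants = NULL,
                             min_mean_q = 20, min_overlap = 6L,
                             max_mismatch_adaptor = 1L, contaminant_mm = 1L,
                             lo = 15L, hi = 30L, min_copy = 3L) {
  acc <- function(stage, d, n_reads = nrow(d)) {
    tibble(stage = stage, reads = n_reads, unique = dplyr::n_distinct(d$seq))
  }
  report <- acc("raw", reads)
  d <- quality_filter(reads, min_mean_q)
  report <- bind_rows(report, acc("quality", d))
  d <- trim_adaptor(d, adaptor, min_overlap, max_mismatch_adaptor) |>
    filter(.data$trim_status == "trimmed") |>
    select(-"trim_status")
  report <- bind_rows(report, acc("adaptor", d))
  removed <- NULL
  if (!is.null(contaminants)) {
    cf <- contaminant_filter(d, contaminants, contaminant_mm)
    d <- cf$data
    removed <- cf$removed
  }
  report <- bind_rows(report, acc("contaminant", d))
  d <- length_filter(d, lo, hi)
  report <- bind_rows(report, acc("length", d))
  tags <- collapse_reads(d)
  report <- bind_rows(report,
                      tibble(stage = "collapse", reads = sum(tags$count),
                             unique = nrow(tags)))
  tags <- copy_filter(tags, min_copy)
  report <- bind_rows(report,
                      tibble(stage = "copy", reads = sum(tags$count),
                             unique = nrow(tags)))
  list(tags = tags, report = report, contaminants_removed = removed)
}
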