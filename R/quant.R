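# Relative-expression statistics: qPCR 2^-ddCt against an endogenous control
# with paired testing between stages, and dual-luciferase ratio normalisation
# with one-way ANOVA and comparisons against the negative control.

#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged per (individual, stage, target); dCt is
#' the target Ct minus the normaliser Ct for the same sample; ddCt subtracts
#' the mean reference-stage dCt; the fold change is `2^-ddCt`. Stages are
#' compared with a paired t-test on dCt over matched individuals (Welch
#' fallback, flagged, when no complete pairs exist). Samples missing the
#' normaliser are excluded with a message.
#'
#' @param records Ct tibble: `individual`, `stage`, `target`, `rep`, `ct`
#'   (cycles, in (0, 40]).
#' @param reference_stage Stage label used as the calibrator (default "GV").
#' @param normalizer Endogenous-control target name (default "U6").
#' @param alpha Significance level (default 0.05).
#' @return Object of class `ddct_result`: list with `per_sample` (per
#'   individual dCt/ddCt/fold), `summary` (per miRNA and non-reference stage:
#'   n, mean_fold, se_fold, t, df, p_value, paired, significant), and the
#'   settings.
#' @export
ddct <- function(records, reference_stage = "GV", normalizer = "U6",
                 alpha = 0.05) {
  stopifnot(all(c("individual", "stage", "target", "ct") %in% names(records)))
  if (any(records$ct <= 0 | records$ct > 40)) {
    stop("Ct values must lie in (0, 40]", call. = FALSE)
  }
  if (!reference_stage %in% records$stage) {
    stop("reference stage '", reference_stage, "' absent from records",
         call. = FALSE)
  }
  tech <- records |>
    group_by(.data$individual, .data$stage, .data$target) |>
    summarise(ct = mean(.data$ct), .groups = "drop")
  norm <- tech |>
    filter(.data$target == normalizer) |>
    select("individual", "stage", norm_ct = "ct")
  d <- tech |>
    filter(.data$target != normalizer) |>
    left_join(norm, by = c("individual", "stage"))
  dropped <- d |> filter(is.na(.data$norm_ct))
  if (nrow(dropped)) {
    message(nrow(dropped), " sample(s) lack ", normalizer, " and were excluded")
    d <- d |> filter(!is.na(.data$norm_ct))
  }
  d <- d |> mutate(dct = .data$ct - .data$norm_ct)
  ref_means <- d |>
    filter(.data$stage == reference_stage) |>
    group_by(.data$target) |>
    summarise(ref_dct = mean(.data$dct), .groups = "drop")
  per_sample <- d |>
    inner_join(ref_means, by = "target") |>
    mutate(ddct = .data$dct - .data$ref_dct,
           fold = 2^-.data$ddct) |>
    select("individual", "stage", mirna = "target", "dct", "ddct", "fold")

  test_one <- function(sub) {
    ref <- sub |> filter(.data$stage == reference_stage)
    alt <- sub |> filter(.data$stage != reference_stage)
    paired_ids <- intersect(ref$individual, alt$individual)
    safe_t <- function(...) {
      # zero-variance (e.g. noise-free simulated) data has no defined t
      tryCatch(t.test(...), error = function(e) NULL)
    }
    if (length(paired_ids) >= 2L) {
      tt <- safe_t(alt$dct[match(paired_ids, alt$individual)],
                   ref$dct[match(paired_ids, ref$individual)],
                   paired = TRUE)
      paired <- TRUE
    } else if (nrow(ref) >= 2L && nrow(alt) >= 2L) {
      tt <- safe_t(alt$dct, ref$dct, paired = FALSE)
      paired <- FALSE
    } else {
      tt <- NULL; paired <- NA
    }
    if (is.null(tt)) {
      return(tibble(t = NA_real_, df = NA_real_, p_value = NA_real_,
                    paired = paired))
    }
    tibble(t = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value, paired = paired)
  }

  summary <- per_sample |>
    filter(.data$stage != reference_stage) |>
    group_by(.data$mirna, .data$stage) |>
    summarise(n = n(), mean_fold = mean(.data$fold),
              se_fold = sd(.data$fold) / sqrt(n()), .groups = "drop")
  tests <- per_sample |>
    group_by(.data$mirna) |>
    dplyr::group_modify(~ test_one(.x)) |>
    ungroup()
  summary <- summary |>
    left_join(tests, by = "mirna") |>
    mutate(significant = !is.na(.data$p_value) & .data$p_value < alpha,
           contrast = paste(.data$stage, "vs", reference_stage))

  structure(list(per_sample = per_sample, summary = summary,
                 reference_stage = reference_stage, normalizer = normalizer,
                 alpha = alpha),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat("2^-ddCt relative expression (reference: ", x$reference_stage,
      ", normaliser: ", x$normalizer, ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.ddct_result <- function(x, ...) {
  x$summary |>
    select("mirna", "contrast", "n", estimate = "mean_fold",
           std.error = "se_fold", statistic = "t", "df", p.value = "p_value",
           "paired", "significant")
}

#' @export
glance.ddct_result <- function(x, ...) {
  tibble(n_mirnas = dplyr::n_distinct(x$summary$mirna),
         n_individuals = dplyr::n_distinct(x$per_sample$individual),
         reference_stage = x$reference_stage,
         normalizer = x$normalizer, alpha = x$alpha)
}

#' @export
autoplot.ddct_result <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$mirna, y = .data$mean_fold,
                               fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_fold - .data$se_fold,
                   ymax = .data$mean_fold + .data$se_fold),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(2^-Delta * Delta * "Ct fold change"),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Dual-luciferase ratio normalisation and testing
#'
#' Per-well ratio = firefly / renilla; ratios are scaled so the
#' negative-control mean is 1 within each construct. Because reporter noise is
#' multiplicative, the model is fitted on log-ratios (variance-stabilising);
#' estimates are reported back on the ratio scale as geometric means. Mimic
#' groups are compared by one-way ANOVA within each construct, followed by
#' two-sided comparisons of each mimic against the negative control: Dunnett
#' contrasts on the ANOVA fit (default), Holm-adjusted Welch t-tests, or
#' unadjusted t-tests.
#'
#' @param records Tibble: `construct`, `mimic`, `rep`, `firefly`, `renilla`
#'   (signals must be positive; offending rows are rejected with an error).
#' @param negative_control Mimic label of the negative control (default "NC").
#' @param method Post-hoc method: `"dunnett"`, `"holm-t"` or `"none"`.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Object of class `luciferase_result`: `wells` (normalised ratios),
#'   `anova` (per construct: F, df, p), `comparisons` (per construct and
#'   mimic: mean relative activity, p_value, significant).
#' @export
luciferase_ratios <- function(records, negative_control = "NC",
                              method = c("dunnett", "holm-t", "none"),
                              alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(all(c("construct", "mimic", "firefly", "renilla") %in%
                  names(records)))
  bad <- which(records$firefly <= 0 | records$renilla <= 0)
  if (length(bad)) {
    stop("non-positive luciferase signal in row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (!negative_control %in% records$mimic) {
    stop("negative control '", negative_control, "' absent", call. = FALSE)
  }
  wells <- records |>
    mutate(ratio = .data$firefly / .data$renilla) |>
    group_by(.data$construct) |>
    mutate(rel_activity = .data$ratio /
             mean(.data$ratio[.data$mimic == negative_control])) |>
    ungroup()
  n_rep <- wells |> count(.data$construct, .data$mimic)
  if (any(n_rep$n < 2L)) stop("every condition needs >= 2 replicates",
                              call. = FALSE)

  res <- wells |>
    tidyr::nest(data = -"construct") |>
    mutate(fit = purrr::map(.data$data, function(d) {
      d$mimic <- stats::relevel(factor(d$mimic), ref = negative_control)
      aov(log(rel_activity) ~ mimic, data = d)
    }))

  anova_tbl <- res |>
    mutate(s = purrr::map(.data$fit, function(f) {
      a <- summary(f)[[1]]
      tibble(statistic = a$`F value`[1], df = a$Df[1], df_residual = a$Df[2],
             p_value = a$`Pr(>F)`[1])
    })) |>
    select("construct", "s") |>
    tidyr::unnest("s")

  cmp_one <- function(d, fit) {
    d$mimic <- stats::relevel(factor(d$mimic), ref = negative_control)
    grp <- d |>
      filter(.data$mimic != negative_control) |>
      group_by(mimic = as.character(.data$mimic)) |>
      summarise(estimate = exp(mean(log(.data$rel_activity))),
                .groups = "drop")
    if (method == "dunnett") {
      sm <- tryCatch(summary(multcomp::glht(
        fit, linfct = multcomp::mcp(mimic = "Dunnett")))$test,
        error = function(e) NULL)
      grp$p_value <- if (is.null(sm)) NA_real_ else {
        nm <- sub(" - .*$", "", names(sm$coefficients))
        sm$pvalues[match(grp$mimic, nm)]
      }
    } else {
      nc <- log(d$rel_activity[d$mimic == negative_control])
      grp$p_value <- vapply(grp$mimic, function(g) {
        # degenerate (constant) data has no defined t
        tryCatch(t.test(log(d$rel_activity[d$mimic == g]), nc)$p.value,
                 error = function(e) NA_real_)
      }, numeric(1))
      if (method == "holm-t") grp$p_value <- p.adjust(grp$p_value, "holm")
    }
    grp
  }
  comparisons <- res |>
    mutate(cmp = purrr::map2(.data$data, .data$fit, cmp_one)) |>
    select("construct", "cmp") |>
    tidyr::unnest("cmp") |>
    mutate(significant = !is.na(.data$p_value) & .data$p_value < alpha)

  structure(list(wells = wells |> select(-"ratio"), anova = anova_tbl,
                 comparisons = comparisons, method = method,
                 negative_control = negative_control, alpha = alpha),
            class = "luciferase_result")
}

#' @export
print.luciferase_result <- function(x, ...) {
  cat("Dual-luciferase relative activity (", x$method, " vs ",
      x$negative_control, ")\n", sep = "")
  print(x$comparisons)
  invisible(x)
}

#' @export
tidy.luciferase_result <- function(x, ...) {
  x$comparisons |>
    select("construct", term = "mimic", "estimate", p.value = "p_value",
           "significant")
}

#' @export
glance.luciferase_result <- function(x, ...) {
  x$anova |> mutate(method = x$method, alpha = x$alpha)
}

#' @export
autoplot.luciferase_result <- function(object, ...) {
  sm <- object$wells |>
    group_by(.data$construct, .data$mimic) |>
    summarise(mean = mean(.data$rel_activity),
              se = sd(.data$rel_activity) / sqrt(n()), .groups = "drop")
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$mimic, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.3) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~construct) +
    ggplot2::labs(x = NULL, y = "relative luciferase activity") +
    ggplot2::theme_minimal()
}
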