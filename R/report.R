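#' Person-level mean Ln(HF-HRV)
#'
#' The traditional summary measure: the unweighted mean of Ln(HF) over all
#' valid epochs across a subject's valid days.
#'
#' @param epochs Epoch tibble with `subject_id`, `day_index`, `ln_hf`,
#'   `valid`.
#' @param min_valid_epochs Day-validity threshold; set to `0` to include
#'   epochs from all days.
#' @return Tibble (`subject_id`, `mean_ln_hf`, `n_epochs`); subjects with no
#'   valid epoch are absent.
#' @export
person_level_means <- function(epochs, min_valid_epochs = 100L) {
  days <- day_table(epochs, min_valid_epochs)
  epochs |>
    dplyr::filter(.data$valid, !is.na(.data$ln_hf)) |>
    dplyr::inner_join(days[days$day_valid, c("subject_id", "day_index")],
                      by = c("subject_id", "day_index")) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(mean_ln_hf = mean(.data$ln_hf),
                     n_epochs = dplyr::n(), .groups = "drop")
}

fmt_mean_sd <- function(x) sprintf("%.1f (%.1f)", mean(x), sd(x))
fmt_median_iqr <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  sprintf("%.1f (%.1f, %.1f)", q[2], q[1], q[3])
}
fmt_n_pct <- function(k, n) sprintf("%d (%.0f%%)", k, 100 * k / n)

# expected-count rule: exact test when any expected cell count < 5
categorical_test <- function(tab) {
  if (nrow(tab) < 2 || ncol(tab) < 2)
    return(list(p = NA_real_, test = "none"))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    list(p = fisher.test(tab)$p.value, test = "fisher")
  } else {
    list(p = suppressWarnings(chisq.test(tab, correct = FALSE)$p.value),
         test = "chisq")
  }
}

#' Cohort descriptives stratified by cognitive status
#'
#' Table-1 style summaries of the covariates and person-level mean
#' Ln(HF-HRV), overall and by MCI status, with group-comparison tests:
#' Wilcoxon rank-sum for continuous variables; Pearson chi-squared for
#' categorical variables, switching to Fisher's exact test when any
#' expected cell count is below 5.
#'
#' @param covariates Covariate tibble with `subject_id`, `age`, `sex`,
#'   `ethnicity`, `education`, `mci`, and comorbidity flags.
#' @param person_means Output of [person_level_means()] (optional).
#' @param valid_days Optional per-subject tibble with `n_recorded_days`,
#'   `n_valid_days` (e.g. from [exclusion_report()]).
#' @return A `hrv_cohort_summary`: list with `table` (tidy rows: variable,
#'   statistic, overall, cn, mci, p_value, test) and group counts.
#' @export
summarize_cohort <- function(covariates, person_means = NULL,
                             valid_days = NULL) {
  cov <- covariates
  if (!is.null(person_means))
    cov <- dplyr::left_join(cov, person_means, by = "subject_id")
  if (!is.null(valid_days))
    cov <- dplyr::left_join(cov, valid_days, by = "subject_id")
  grp <- factor(ifelse(cov$mci == 1, "MCI", "CN"), levels = c("CN", "MCI"))
  n <- nrow(cov)
  n_grp <- table(grp)
  both <- all(n_grp > 0)

  rows <- list()
  add_continuous <- function(name, x) {
    keep <- !is.na(x)
    p <- if (both) wilcox.test(x[keep] ~ grp[keep], exact = FALSE)$p.value
         else NA_real_
    per <- function(g) x[keep & grp == g]
    rows[[length(rows) + 1]] <<- tibble::tibble(
      variable = name,
      statistic = c("mean_sd", "median_iqr"),
      overall = c(fmt_mean_sd(x[keep]), fmt_median_iqr(x[keep])),
      cn = c(fmt_mean_sd(per("CN")), fmt_median_iqr(per("CN"))),
      mci = c(fmt_mean_sd(per("MCI")), fmt_median_iqr(per("MCI"))),
      p_value = c(p, NA), test = c(if (both) "wilcoxon" else "none", NA))
  }
  add_categorical <- function(name, x) {
    keep <- !is.na(x)
    x <- factor(x[keep])
    tab <- table(x, grp[keep])
    tst <- if (both) categorical_test(t(tab)) else list(p = NA, test = "none")
    lv <- levels(x)
    rows[[length(rows) + 1]] <<- tibble::tibble(
      variable = name, statistic = lv,
      overall = vapply(lv, function(l) fmt_n_pct(sum(x == l), length(x)), ""),
      cn = vapply(lv, function(l) fmt_n_pct(tab[l, "CN"], sum(tab[, "CN"])), ""),
      mci = vapply(lv, function(l) fmt_n_pct(tab[l, "MCI"], sum(tab[, "MCI"])), ""),
      p_value = c(tst$p, rep(NA, length(lv) - 1)),
      test = c(tst$test, rep(NA, length(lv) - 1)))
  }

  add_continuous("age", cov$age)
  add_continuous("education_years", cov$education)
  add_categorical("sex", cov$sex)
  add_categorical("ethnicity", cov$ethnicity)
  for (v in intersect(c("depression", "diabetes", "hypertension"), names(cov)))
    add_categorical(v, ifelse(cov[[v]] == 1, "yes", "no"))
  if ("n_recorded_days" %in% names(cov))
    add_continuous("n_recorded_days", cov$n_recorded_days)
  if ("n_valid_days" %in% names(cov))
    add_continuous("n_valid_days", cov$n_valid_days)
  if ("mean_ln_hf" %in% names(cov))
    add_continuous("person_mean_ln_hf", cov$mean_ln_hf)

  structure(list(table = dplyr::bind_rows(rows), n = n,
                 n_cn = unname(n_grp["CN"]), n_mci = unname(n_grp["MCI"]),
                 tests_skipped = !both),
            class = "hrv_cohort_summary")
}

#' @export
print.hrv_cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary: N = %d (CN %d, MCI %d%s)\n\n", x$n, x$n_cn,
              x$n_mci,
              if (x$tests_skipped) "; group tests skipped (empty group)"
              else ""))
  print(as.data.frame(x$table), right = FALSE, row.names = FALSE)
  invisible(x)
}

#' Render a cohort summary as a Markdown table
#'
#' @param summary A [summarize_cohort()] result.
#' @return Character vector of Markdown lines.
#' @export
render_table_markdown <- function(summary) {
  tb <- summary$table
  header <- c(
    sprintf("| Characteristic | Full sample (N = %d) | CN (N = %d) | MCI (N = %d) | p |",
            summary$n, summary$n_cn, summary$n_mci),
    "|---|---|---|---|---|")
  body <- sprintf("| %s: %s | %s | %s | %s | %s |",
                  tb$variable, tb$statistic, tb$overall, tb$cn, tb$mci,
                  ifelse(is.na(tb$p_value), "", sprintf("%.3f", tb$p_value)))
  c(header, body)
}

#' Plot observed 24-h profiles with group averages
#'
#' Faded per-subject profiles with bold group-average curves, split by a
#' grouping covariate.
#'
#' @param profiles Output of [build_profiles()].
#' @param covariates Covariate tibble.
#' @param group Covariate column used for coloring (default `"mci"`).
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles, covariates, group = "mci") {
  df <- dplyr::left_join(profiles,
                         covariates[, c("subject_id", group)],
                         by = "subject_id")
  df$grp <- factor(df[[group]])
  df$hour <- bin_to_hour(df$bin)
  avg <- df |>
    dplyr::group_by(.data$grp, .data$hour) |>
    dplyr::summarise(y = mean(.data$y), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hour, y = .data$y,
                                   color = .data$grp)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id), alpha = 0.15) +
    ggplot2::geom_line(data = avg, linewidth = 1.2) +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6)) +
    ggplot2::labs(x = "Time of day (h)", y = "Ln(HF-HRV), ln ms²",
                  color = group) +
    ggplot2::theme_minimal()
}

#' Plot coefficient curves with pointwise confidence bands
#'
#' One panel per coefficient curve: the estimate with its shaded pointwise
#' interval and a zero reference line.
#'
#' @param fit A [fosr_fit()] result.
#' @param level Band level.
#' @param coefficients Curves to show (default all but the intercept).
#' @return A ggplot object.
#' @export
plot_coefficients <- function(fit, level = 0.95, coefficients = NULL) {
  terms <- coefficients %||%
    setdiff(colnames(fit$coefficients), "intercept")
  ci <- pointwise_ci(fit, level, terms)
  ggplot2::ggplot(ci, ggplot2::aes(x = .data$hour, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~coefficient, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6)) +
    ggplot2::labs(x = "Time of day (h)",
                  y = "Effect on Ln(HF-HRV), ln ms²") +
    ggplot2::theme_minimal()
}
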