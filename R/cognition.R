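#' @rdname classify_jak_bondi
#' @format NULL
#' @export
NEUROPSYCH_INSTRUMENTS <- c(
  "memory_fcsrt_free_recall", "memory_benson_delayed",
  "exec_trails_b", "exec_phonemic_fluency",
  "attn_trails_a", "attn_number_span",
  "lang_mint", "lang_category_fluency",
  "visuo_benson_immediate", "visuo_block_design")

NEUROPSYCH_DOMAINS <- c("memory", "executive", "attention", "language",
                        "visuospatial")

#' Actuarial MCI classification (Jak/Bondi criteria)
#'
#' Classifies a subject as MCI or cognitively normal (CN) from
#' age-, sex-, and education-adjusted z-scores on a 10-instrument battery
#' (two measures in each of five domains) plus the Lawton-Brody count of
#' dependent instrumental-activity items. A score is impaired when it lies
#' strictly more than `cutoff_sd` SD below the normative mean (z = -1
#' exactly is unimpaired). MCI is met by any of:
#' \itemize{
#'   \item rule 1 - both measures impaired within at least one domain;
#'   \item rule 2 - at least one impaired measure in each of three of the
#'     five domains;
#'   \item rule 3 - Lawton-Brody score of 4 (dependent on all four
#'     instrumental-activity items).
#' }
#'
#' @param z Numeric vector of 10 z-scores ordered as
#'   `NEUROPSYCH_INSTRUMENTS` (two consecutive scores per domain), or a
#'   named vector/list containing those names.
#' @param lawton_brody Integer in 0-4.
#' @param cutoff_sd Impairment cutoff in SD units (default 1).
#' @param rule1_domains Domains over which rule 1 is applied; default all
#'   five.
#' @return List with `status` ("MCI"/"CN"), `rules_fired` (character), and
#'   `trace` (per-domain impairment detail).
#' @export
#' @examples
#' classify_jak_bondi(c(-1.2, -1.4, rep(0, 8)), 0)$status  # "MCI" via rule 1
classify_jak_bondi <- function(z, lawton_brody, cutoff_sd = 1.0,
                               rule1_domains = NEUROPSYCH_DOMAINS) {
  if (!is.null(names(z)) && all(NEUROPSYCH_INSTRUMENTS %in% names(z)))
    z <- as.numeric(unlist(z)[NEUROPSYCH_INSTRUMENTS])
  z <- as.numeric(z)
  if (length(z) != 10L)
    stop("expected 10 instrument z-scores", call. = FALSE)
  missing_z <- which(is.na(z))
  if (length(missing_z) > 0)
    stop("missing score for instrument: ",
         paste(NEUROPSYCH_INSTRUMENTS[missing_z], collapse = ", "),
         call. = FALSE)
  if (is.na(lawton_brody) || lawton_brody < 0 || lawton_brody > 4)
    stop("lawton_brody must be an integer in 0-4", call. = FALSE)

  impaired <- z < -cutoff_sd  # strictly more than cutoff_sd below the mean
  by_domain <- matrix(impaired, nrow = 2,
                      dimnames = list(NULL, NEUROPSYCH_DOMAINS))
  both <- colSums(by_domain) == 2L
  any_imp <- colSums(by_domain) >= 1L

  rule1 <- any(both[rule1_domains])
  rule2 <- sum(any_imp) >= 3L
  rule3 <- lawton_brody == 4L
  fired <- c("rule1_two_impaired_one_domain",
             "rule2_one_impaired_three_domains",
             "rule3_lawton_brody_dependent")[c(rule1, rule2, rule3)]
  list(status = if (length(fired) > 0) "MCI" else "CN",
       rules_fired = fired,
       trace = list(impaired = stats::setNames(impaired,
                                               NEUROPSYCH_INSTRUMENTS),
                    domain_both_impaired = both,
                    domain_any_impaired = any_imp,
                    lawton_brody = lawton_brody))
}

#' Per-domain impairment flags (rule-1 criterion per domain)
#'
#' A domain is flagged when both of its measures fall strictly more than
#' `cutoff_sd` SD below the normative mean; these flags drive the
#' domain-specific model runs (the MCI indicator replaced by one domain's
#' flag).
#'
#' @inheritParams classify_jak_bondi
#' @return Named logical vector over the five domains.
#' @export
domain_impairment_flags <- function(z, cutoff_sd = 1.0) {
  if (!is.null(names(z)) && all(NEUROPSYCH_INSTRUMENTS %in% names(z)))
    z <- as.numeric(unlist(z)[NEUROPSYCH_INSTRUMENTS])
  z <- as.numeric(z)
  if (length(z) != 10L || any(is.na(z)))
    stop("expected 10 non-missing instrument z-scores", call. = FALSE)
  impaired <- matrix(z < -cutoff_sd, nrow = 2)
  stats::setNames(colSums(impaired) == 2L, NEUROPSYCH_DOMAINS)
}

#' Classify a cohort scores table
#'
#' @param scores Tibble with `subject_id`, the 10 instrument z-score columns
#'   (`NEUROPSYCH_INSTRUMENTS`), and `lawton_brody`.
#' @inheritParams classify_jak_bondi
#' @return Tibble with `subject_id`, `status`, `mci` (0/1), `rules_fired`
#'   (comma-separated), and the five domain flags.
#' @export
classify_cohort <- function(scores, cutoff_sd = 1.0,
                            rule1_domains = NEUROPSYCH_DOMAINS) {
  missing_cols <- setdiff(c(NEUROPSYCH_INSTRUMENTS, "lawton_brody"),
                          names(scores))
  if (length(missing_cols) > 0)
    stop("scores table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  res <- lapply(seq_len(nrow(scores)), function(i) {
    z <- as.numeric(scores[i, NEUROPSYCH_INSTRUMENTS])
    cls <- classify_jak_bondi(z, scores$lawton_brody[i], cutoff_sd,
                              rule1_domains)
    flags <- domain_impairment_flags(z, cutoff_sd)
    tibble::tibble(subject_id = scores$subject_id[i], status = cls$status,
                   mci = as.integer(cls$status == "MCI"),
                   rules_fired = paste(cls$rules_fired, collapse = ","),
                   !!!as.list(stats::setNames(flags,
                       paste0("impaired_", NEUROPSYCH_DOMAINS))))
  })
  dplyr::bind_rows(res)
}
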