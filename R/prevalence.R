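#' Presence/absence counts per feature
#'
#' Tabulates, for every feature, in how many control and experimental
#' samples it is detected.  Detection means a count of at least
#' `detect_min` reads (default 1, i.e. any nonzero count).
#'
#' @param table feature table.
#' @param metadata sample metadata with at least one control and one
#'   experimental sample present in the table.
#' @param detect_min minimum count regarded as presence (default 1).
#' @return data.frame with columns `feature_id`, `k_ctrl`, `n_ctrl`,
#'   `k_exp`, `n_exp`.
#' @export
presence_counts <- function(table, metadata, detect_min = 1) {
  validate_metadata(metadata, table)
  ctrl <- intersect(metadata$sample_id[metadata$role == "control"], colnames(table))
  expt <- intersect(metadata$sample_id[metadata$role == "experimental"], colnames(table))
  if (length(ctrl) == 0L || length(expt) == 0L) {
    stop_metadata("need at least one control and one experimental sample")
  }
  present <- table >= detect_min
  data.frame(
    feature_id = rownames(table),
    k_ctrl = rowSums(present[, ctrl, drop = FALSE]),
    n_ctrl = length(ctrl),
    k_exp = rowSums(present[, expt, drop = FALSE]),
    n_exp = length(expt),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# One-sided hypergeometric tail (= one-sided Fisher's exact test) that the
# number of presence calls falling in the control group is at least the
# observed k_ctrl, conditioning on both margins.
prevalence_fisher_p <- function(k_ctrl, n_ctrl, k_exp, n_exp) {
  stats::phyper(k_ctrl - 1, n_ctrl, n_exp, k_ctrl + k_exp, lower.tail = FALSE)
}

# Pearson chi-square p-value (no continuity correction) for the 2x2
# presence table; identical to chisq.test(correct = FALSE) but vectorised.
prevalence_chisq_p <- function(k_ctrl, n_ctrl, k_exp, n_exp) {
  a <- k_ctrl; b <- k_exp
  c_ <- n_ctrl - k_ctrl; d <- n_exp - k_exp
  n <- n_ctrl + n_exp
  denom <- (a + b) * (c_ + d) * n_ctrl * n_exp
  stat <- ifelse(denom > 0, n * (a * d - b * c_)^2 / denom, 0)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Prevalence-based contaminant score
#'
#' One-sided score on the 2x2 presence/absence table of a feature in
#' control versus experimental samples: a small score indicates the
#' feature is detected more often in controls, the expected signature of a
#' reagent contaminant.
#'
#' The default (`method = "auto"`) uses the Pearson chi-square test without
#' continuity correction, halved and directed by the sign of the prevalence
#' difference (`k_ctrl/n_ctrl - k_exp/n_exp`), so that features more
#' prevalent in experimental samples score at least 0.5 and are never
#' classified.  Whenever any expected cell of the 2x2 table is below 5 the
#' asymptotic test is unreliable and the one-sided Fisher exact test (a
#' hypergeometric tail) is substituted.  Degenerate margins — a feature
#' present in every sample of both groups, or absent everywhere — carry no
#' information and score 1.
#'
#' Absolute scores from other prevalence-based implementations may differ
#' in their tail conventions; the ordering and the monotonicity in
#' (`k_ctrl`, `k_exp`) are the properties this score is built to preserve.
#'
#' @param k_ctrl,n_ctrl detections and totals among control samples.
#' @param k_exp,n_exp detections and totals among experimental samples.
#' @param method `"auto"` (expected-cell rule, with directed chi-square
#'   and degenerate handling), `"fisher"` (raw one-sided hypergeometric
#'   tail), or `"chisq"` (directed half chi-square).  Vectorised.
#' @return numeric vector of scores in \[0, 1\].
#' @export
prevalence_score <- function(k_ctrl, n_ctrl, k_exp, n_exp,
                             method = c("auto", "fisher", "chisq")) {
  method <- match.arg(method)
  k_ctrl <- as.numeric(k_ctrl); k_exp <- as.numeric(k_exp)
  n_ctrl <- as.numeric(n_ctrl); n_exp <- as.numeric(n_exp)
  if (any(n_ctrl < 1) || any(n_exp < 1)) {
    stop_validation("need n_ctrl >= 1 and n_exp >= 1")
  }
  if (any(k_ctrl < 0 | k_ctrl > n_ctrl) || any(k_exp < 0 | k_exp > n_exp)) {
    stop_validation("presence counts must satisfy 0 <= k <= n")
  }
  if (method == "fisher") {
    return(prevalence_fisher_p(k_ctrl, n_ctrl, k_exp, n_exp))
  }
  diff <- k_ctrl / n_ctrl - k_exp / n_exp
  if (method == "chisq") {
    half <- prevalence_chisq_p(k_ctrl, n_ctrl, k_exp, n_exp) / 2
    return(ifelse(diff > 0, half, pmax(1 - half, 0.5)))
  }
  # auto: degenerate margins -> 1; small expected cells -> Fisher
  kk <- k_ctrl + k_exp
  n <- n_ctrl + n_exp
  degenerate <- kk == 0 | kk == n
  min_expected <- pmin(kk * n_ctrl, kk * n_exp, (n - kk) * n_ctrl, (n - kk) * n_exp) / n
  use_fisher <- min_expected < 5
  half <- prevalence_chisq_p(k_ctrl, n_ctrl, k_exp, n_exp) / 2
  p <- ifelse(diff > 0, half, pmax(1 - half, 0.5))
  fp <- prevalence_fisher_p(k_ctrl, n_ctrl, k_exp, n_exp)
  fp <- ifelse(diff > 0, fp, pmax(fp, 0.5))
  p <- ifelse(use_fisher, fp, p)
  ifelse(degenerate, 1, p)
}

#' Screen a data set with the prevalence-based score
#'
#' Runs [presence_counts()] and [prevalence_score()] over every feature of
#' a data set and classifies at one or more thresholds P*: a feature is a
#' candidate contaminant when its score is strictly below P*.  The common
#' practice is to evaluate the default threshold 0.1 alongside a stricter
#' 0.5 and compare.
#'
#' @param table feature table.
#' @param metadata sample metadata.
#' @param p_star numeric vector of classification thresholds in (0, 1);
#'   default `c(0.1, 0.5)`.
#' @param detect_min minimum count regarded as presence.
#' @return data.frame of per-feature presence counts, `score_P`, and one
#'   logical `contaminant_at_<p_star>` column per threshold.
#' @export
prevalence_screen <- function(table, metadata, p_star = c(0.1, 0.5),
                              detect_min = 1) {
  if (any(p_star <= 0 | p_star >= 1)) {
    stop_validation("p_star thresholds must lie in (0, 1)")
  }
  res <- presence_counts(table, metadata, detect_min = detect_min)
  res$score_P <- prevalence_score(res$k_ctrl, res$n_ctrl, res$k_exp, res$n_exp)
  for (ps in p_star) {
    res[[sprintf("contaminant_at_%g", ps)]] <- res$score_P < ps
  }
  res
}

#' Classify features from prevalence scores
#'
#' @param results data.frame with columns `feature_id` and `score_P`
#'   (e.g. from [prevalence_screen()]).
#' @param p_star classification threshold in (0, 1); classification is
#'   strict (`score_P < p_star`).
#' @return character vector of classified feature identifiers.
#' @export
classify_prevalence <- function(results, p_star) {
  if (length(p_star) != 1L || is.na(p_star) || p_star <= 0 || p_star >= 1) {
    stop_validation("p_star must be a single value in (0, 1)")
  }
  if (nrow(results) == 0L) return(character(0))
  results$feature_id[results$score_P < p_star]
}
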