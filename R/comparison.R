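#' Paired comparison of two treatments
#'
#' Compares paired diversity values from two treatments.  Pairs with a
#' missing value in either arm are dropped.  The test is chosen from the
#' paired differences: all-zero differences mean the treatments are
#' indistinguishable on this metric (`test_used = "degenerate"`, p = 1);
#' otherwise a Shapiro-Wilk test on the differences (alpha 0.05) gates
#' between the paired t test (normality not rejected) and the Wilcoxon
#' signed-rank test.  Gating on the differences — rather than on each
#' treatment's values — targets the quantity the paired tests actually
#' model; per-arm gating is available via `gate_on`.
#'
#' Wilcoxon conventions: zero differences are dropped, the exact null is
#' used for up to 25 informative pairs, and the normal approximation with
#' tie correction above that.
#'
#' @param x,y equal-length numeric vectors, paired by position.
#' @param alpha significance level (default 0.05).
#' @param gate_on `"differences"` (default) or `"values"`: what the
#'   Shapiro-Wilk normality gate is applied to.
#' @return list of class `paired_test` with `n_pairs`, `test_used`
#'   (`paired_t`, `wilcoxon_signed_rank`, or `degenerate`), `p_value`,
#'   and `significant`.
#' @export
paired_compare <- function(x, y, alpha = 0.05,
                           gate_on = c("differences", "values")) {
  gate_on <- match.arg(gate_on)
  if (length(x) != length(y)) stop_validation("x and y must be paired (equal length)")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_data("fewer than 3 complete pairs; paired test not possible")
  d <- x - y
  if (all(d == 0)) {
    res <- list(n_pairs = n, test_used = "degenerate", p_value = 1,
                significant = FALSE, alpha = alpha)
    return(structure(res, class = "paired_test"))
  }
  # (near-)constant nonzero shift: no dispersion to assess normality from,
  # and the t denominator degenerates; take the rank test
  near_constant <- stats::sd(d) <= 1e-10 * max(abs(d))
  normal <- if (near_constant) {
    FALSE
  } else if (gate_on == "differences") {
    shapiro_ok(d)
  } else {
    shapiro_ok(x) && shapiro_ok(y)
  }
  if (normal) {
    p <- stats::t.test(x, y, paired = TRUE)$p.value
    test <- "paired_t"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, exact = sum(d != 0) <= 25)
    )$p.value
    test <- "wilcoxon_signed_rank"
  }
  structure(list(n_pairs = n, test_used = test, p_value = p,
                 significant = p < alpha, alpha = alpha),
            class = "paired_test")
}

# TRUE when Shapiro-Wilk does not reject normality at 0.05.  The test is
# defined for 3..5000 observations; larger vectors are subsampled
# deterministically (evenly spaced order statistics).
shapiro_ok <- function(v) {
  if (stats::sd(v) == 0) return(FALSE)
  if (length(v) > 5000L) v <- sort(v)[round(seq(1, length(v), length.out = 5000L))]
  stats::shapiro.test(v)$p.value >= 0.05
}

#' @export
print.paired_test <- function(x, ...) {
  cat(sprintf("paired test (%s): n = %d, p = %.4g%s\n",
              x$test_used, x$n_pairs, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Compare diversity values across all treatments
#'
#' Takes a long data.frame of per-unit diversity values under each
#' treatment and runs every pairwise [paired_compare()], pairing on `id`.
#' For alpha diversity the pairing unit is the sample; for beta diversity
#' it is the unordered sample pair (see [beta_values_long()]).  A compact
#' letter display is built from the resulting non-significance graph.
#'
#' @param values data.frame with columns `treatment`, `id`, `value`.
#'   Treatment order follows factor levels when `treatment` is a factor,
#'   otherwise first appearance.
#' @param alpha significance level (default 0.05).
#' @param p_adjust multiplicity correction applied across the pairwise
#'   p-values before significance calls (a [stats::p.adjust()] method);
#'   default `"none"`, matching the convention of reporting raw paired
#'   p-values per data set.
#' @param gate_on passed to [paired_compare()].
#' @return list with `tests` (data.frame: `treatment_a`, `treatment_b`,
#'   `n_pairs`, `test_used`, `p_value`, `significant`) and `letters`
#'   (named character vector; treatments share a letter iff not
#'   significantly different).
#' @export
compare_treatments <- function(values, alpha = 0.05, p_adjust = "none",
                               gate_on = "differences") {
  stopifnot(all(c("treatment", "id", "value") %in% names(values)))
  trts <- if (is.factor(values$treatment)) levels(values$treatment)
          else unique(as.character(values$treatment))
  trts <- trts[trts %in% as.character(values$treatment)]
  if (length(trts) < 2L) stop_data("need at least two treatments to compare")
  by_trt <- lapply(trts, function(tt) {
    v <- values[values$treatment == tt, c("id", "value")]
    if (anyDuplicated(v$id)) stop_validation(
      sprintf("duplicate pairing ids within treatment '%s'", tt))
    stats::setNames(v$value, v$id)
  })
  names(by_trt) <- trts
  rows <- list()
  for (i in seq_len(length(trts) - 1L)) {
    for (j in seq(i + 1L, length(trts))) {
      a <- by_trt[[i]]; b <- by_trt[[j]]
      ids <- intersect(names(a), names(b))
      res <- paired_compare(a[ids], b[ids], alpha = alpha, gate_on = gate_on)
      rows[[length(rows) + 1L]] <- data.frame(
        treatment_a = trts[i], treatment_b = trts[j],
        n_pairs = res$n_pairs, test_used = res$test_used,
        p_value = res$p_value, stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, rows)
  tests$p_value <- stats::p.adjust(tests$p_value, method = p_adjust)
  tests$significant <- tests$p_value < alpha
  list(tests = tests, letters = letter_groups(trts, tests))
}

#' Compact letter display from pairwise test results
#'
#' Assigns letter strings to treatments so that two treatments share a
#' letter if and only if their pairwise comparison was not significant.
#' Letters correspond to the maximal cliques of the non-significance
#' graph, enumerated with [igraph::max_cliques()] and ordered
#' deterministically by their lowest-ranked member (then by size).
#'
#' @param treatments character vector of treatment names, in display
#'   order.
#' @param tests data.frame with columns `treatment_a`, `treatment_b`,
#'   `significant` (e.g. from [compare_treatments()]).
#' @return named character vector of letter strings.
#' @export
letter_groups <- function(treatments, tests) {
  k <- length(treatments)
  adj <- matrix(FALSE, k, k, dimnames = list(treatments, treatments))
  for (r in seq_len(nrow(tests))) {
    if (!tests$significant[r]) {
      adj[tests$treatment_a[r], tests$treatment_b[r]] <- TRUE
      adj[tests$treatment_b[r], tests$treatment_a[r]] <- TRUE
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cl <- igraph::max_cliques(g)
  members <- lapply(cl, function(cc) sort(match(names(cc), treatments)))
  ord <- order(vapply(members, min, numeric(1)),
               -lengths(members),
               vapply(members, function(m) paste(m, collapse = ","), character(1)))
  members <- members[ord]
  if (length(members) > 26L) stop_data("more than 26 letter groups; display not possible")
  out <- stats::setNames(rep("", k), treatments)
  for (i in seq_along(members)) {
    idx <- members[[i]]
    out[idx] <- paste0(out[idx], letters[i])
  }
  out
}

#' Long-format alpha diversity across treatments
#'
#' Convenience builder for [compare_treatments()]: computes
#' [alpha_diversity()] for each treatment's table and stacks one metric,
#' paired by sample.
#'
#' @param tables named list of feature tables, one per treatment.
#' @param metric `"richness"`, `"shannon"`, or `"pielou"`.
#' @return data.frame with columns `treatment`, `id`, `value`.
#' @export
alpha_values_long <- function(tables, metric = c("richness", "shannon", "pielou")) {
  metric <- match.arg(metric)
  do.call(rbind, lapply(names(tables), function(tt) {
    a <- alpha_diversity(tables[[tt]])
    data.frame(treatment = tt, id = a$sample_id, value = a[[metric]],
               stringsAsFactors = FALSE)
  }))
}

#' Long-format beta diversity across treatments
#'
#' Computes a [distance_matrix()] per treatment and stacks the
#' off-diagonal values, paired by the unordered sample pair, so that the
#' same pair of samples is compared across treatments.
#'
#' @param tables named list of feature tables, one per treatment.
#' @param metric `"jaccard"` or `"bray_curtis"`.
#' @return data.frame with columns `treatment`, `id` (canonical
#'   `"s1|s2"` pair key), `value`.
#' @export
beta_values_long <- function(tables, metric = c("jaccard", "bray_curtis")) {
  metric <- match.arg(metric)
  do.call(rbind, lapply(names(tables), function(tt) {
    m <- distance_matrix(tables[[tt]], metric)
    ids <- rownames(m)
    pairs <- utils::combn(ids, 2)
    key <- apply(pairs, 2, function(pp) paste(sort(pp), collapse = "|"))
    data.frame(treatment = tt, id = key,
               value = m[cbind(pairs[1, ], pairs[2, ])],
               stringsAsFactors = FALSE)
  }))
}
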