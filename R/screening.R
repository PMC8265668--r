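#' Construct a relative-abundance profile
#'
#' An abundance profile is a named numeric vector of per-feature relative
#' abundances (fractions in \[0, 1\]) over some subset of samples, as used
#' for threshold classification.  Profiles built by
#' [pooled_relative_abundance()] always sum to 1; profiles entered directly
#' (e.g. the published per-ASV percentage blocks, which only list features
#' above a cutoff) may sum to less.
#'
#' @param values named numeric vector of abundances.
#' @param percent are `values` on the percent scale (divided by 100 on
#'   input)?  Default `FALSE` (fractions).
#' @param subset_label optional label for the sample subset.
#' @param total_counts optional total read count behind the profile.
#' @return object of class `abundance_profile` (a named numeric vector).
#' @export
abundance_profile <- function(values, percent = FALSE, subset_label = NULL,
                              total_counts = NA_real_) {
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop_identifier("abundance profile values must be named by feature")
  }
  if (anyDuplicated(names(values))) {
    stop_identifier("duplicated feature names in abundance profile")
  }
  v <- as.numeric(values)
  if (percent) v <- v / 100
  if (anyNA(v) || any(v < 0) || any(v > 1 + 1e-9)) {
    stop_validation("abundances must lie in [0, 1] (or [0, 100] as percent)")
  }
  structure(stats::setNames(v, names(values)),
            class = "abundance_profile",
            subset_label = subset_label,
            total_counts = total_counts)
}

#' @export
print.abundance_profile <- function(x, ...) {
  lab <- attr(x, "subset_label")
  cat(sprintf("abundance profile%s: %d features, sum %.4f\n",
              if (is.null(lab)) "" else paste0(" [", lab, "]"),
              length(x), sum(x)))
  print(stats::setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

#' Pooled (overall) relative abundance over a sample subset
#'
#' The pooled relative abundance of a feature over a subset of samples is
#' its summed count divided by the subset's total count.  Pooling — rather
#' than averaging per-sample proportions — is the natural reading of an
#' "overall" abundance and is the only consistent one when a subset holds a
#' single sample (common for negative controls).
#'
#' @param table feature table.
#' @param sample_ids non-empty subset of `colnames(table)`.
#' @param subset_label optional label carried on the profile.
#' @return [abundance_profile()] over all features of `table`, summing to 1.
#' @export
pooled_relative_abundance <- function(table, sample_ids, subset_label = NULL) {
  if (length(sample_ids) == 0L) stop_validation("sample_ids must be non-empty")
  missing_ids <- setdiff(sample_ids, colnames(table))
  if (length(missing_ids)) {
    stop_identifier(sprintf("sample(s) not in table: %s",
                            paste(missing_ids, collapse = ", ")))
  }
  sub <- table[, sample_ids, drop = FALSE]
  tot <- sum(sub)
  if (tot == 0) stop_validation("subset has zero total count; profile undefined")
  abundance_profile(rowSums(sub) / tot,
                    subset_label = subset_label, total_counts = tot)
}

#' Classify candidate contaminants by control abundance threshold
#'
#' Returns the features whose relative abundance in the (control) profile
#' is at or above `tau` percent.  The comparison is inclusive, matching the
#' ">= tau%" phrasing of threshold-based removal.
#'
#' @param control_profile [abundance_profile()] over negative-control
#'   samples.
#' @param tau threshold on the percent scale (> 0); the graded treatments
#'   use 1, 5, and 10.
#' @return character vector of classified feature identifiers.
#' @export
classify_threshold <- function(control_profile, tau) {
  if (length(tau) != 1L || is.na(tau) || tau <= 0) {
    stop_validation("tau must be a single positive percent")
  }
  names(control_profile)[as.numeric(control_profile) >= tau / 100]
}

#' Shared-contaminant burden in a tissue subset
#'
#' For a set of candidate contaminants, counts how many are also detected
#' (nonzero pooled abundance) in a tissue profile and sums their tissue
#' relative abundance.  Candidates absent from the tissue profile count as
#' zero abundance.
#'
#' @param candidates character vector of candidate feature identifiers.
#' @param tissue_profile [abundance_profile()] over the experimental
#'   samples of one tissue.
#' @return list with `n_candidates`, `n_shared`, and `pct_tissue` (summed
#'   tissue abundance of shared candidates, percent scale, unrounded;
#'   report writers round to two decimals).
#' @export
shared_contaminant_summary <- function(candidates, tissue_profile) {
  candidates <- unique(as.character(candidates))
  ab <- stats::setNames(as.numeric(tissue_profile), names(tissue_profile))
  tiss <- ifelse(candidates %in% names(ab), ab[candidates], 0)
  shared <- tiss > 0
  list(
    n_candidates = length(candidates),
    n_shared = sum(shared),
    pct_tissue = 100 * sum(tiss[shared])
  )
}

#' Per-data-set contaminant screening report
#'
#' For every data set in the metadata, pools the negative controls, lists
#' each feature's control abundance next to its abundance in every tissue
#' (features at or above the smallest threshold), and summarises the shared
#' burden per tissue for each threshold plus the full-removal set (every
#' feature detected in a control).  Data sets without controls or without
#' experimental samples are skipped with a warning.
#'
#' @param table feature table.
#' @param metadata sample metadata (see [validate_metadata()]).
#' @param taus thresholds on the percent scale, default `c(1, 5, 10)`.
#' @return list with two data.frames: `features` (per-feature abundance
#'   block, percent scale) and `summary` (per data set x tissue x
#'   treatment: `n_candidates`, `n_shared`, `pct_tissue`).  `tau = 0` rows
#'   denote the full-removal set.
#' @export
screening_report <- function(table, metadata, taus = c(1, 5, 10)) {
  validate_metadata(metadata, table)
  if (any(taus <= 0)) stop_validation("all taus must be positive")
  taus <- sort(unique(taus), decreasing = FALSE)
  feat_rows <- list()
  sum_rows <- list()
  for (ds in unique(metadata$dataset)) {
    md <- metadata[metadata$dataset == ds, , drop = FALSE]
    ctrl <- intersect(md$sample_id[md$role == "control"], colnames(table))
    expt <- intersect(md$sample_id[md$role == "experimental"], colnames(table))
    if (length(ctrl) == 0L || length(expt) == 0L) {
      warning(sprintf(
        "dataset '%s' lacks %s samples; skipped", ds,
        if (length(ctrl) == 0L) "control" else "experimental"))
      next
    }
    cp <- pooled_relative_abundance(table, ctrl, subset_label = ds)
    full_set <- names(cp)[as.numeric(cp) > 0]
    tissues <- unique(md$tissue[md$role == "experimental" & md$sample_id %in% expt])
    profiles <- lapply(tissues, function(tt) {
      ids <- md$sample_id[md$role == "experimental" & md$tissue == tt]
      pooled_relative_abundance(table, intersect(ids, colnames(table)),
                                subset_label = paste(ds, tt, sep = "_"))
    })
    names(profiles) <- tissues

    shown <- classify_threshold(cp, min(taus))
    if (length(shown)) {
      ord <- order(-as.numeric(cp[shown]))
      block <- data.frame(dataset = ds, feature_id = shown[ord],
                          control = 100 * as.numeric(cp[shown][ord]),
                          stringsAsFactors = FALSE)
      for (tt in tissues) block[[tt]] <- 100 * as.numeric(profiles[[tt]][block$feature_id])
      feat_rows[[ds]] <- block
    }
    for (tt in tissues) {
      for (tau in c(taus, 0)) {
        cand <- if (tau == 0) full_set else classify_threshold(cp, tau)
        s <- shared_contaminant_summary(cand, profiles[[tt]])
        sum_rows[[length(sum_rows) + 1L]] <- data.frame(
          dataset = ds, tissue = tt, tau = tau,
          n_candidates = s$n_candidates, n_shared = s$n_shared,
          pct_tissue = s$pct_tissue, stringsAsFactors = FALSE)
      }
    }
  }
  list(
    features = if (length(feat_rows)) do.call(rbind, c(feat_rows, make.row.names = FALSE))
               else data.frame(),
    summary = if (length(sum_rows)) do.call(rbind, c(sum_rows, make.row.names = FALSE))
              else data.frame()
  )
}
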