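#' Specify a contaminant-removal treatment
#'
#' The analysis compares five treatments of a data set: no removal, full
#' removal of every feature detected in a negative control, and removal of
#' features whose pooled control abundance is at or above a percent
#' threshold (the graded treatments use 1, 5, and 10).
#'
#' @param kind `"none"`, `"full_removal"`, or `"threshold"`.
#' @param tau percent threshold, required (and > 0) when
#'   `kind = "threshold"`.
#' @return object of class `treatment_spec`.
#' @export
treatment_spec <- function(kind = c("none", "full_removal", "threshold"),
                           tau = NULL) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop_spec("unknown treatment kind"))
  if (kind == "threshold") {
    if (is.null(tau) || length(tau) != 1L || is.na(tau) || tau <= 0) {
      stop_spec("threshold treatments need a single positive tau (percent)")
    }
  } else if (!is.null(tau)) {
    stop_spec(sprintf("tau is only meaningful for threshold treatments, not '%s'", kind))
  }
  structure(list(kind = kind, tau = tau), class = "treatment_spec")
}

#' @export
print.treatment_spec <- function(x, ...) {
  cat("treatment:", treatment_label(x), "\n")
  invisible(x)
}

#' Label for a treatment
#'
#' Short labels used in file names and report tables: `none`, `full`,
#' `t1`, `t5`, `t10`, ...
#'
#' @param spec a [treatment_spec()].
#' @return character scalar.
#' @export
treatment_label <- function(spec) {
  switch(spec$kind,
         none = "none",
         full_removal = "full",
         threshold = sprintf("t%g", spec$tau))
}

#' The five standard treatments
#'
#' @param taus percent thresholds for the graded treatments, default
#'   `c(1, 5, 10)`.
#' @return named list of [treatment_spec()] objects (`none`, `full`,
#'   `t<tau>` ...).
#' @export
default_treatments <- function(taus = c(1, 5, 10)) {
  specs <- c(list(treatment_spec("none"), treatment_spec("full_removal")),
             lapply(taus, function(tt) treatment_spec("threshold", tau = tt)))
  stats::setNames(specs, vapply(specs, treatment_label, character(1)))
}

#' Apply a removal treatment to a data set
#'
#' Determines the candidate contaminant set from the negative controls of
#' the table (full removal: every feature with a nonzero control count;
#' threshold: [classify_threshold()] on the pooled control profile), drops
#' those features from every experimental sample, and returns the trimmed
#' experimental table.  Removal is feature-global: a classified feature is
#' removed from all experimental samples of the data set.  Control samples
#' are excluded from the output for every treatment, including `none`.
#' Counts are not re-normalized after removal.
#'
#' @param table feature table containing control and experimental samples.
#' @param metadata sample metadata covering the table's samples.
#' @param spec a [treatment_spec()].
#' @return list of class `removal_outcome` with `treatment`,
#'   `removed_features`, `table` (experimental samples only, removed
#'   features dropped), and `removed_fraction` (named per-sample fraction
#'   of reads removed).
#' @export
apply_treatment <- function(table, metadata, spec) {
  if (!inherits(spec, "treatment_spec")) stop_spec("spec must be a treatment_spec")
  validate_metadata(metadata, table)
  expt <- intersect(metadata$sample_id[metadata$role == "experimental"], colnames(table))
  ctrl <- intersect(metadata$sample_id[metadata$role == "control"], colnames(table))
  if (length(expt) == 0L) stop_metadata("no experimental samples in table")
  removed <- character(0)
  if (spec$kind != "none") {
    if (length(ctrl) == 0L) {
      stop_metadata("treatment needs negative-control samples to screen against")
    }
    cp <- pooled_relative_abundance(table, ctrl)
    removed <- if (spec$kind == "full_removal") {
      names(cp)[as.numeric(cp) > 0]
    } else {
      classify_threshold(cp, spec$tau)
    }
  }
  exp_tab <- table[, expt, drop = FALSE]
  totals <- colSums(exp_tab)
  removed_reads <- colSums(exp_tab[removed, , drop = FALSE])
  frac <- ifelse(totals > 0, removed_reads / totals, 0)
  out <- exp_tab[setdiff(rownames(exp_tab), removed), , drop = FALSE]
  structure(list(
    treatment = spec,
    removed_features = removed,
    table = out,
    removed_fraction = stats::setNames(frac, expt)
  ), class = "removal_outcome")
}

#' @export
print.removal_outcome <- function(x, ...) {
  cat(sprintf("removal outcome [%s]: %d feature(s) removed, %d x %d table, mean removed fraction %.3f\n",
              treatment_label(x$treatment), length(x$removed_features),
              nrow(x$table), ncol(x$table), mean(x$removed_fraction)))
  invisible(x)
}
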