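#' Alpha diversity per sample
#'
#' Observed richness (number of features with nonzero count), Shannon
#' diversity, and Pielou's evenness for every sample of a feature table.
#' Shannon uses the natural logarithm by default (`base` configurable);
#' Pielou's J = H / log(S) is undefined for samples with at most one
#' feature and is reported as `NA`.  Empty samples yield all-`NA` rows with
#' a warning.
#'
#' @param table feature table.
#' @param base logarithm base for Shannon (default `exp(1)`, nats).
#' @return data.frame with columns `sample_id`, `richness`, `shannon`,
#'   `pielou`.
#' @export
alpha_diversity <- function(table, base = exp(1)) {
  totals <- colSums(table)
  s <- colSums(table > 0)
  h <- suppressWarnings(vegan::diversity(t(table), index = "shannon", base = base))
  j <- ifelse(s > 1, h / log(s, base = base), NA_real_)
  if (any(totals == 0)) {
    warning(sprintf("%d empty sample(s); diversity reported as NA", sum(totals == 0)))
    h[totals == 0] <- NA_real_
    s[totals == 0] <- NA_integer_
  }
  data.frame(sample_id = colnames(table), richness = as.integer(s),
             shannon = as.numeric(h), pielou = as.numeric(j),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Beta diversity between two samples
#'
#' Jaccard distance on presence/absence (1 minus shared over union of
#' detected features) or Bray-Curtis dissimilarity on counts
#' (sum |a - b| / sum (a + b)).  Both range over \[0, 1\]; two empty
#' samples have undefined distance (`NA` with a warning).
#'
#' @param a,b count vectors over the same feature universe.
#' @param metric `"jaccard"` or `"bray_curtis"`.
#' @return distance in \[0, 1\], or `NA` when undefined.
#' @export
beta_distance <- function(a, b, metric = c("jaccard", "bray_curtis")) {
  metric <- match.arg(metric)
  if (length(a) != length(b)) stop_validation("samples must share a feature universe")
  if (sum(a) == 0 && sum(b) == 0) {
    warning("both samples are empty; distance undefined")
    return(NA_real_)
  }
  if (metric == "jaccard") {
    pa <- a > 0; pb <- b > 0
    u <- sum(pa | pb)
    1 - sum(pa & pb) / u
  } else {
    sum(abs(a - b)) / sum(a + b)
  }
}

#' Pairwise distance matrix over the samples of a table
#'
#' Computed with [vegan::vegdist()] (`"bray"`, or binary `"jaccard"` for
#' presence/absence Jaccard) and returned as a full symmetric matrix with
#' zero diagonal.
#'
#' @param table feature table with at least two samples.
#' @param metric `"jaccard"` or `"bray_curtis"`.
#' @return symmetric numeric matrix, samples x samples.
#' @export
distance_matrix <- function(table, metric = c("jaccard", "bray_curtis")) {
  metric <- match.arg(metric)
  if (ncol(table) < 2L) stop_validation("need at least two samples for distances")
  d <- if (metric == "jaccard") {
    vegan::vegdist(t(table), method = "jaccard", binary = TRUE)
  } else {
    vegan::vegdist(t(table), method = "bray")
  }
  m <- as.matrix(d)
  dimnames(m) <- list(colnames(table), colnames(table))
  m
}
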