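#' Configuration for the synthetic community generator
#'
#' The generator emulates the contamination structure of low-biomass 16S
#' data sets sequenced alongside negative controls:
#'
#' * a reagent/laboratory contaminant pool ("kitome") whose composition is
#'   drawn once per data set from a symmetric Dirichlet — a small
#'   concentration makes the pool uneven, so one or two contaminants
#'   dominate the controls, as observed in real blanks;
#' * biomass-dependent bleed-through: every experimental sample receives a
#'   Beta-distributed fraction `bleed_mean`/`bleed_sd` of its reads from
#'   the pool, modelling the rising kitome share as true biomass falls;
#' * cross-contamination: a fraction `cross_fraction` of control reads
#'   comes from the average true community, modelling leakage of real
#'   symbionts into blanks (the signature that makes naive full removal
#'   risky);
#' * an optional endosymbiont: the first true feature is given a fixed
#'   share of the true community, reproducing the classic pattern of a
#'   dominant vertically-transmitted symbiont that also shows up faintly
#'   in controls.
#'
#' Defaults mirror a lab study arm with 23 experimental pools and 6
#' extraction blanks sequenced to a depth around 25,000 reads.
#'
#' @param n_experimental,n_controls sample counts.
#' @param n_true_features,n_contam_features feature counts for the true
#'   community and the contaminant pool.
#' @param true_sigma log-normal sigma of the true rank-abundance profile.
#' @param sample_sigma per-sample log-normal jitter around the true
#'   profile (between-sample community variation).
#' @param contam_alpha symmetric Dirichlet concentration of the
#'   contaminant pool (small = uneven).
#' @param bleed_mean,bleed_sd mean and spread of the per-sample
#'   bleed-through fraction (Beta-distributed; `bleed_sd = 0` fixes it).
#' @param cross_fraction fraction of control reads drawn from the mean
#'   true community.
#' @param depth_range integer range of per-sample sequencing depths,
#'   drawn uniformly.
#' @param singleton_rate singleton features injected, as a fraction of the
#'   feature count (each replaces one read of its sample's most abundant
#'   feature, so column totals are preserved).
#' @param endosymbiont_share share of the true community assigned to the
#'   designated endosymbiont feature (0 disables).
#' @param seed integer seed; generation is fully deterministic given the
#'   config.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_experimental = 23, n_controls = 6,
                             n_true_features = 150, n_contam_features = 30,
                             true_sigma = 1.5, sample_sigma = 0.6,
                             contam_alpha = 0.3,
                             bleed_mean = 0.3, bleed_sd = 0.1,
                             cross_fraction = 0.02,
                             depth_range = c(20000, 30000),
                             singleton_rate = 0.05,
                             endosymbiont_share = 0.3,
                             seed = 1) {
  cfg <- list(n_experimental = n_experimental, n_controls = n_controls,
              n_true_features = n_true_features,
              n_contam_features = n_contam_features,
              true_sigma = true_sigma, sample_sigma = sample_sigma,
              contam_alpha = contam_alpha,
              bleed_mean = bleed_mean, bleed_sd = bleed_sd,
              cross_fraction = cross_fraction,
              depth_range = depth_range, singleton_rate = singleton_rate,
              endosymbiont_share = endosymbiont_share, seed = seed)
  with(cfg, {
    if (n_experimental < 1 || n_controls < 1) stop_spec("need >= 1 sample per role")
    if (n_true_features < 1 || n_contam_features < 1) {
      stop_spec("need >= 1 true and >= 1 contaminant feature")
    }
    if (bleed_mean < 0 || bleed_mean > 1 || cross_fraction < 0 || cross_fraction > 1) {
      stop_spec("bleed_mean and cross_fraction must lie in [0, 1]")
    }
    if (endosymbiont_share < 0 || endosymbiont_share >= 1) {
      stop_spec("endosymbiont_share must lie in [0, 1)")
    }
    if (length(depth_range) != 2L || any(depth_range < 1) ||
        depth_range[1] > depth_range[2]) {
      stop_spec("depth_range must be an increasing pair of positive depths")
    }
    if (true_sigma < 0 || sample_sigma < 0 || contam_alpha <= 0 ||
        bleed_sd < 0 || singleton_rate < 0) {
      stop_spec("dispersion and rate parameters must be non-negative (contam_alpha > 0)")
    }
  })
  structure(cfg, class = "generator_config")
}

# Beta draw parameterised by mean and sd, clamped to a proper Beta;
# sd = 0 (or mean at the boundary) degenerates to the constant mean.
rbeta_mean_sd <- function(n, mean, sd) {
  if (sd == 0 || mean == 0 || mean == 1) return(rep(mean, n))
  v <- min(sd^2, mean * (1 - mean) * 0.999)
  k <- mean * (1 - mean) / v - 1
  stats::rbeta(n, mean * k, (1 - mean) * k)
}

#' Generate a synthetic low-biomass data set with ground truth
#'
#' Draws a contaminant pool and a true community per the
#' [generator_config()], composes control samples as
#' `(1 - cross_fraction) * pool + cross_fraction * mean true profile` and
#' experimental samples as
#' `(1 - bleed_i) * sample true profile + bleed_i * pool`, and samples
#' counts multinomially at each sample's drawn depth (so column totals are
#' exact).  Singletons are then injected by swapping single reads.
#'
#' @param config a [generator_config()].
#' @return list of class `sim_community` with `table` (feature table),
#'   `metadata` (sample metadata, dataset `"sim"`, tissue `"tissue"`),
#'   `truth` (data.frame: `feature_id`, `label` in
#'   `contaminant`/`true_resident`, and `control_abundance`, the realized
#'   pooled control relative abundance), and the `config`.
#' @export
generate_community <- function(config = generator_config()) {
  if (!inherits(config, "generator_config")) stop_spec("config must be a generator_config")
  withr::with_seed(config$seed, generate_community_impl(config))
}

generate_community_impl <- function(cfg) {
  m <- cfg$n_contam_features
  n <- cfg$n_true_features
  contam_ids <- sprintf("C%03d", seq_len(m))
  true_ids <- sprintf("T%03d", seq_len(n))

  # contaminant pool: symmetric Dirichlet via normalized gammas
  pool <- stats::rgamma(m, shape = cfg$contam_alpha)
  if (sum(pool) == 0) pool <- rep(1, m)
  pool <- pool / sum(pool)

  # true community base profile (log-normal rank abundance)
  base <- stats::rlnorm(n, 0, cfg$true_sigma)
  if (cfg$endosymbiont_share > 0 && n > 1) {
    share <- cfg$endosymbiont_share
    base[1] <- share / (1 - share) * sum(base[-1])
  }
  mean_true <- base / sum(base)

  nf <- m + n
  ids <- c(contam_ids, true_ids)
  pool_full <- c(pool, rep(0, n))
  mean_true_full <- c(rep(0, m), mean_true)

  depth_of <- function(k) sample(cfg$depth_range[1]:cfg$depth_range[2], k, replace = TRUE)

  n_exp <- cfg$n_experimental
  bleed <- rbeta_mean_sd(n_exp, cfg$bleed_mean, cfg$bleed_sd)
  exp_depths <- depth_of(n_exp)
  exp_counts <- vapply(seq_len(n_exp), function(i) {
    ti <- base * stats::rlnorm(n, 0, cfg$sample_sigma)
    ti <- ti / sum(ti)
    comp <- (1 - bleed[i]) * c(rep(0, m), ti) + bleed[i] * pool_full
    stats::rmultinom(1, exp_depths[i], comp)[, 1]
  }, numeric(nf))

  n_ctrl <- cfg$n_controls
  ctrl_depths <- depth_of(n_ctrl)
  ctrl_comp <- (1 - cfg$cross_fraction) * pool_full + cfg$cross_fraction * mean_true_full
  ctrl_counts <- vapply(seq_len(n_ctrl), function(j) {
    stats::rmultinom(1, ctrl_depths[j], ctrl_comp)[, 1]
  }, numeric(nf))

  counts <- cbind(exp_counts, ctrl_counts)
  rownames(counts) <- ids
  sample_ids <- c(sprintf("E%02d", seq_len(n_exp)), sprintf("B%02d", seq_len(n_ctrl)))
  colnames(counts) <- sample_ids

  # singleton injection: one read swapped from the sample's top feature
  n_single <- round(cfg$singleton_rate * nf)
  if (n_single > 0) {
    singles <- matrix(0, n_single, ncol(counts),
                      dimnames = list(sprintf("S%03d", seq_len(n_single)), sample_ids))
    hosts <- sample(seq_len(ncol(counts)), n_single, replace = TRUE)
    for (k in seq_len(n_single)) {
      col <- hosts[k]
      top <- which.max(counts[, col])
      if (counts[top, col] > 1) {
        counts[top, col] <- counts[top, col] - 1
        singles[k, col] <- 1
      }
    }
    counts <- rbind(counts, singles)
  }

  metadata <- data.frame(
    sample_id = sample_ids,
    role = c(rep("experimental", n_exp), rep("control", n_ctrl)),
    dataset = "sim", tissue = "tissue", stringsAsFactors = FALSE)

  ctrl_tot <- sum(counts[, metadata$sample_id[metadata$role == "control"]])
  ctrl_ab <- rowSums(counts[, metadata$sample_id[metadata$role == "control"], drop = FALSE]) / ctrl_tot
  truth <- data.frame(
    feature_id = rownames(counts),
    label = ifelse(rownames(counts) %in% contam_ids, "contaminant", "true_resident"),
    control_abundance = as.numeric(ctrl_ab),
    stringsAsFactors = FALSE)

  structure(list(table = as_feature_table(counts, drop_empty_samples = FALSE),
                 metadata = metadata, truth = truth, config = cfg),
            class = "sim_community")
}

#' @export
print.sim_community <- function(x, ...) {
  cat(sprintf("synthetic community: %d features x %d samples (%d experimental, %d controls), %d contaminant features\n",
              nrow(x$table), ncol(x$table),
              sum(x$metadata$role == "experimental"),
              sum(x$metadata$role == "control"),
              sum(x$truth$label == "contaminant")))
  invisible(x)
}

#' Precision and recall of a contaminant call set against ground truth
#'
#' @param truth truth data.frame from [generate_community()] (columns
#'   `feature_id`, `label`).
#' @param called character vector of features called contaminant.
#' @return list with `precision` (`NA` when nothing was called) and
#'   `recall` (`NA` when the truth holds no contaminants).
#' @export
recovery_metrics <- function(truth, called) {
  called <- unique(as.character(called))
  unknown <- setdiff(called, truth$feature_id)
  if (length(unknown)) {
    stop_validation(sprintf("called feature(s) outside the truth universe: %s",
                            paste(utils::head(unknown, 5), collapse = ", ")))
  }
  contam <- truth$feature_id[truth$label == "contaminant"]
  tp <- length(intersect(called, contam))
  list(
    precision = if (length(called)) tp / length(called) else NA_real_,
    recall = if (length(contam)) tp / length(contam) else NA_real_
  )
}

#' Published per-ASV abundance blocks (worked-example fixture)
#'
#' The per-ASV percentage blocks for the five mosquito data sets (Aedes,
#' Aegypti, Albopictus, Anopheles1, Anopheles2): each block lists, for
#' every ASV at >= 1% pooled abundance in that data set's negative
#' controls, its control abundance and its pooled abundance in each
#' sampled tissue (gut, and where available upper/lower reproductive
#' tract).  Shipped as a plain TSV under `inst/extdata` and used as the
#' package's worked example: feeding a block through
#' [classify_threshold()] and [shared_contaminant_summary()] reproduces
#' the published shared-burden table.
#'
#' @return named list of blocks; each block is a list with `dataset`,
#'   `control` (an [abundance_profile()], fractions), and `tissues`
#'   (named list of [abundance_profile()]s for the available tissue
#'   columns).
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "control_asv_blocks.tsv", package = "asvscreen",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(split(df, df$dataset)[unique(df$dataset)], function(block) {
    ids <- block$asv_id
    mk <- function(col) {
      v <- block[[col]]
      if (all(is.na(v))) return(NULL)
      abundance_profile(stats::setNames(v, ids), percent = TRUE,
                        subset_label = paste(block$dataset[1], col, sep = "_"))
    }
    tissues <- Filter(Negate(is.null),
                      list(gut = mk("gut"), urt = mk("urt"), lrt = mk("lrt")))
    list(dataset = block$dataset[1], control = mk("control"), tissues = tissues)
  })
}
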