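#' Run the full screening / removal / diversity pipeline
#'
#' Orchestrates the end-to-end analysis for one or more data sets:
#' load (or simulate) a feature table and metadata, filter singletons,
#' optionally rarefy, screen for candidate contaminants (abundance
#' thresholds and the prevalence score), apply the removal treatments,
#' compute alpha/beta diversity per treatment, compare treatments with
#' paired tests, and write every stage's table plus a `report.md` summary
#' and a JSON run log.
#'
#' The configuration is a named list (or a path to a YAML/JSON file) with
#' blocks:
#'
#' * `table` / `metadata`: input TSV paths, **or** `simulate`: a list of
#'   [generator_config()] arguments, **or** `abundance_only: TRUE` to run
#'   the screening summary straight from the packaged per-ASV percentage
#'   blocks ([table2_fixture()]) without counts (count-dependent stages
#'   are skipped with a notice);
#' * `taus` (default `c(1, 5, 10)`), `p_star` (default `c(0.1, 0.5)`),
#'   `alpha` (default 0.05), `seed` (default 1);
#' * `normalize`: list with `depth` and optional `enabled`
#'   (default: enabled when `depth` given) — rarefaction applied before
#'   screening, `per_treatment = TRUE` instead rarefies each treatment's
#'   table independently after removal;
#' * `output_dir`: where stage outputs are written.
#'
#' @param config named list or path to a YAML/JSON config file.
#' @param output_dir output directory (overrides `config$output_dir`).
#' @return invisibly, a list with the per-stage results (`screening`,
#'   `prevalence`, `treatments`, `alpha`, `comparisons`, `report_path`).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)  # reads JSON too (YAML superset)
  }
  if (!is.list(config)) stop_spec("config must be a list or a config file path")
  out_dir <- output_dir %||% config$output_dir %||%
    stop_spec("config needs an output_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  taus <- config$taus %||% c(1, 5, 10)
  p_star <- config$p_star %||% c(0.1, 0.5)
  alpha <- config$alpha %||% 0.05
  seed <- config$seed %||% 1
  log <- list(package_version = as.character(utils::packageVersion("asvscreen")),
              r_version = R.version.string, seed = seed, taus = taus,
              p_star = p_star, alpha = alpha, stages = list())
  note <- function(stage, ...) {
    msg <- sprintf(...)
    message(sprintf("[%s] %s", stage, msg))
    log$stages[[stage]] <<- msg
  }

  if (isTRUE(config$abundance_only)) {
    blocks <- table2_fixture()
    summary <- abundance_only_summary(blocks, taus)
    utils::write.table(summary, file.path(out_dir, "shared_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("screen", "abundance-only mode: %d data sets, %d summary rows; count-dependent stages skipped",
         length(blocks), nrow(summary))
    report_path <- write_report(out_dir, summary = summary, comparisons = NULL)
    log$config_hash <- config_hash(config)
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(list(screening = list(summary = summary),
                          report_path = report_path)))
  }

  # --- load or simulate ------------------------------------------------
  if (!is.null(config$simulate)) {
    gc_args <- config$simulate
    gc_args$seed <- gc_args$seed %||% seed
    sim <- generate_community(do.call(generator_config, gc_args))
    table <- sim$table
    metadata <- sim$metadata
    utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("input", "simulated %d features x %d samples (seed %d)",
         nrow(table), ncol(table), gc_args$seed)
  } else {
    if (is.null(config$table) || is.null(config$metadata)) {
      stop_spec("config needs either 'table' + 'metadata' paths, a 'simulate' block, or abundance_only")
    }
    table <- read_feature_table(config$table)
    metadata <- read_sample_metadata(config$metadata)
    note("input", "read %d features x %d samples", nrow(table), ncol(table))
  }
  validate_metadata(metadata, table)
  for (ds in unique(metadata$dataset)) {
    md <- metadata[metadata$dataset == ds, ]
    if (!any(md$role == "control" & md$sample_id %in% colnames(table))) {
      stop_metadata(sprintf("dataset '%s' has no control samples in the table", ds))
    }
  }

  n0 <- nrow(table)
  table <- filter_singletons(table)
  note("singletons", "removed %d singleton feature(s)", n0 - nrow(table))

  norm <- config$normalize %||% list()
  per_treatment_norm <- isTRUE(norm$per_treatment)
  norm_enabled <- !is.null(norm$depth) && !isFALSE(norm$enabled)
  if (norm_enabled && !per_treatment_norm) {
    table <- subsample_to_depth(table, depth = norm$depth, seed = seed)
    metadata <- metadata[metadata$sample_id %in% colnames(table), , drop = FALSE]
    note("normalize", "rarefied to %d reads per sample; %d samples retained",
         norm$depth, ncol(table))
  }

  scr <- screening_report(table, metadata, taus = taus)
  utils::write.table(scr$features, file.path(out_dir, "contaminants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scr$summary, file.path(out_dir, "shared_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("screen", "%d candidate feature rows across %d summary rows",
       nrow(scr$features), nrow(scr$summary))

  prev_rows <- lapply(unique(metadata$dataset), function(ds) {
    md <- metadata[metadata$dataset == ds, , drop = FALSE]
    sub <- table[, intersect(md$sample_id, colnames(table)), drop = FALSE]
    res <- prevalence_screen(sub, md, p_star = p_star)
    cbind(dataset = ds, res)
  })
  prev <- do.call(rbind, prev_rows)
  utils::write.table(prev, file.path(out_dir, "prevalence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("prevalence", "scored %d feature x dataset rows", nrow(prev))

  specs <- default_treatments(taus)
  comparisons <- list()
  alphas <- list()
  for (ds in unique(metadata$dataset)) {
    md <- metadata[metadata$dataset == ds, , drop = FALSE]
    sub <- table[, intersect(md$sample_id, colnames(table)), drop = FALSE]
    outcomes <- lapply(specs, function(sp) apply_treatment(sub, md, sp))
    tabs <- lapply(outcomes, `[[`, "table")
    if (norm_enabled && per_treatment_norm) {
      tabs <- lapply(seq_along(tabs), function(i) {
        subsample_to_depth(tabs[[i]], depth = norm$depth, seed = seed + i)
      })
      names(tabs) <- names(outcomes)
    }
    for (lab in names(tabs)) {
      write_feature_table(tabs[[lab]],
                          file.path(out_dir, sprintf("table_%s_%s.tsv", ds, lab)))
    }
    a_rows <- lapply(names(tabs), function(lab) {
      cbind(dataset = ds, treatment = lab, alpha_diversity(tabs[[lab]]))
    })
    alphas[[ds]] <- do.call(rbind, a_rows)
    for (metric in c("richness", "shannon", "pielou")) {
      vals <- alpha_values_long(tabs, metric)
      cmp <- compare_treatments(vals, alpha = alpha,
                                p_adjust = config$p_adjust %||% "none")
      comparisons[[length(comparisons) + 1L]] <-
        cbind(dataset = ds, metric = metric, family = "alpha", cmp$tests,
              letters_a = cmp$letters[cmp$tests$treatment_a],
              letters_b = cmp$letters[cmp$tests$treatment_b])
    }
    if (min(vapply(tabs, ncol, integer(1))) >= 3) {
      for (metric in c("jaccard", "bray_curtis")) {
        vals <- beta_values_long(tabs, metric)
        cmp <- compare_treatments(vals, alpha = alpha,
                                  p_adjust = config$p_adjust %||% "none")
        comparisons[[length(comparisons) + 1L]] <-
          cbind(dataset = ds, metric = metric, family = "beta", cmp$tests,
                letters_a = cmp$letters[cmp$tests$treatment_a],
                letters_b = cmp$letters[cmp$tests$treatment_b])
      }
    }
  }
  alpha_df <- do.call(rbind, alphas)
  utils::write.table(alpha_df, file.path(out_dir, "alpha.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cmp_df <- do.call(rbind, comparisons)
  cmp_df$band <- significance_band(cmp_df$p_value)
  utils::write.table(cmp_df, file.path(out_dir, "comparisons.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("compare", "%d pairwise treatment comparisons", nrow(cmp_df))

  report_path <- write_report(out_dir, summary = scr$summary, comparisons = cmp_df)
  log$config_hash <- config_hash(config)
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(screening = scr, prevalence = prev, alpha = alpha_df,
                 comparisons = cmp_df, report_path = report_path))
}

# Table-3-analogue summary computed directly from percentage blocks
# (no counts available): per data set x tissue x tau.
abundance_only_summary <- function(blocks, taus) {
  rows <- list()
  for (b in blocks) {
    for (tt in names(b$tissues)) {
      for (tau in taus) {
        cand <- classify_threshold(b$control, tau)
        s <- shared_contaminant_summary(cand, b$tissues[[tt]])
        rows[[length(rows) + 1L]] <- data.frame(
          dataset = b$dataset, tissue = tt, tau = tau,
          n_candidates = s$n_candidates, n_shared = s$n_shared,
          pct_tissue = round_half_up(s$pct_tissue, 2), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# Asterisk bands conventionally attached to reported p-values.
significance_band <- function(p) {
  ifelse(p < 0.0005, "***", ifelse(p < 0.005, "**", ifelse(p < 0.05, "*", "")))
}

config_hash <- function(config) {
  # order-stable digest of the effective configuration
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE)
  sum(utf8ToInt(as.character(s)) * seq_len(nchar(as.character(s)))) %% 2^31
}

write_report <- function(out_dir, summary, comparisons) {
  path <- file.path(out_dir, "report.md")
  lines <- c("# Contaminant screening report", "")
  if (!is.null(summary) && nrow(summary)) {
    lines <- c(lines, "## Shared contaminant burden (per data set, tissue, threshold)",
               "", df_to_md(within(summary, pct_tissue <- round_half_up(pct_tissue, 2))), "")
  }
  if (!is.null(comparisons) && nrow(comparisons)) {
    sig <- comparisons[comparisons$significant, , drop = FALSE]
    lines <- c(lines, "## Treatment comparisons", "",
               sprintf("%d of %d pairwise comparisons significant.",
                       nrow(sig), nrow(comparisons)), "",
               df_to_md(comparisons[, c("dataset", "metric", "treatment_a",
                                        "treatment_b", "test_used", "p_value", "band")]))
  }
  writeLines(lines, path)
  path
}

df_to_md <- function(df) {
  fmt <- function(x) if (is.numeric(x)) formatC(x, format = "g", digits = 4) else as.character(x)
  body <- as.data.frame(lapply(df, fmt), stringsAsFactors = FALSE, check.names = FALSE)
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(body, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
}
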