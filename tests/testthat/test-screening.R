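test_that("pooled relative abundance pools counts over the subset", {
  m <- matrix(c(40, 60,   # s1
                30, 70),  # s2
              nrow = 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  tab <- as_feature_table(m)
  p1 <- pooled_relative_abundance(tab, "s1")
  expect_equal(as.numeric(p1), c(0.40, 0.60))
  expect_equal(sum(p1), 1)

  # pooling definition: summed counts over summed totals, not mean of proportions
  m2 <- matrix(c(10, 90, 30, 70), 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  p <- pooled_relative_abundance(as_feature_table(m2), c("s1", "s2"))
  expect_equal(as.numeric(p["A"]), 40 / 200)

  # a feature absent from the subset has abundance zero
  tab3 <- make_test_table()
  expect_equal(as.numeric(pooled_relative_abundance(tab3, c("B1", "B2"))["ASV_C"]), 0)

  zero <- tab3; zero[, "E3"] <- 0
  zero_tab <- suppressWarnings(as_feature_table(zero, drop_empty_samples = FALSE))
  expect_error(pooled_relative_abundance(zero_tab, "E3"),
               class = "asvscreen_validation_error")
  expect_error(pooled_relative_abundance(tab3, character(0)),
               class = "asvscreen_validation_error")
  expect_error(pooled_relative_abundance(tab3, "nope"),
               class = "asvscreen_identifier_error")
})

test_that("threshold classification is inclusive and matches the published Aedes block", {
  aedes <- table2_fixture()$Aedes
  expect_length(classify_threshold(aedes$control, 1), 4)
  expect_length(classify_threshold(aedes$control, 5), 3)
  expect_length(classify_threshold(aedes$control, 10), 2)
  expect_length(classify_threshold(aedes$control, 200), 0)
  # inclusive boundary: a feature at exactly tau percent is classified
  p <- abundance_profile(c(x = 5, y = 1), percent = TRUE)
  expect_identical(classify_threshold(p, 5), "x")
  expect_error(classify_threshold(p, 0), class = "asvscreen_validation_error")
})

test_that("shared-contaminant summaries reproduce the published worked examples", {
  fx <- table2_fixture()
  aedes <- fx$Aedes
  s <- shared_contaminant_summary(classify_threshold(aedes$control, 1), aedes$tissues$gut)
  expect_equal(s$n_candidates, 4)
  expect_equal(s$n_shared, 3)
  expect_equal(round_half_up(s$pct_tissue, 2), 49.10)

  # a data set whose candidates never occur in tissue: all zeros
  aeg <- fx$Aegypti
  s0 <- shared_contaminant_summary(classify_threshold(aeg$control, 1), aeg$tissues$gut)
  expect_equal(s0$n_candidates, 16)
  expect_equal(s0$n_shared, 0)
  expect_equal(s0$pct_tissue, 0)

  empty <- shared_contaminant_summary(character(0), aedes$tissues$gut)
  expect_equal(unlist(empty), c(n_candidates = 0, n_shared = 0, pct_tissue = 0))

  # candidates absent from the tissue profile count as zero abundance
  s2 <- shared_contaminant_summary(c("Aedes_Serratia_1", "ghost"), aedes$tissues$gut)
  expect_equal(s2$n_shared, 1)
  expect_equal(s2$pct_tissue, 10.16)
})

test_that("pct_tissue is additive over disjoint candidate sets and bounded by 100", {
  withr::local_seed(31)
  for (rep in 1:20) {
    tab <- as_feature_table(random_table(30, 4))
    prof <- pooled_relative_abundance(tab, colnames(tab)[1:2])
    ids <- names(prof)
    setA <- sample(ids, 10)
    setB <- sample(setdiff(ids, setA), 10)
    sA <- shared_contaminant_summary(setA, prof)$pct_tissue
    sB <- shared_contaminant_summary(setB, prof)$pct_tissue
    sAB <- shared_contaminant_summary(c(setA, setB), prof)$pct_tissue
    expect_equal(sA + sB, sAB)
    expect_lte(shared_contaminant_summary(ids, prof)$pct_tissue, 100 + 1e-9)
  }
})

test_that("candidate sets are nested across thresholds and within the control-detected set", {
  withr::local_seed(77)
  for (rep in 1:50) {
    tab <- as_feature_table(random_table(40, 6, lambda = 3))
    ctrl <- colnames(tab)[1:2]
    prof <- pooled_relative_abundance(tab, ctrl)
    full <- names(prof)[as.numeric(prof) > 0]
    c1 <- classify_threshold(prof, 1)
    c5 <- classify_threshold(prof, 5)
    c10 <- classify_threshold(prof, 10)
    expect_true(all(c10 %in% c5))
    expect_true(all(c5 %in% c1))
    expect_true(all(c1 %in% full))
  }
})

test_that("screening_report assembles per-dataset feature blocks and shared summaries", {
  tab <- filter_singletons(make_test_table())
  md <- make_test_metadata()
  rep_ <- screening_report(tab, md, taus = c(1, 5, 10))
  # ASV_A: 80/91 of control reads; ASV_B: 11/91; both >= 1%
  expect_setequal(rep_$features$feature_id, c("ASV_A", "ASV_B"))
  expect_equal(rep_$features$control[rep_$features$feature_id == "ASV_A"],
               100 * 80 / 91)
  # summary covers the three thresholds plus the full-removal row (tau = 0)
  expect_setequal(rep_$summary$tau, c(0, 1, 5, 10))
  full_row <- rep_$summary[rep_$summary$tau == 0, ]
  expect_equal(full_row$n_candidates, 2)  # ASV_A and ASV_B detected in controls
  expect_equal(full_row$n_shared, 2)

  # a dataset without controls is skipped with a warning
  md_noctrl <- md; md_noctrl$role <- "experimental"
  expect_warning(empty <- screening_report(tab, md_noctrl), "lacks control")
  expect_equal(nrow(empty$summary), 0L)

  # single control, single feature: 100% abundance
  m1 <- matrix(c(7, 3), 1, 2, dimnames = list("only", c("b", "e")))
  md1 <- data.frame(sample_id = c("b", "e"), role = c("control", "experimental"),
                    dataset = "d", tissue = "gut")
  r1 <- screening_report(as_feature_table(m1), md1)
  expect_equal(r1$features$control, 100)
})
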