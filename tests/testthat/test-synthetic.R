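test_that("generation is deterministic and column totals equal the drawn depths", {
  cfg <- generator_config(n_experimental = 6, n_controls = 2,
                          n_true_features = 30, n_contam_features = 10,
                          depth_range = c(1000, 2000), seed = 42)
  sim1 <- generate_community(cfg)
  sim2 <- generate_community(cfg)
  expect_identical(sim1$table, sim2$table)
  expect_identical(sim1$truth, sim2$truth)
  totals <- colSums(sim1$table)
  expect_true(all(totals >= 1000 & totals <= 2000))
  # singleton injection swaps reads, so totals stay at the drawn depth:
  # regenerating without singletons must give the same totals
  cfg0 <- generator_config(n_experimental = 6, n_controls = 2,
                           n_true_features = 30, n_contam_features = 10,
                           depth_range = c(1000, 2000), singleton_rate = 0, seed = 42)
  expect_equal(unname(totals), unname(colSums(generate_community(cfg0)$table)))

  expect_false(identical(generate_community(generator_config(
    n_experimental = 6, n_controls = 2, n_true_features = 30,
    n_contam_features = 10, depth_range = c(1000, 2000), seed = 43))$table,
    sim1$table))
})

test_that("zero bleed and zero cross-contamination separate the communities", {
  sim <- generate_community(generator_config(
    n_experimental = 8, n_controls = 3, n_true_features = 40,
    n_contam_features = 12, bleed_mean = 0, bleed_sd = 0,
    cross_fraction = 0, singleton_rate = 0, endosymbiont_share = 0,
    depth_range = c(3000, 4000), seed = 7))
  ctrl <- sim$metadata$sample_id[sim$metadata$role == "control"]
  expt <- sim$metadata$sample_id[sim$metadata$role == "experimental"]
  contam <- sim$truth$feature_id[sim$truth$label == "contaminant"]
  true_f <- sim$truth$feature_id[sim$truth$label == "true_resident"]
  expect_equal(sum(sim$table[true_f, ctrl]), 0)   # controls: pool only
  expect_equal(sum(sim$table[contam, expt]), 0)   # tissues: true community only
})

test_that("full bleed makes experimental samples draws from the control pool", {
  sim <- generate_community(generator_config(
    n_experimental = 10, n_controls = 10, n_true_features = 30,
    n_contam_features = 10, bleed_mean = 1, bleed_sd = 0,
    cross_fraction = 0, singleton_rate = 0,
    depth_range = c(5000, 5000), seed = 11))
  true_f <- sim$truth$feature_id[sim$truth$label == "true_resident"]
  expect_equal(sum(sim$table[true_f, ]), 0)
  # pooled compositions of the two groups agree closely (same multinomial law)
  ctrl <- sim$metadata$sample_id[sim$metadata$role == "control"]
  expt <- sim$metadata$sample_id[sim$metadata$role == "experimental"]
  pc <- pooled_relative_abundance(sim$table, ctrl)
  pe <- pooled_relative_abundance(sim$table, expt)
  expect_lt(max(abs(as.numeric(pc) - as.numeric(pe))), 0.03)
})

test_that("the endosymbiont signature is high in tissues, faint in controls", {
  sim <- generate_community(generator_config(
    n_experimental = 10, n_controls = 4, cross_fraction = 0.02,
    depth_range = c(10000, 15000), seed = 13))
  ctrl <- sim$metadata$sample_id[sim$metadata$role == "control"]
  expt <- sim$metadata$sample_id[sim$metadata$role == "experimental"]
  endo <- "T001"
  pe <- pooled_relative_abundance(sim$table, expt)
  pc <- pooled_relative_abundance(sim$table, ctrl)
  expect_gt(as.numeric(pe[endo]), 0.10)  # dominant in tissue
  expect_lt(as.numeric(pc[endo]), 0.02)  # trace leak into controls
  expect_gt(as.numeric(pc[endo]), 0)
})

test_that("recovery metrics handle the boundary cases", {
  truth <- data.frame(feature_id = c("C1", "C2", "T1", "T2"),
                      label = c("contaminant", "contaminant",
                                "true_resident", "true_resident"))
  expect_equal(recovery_metrics(truth, c("C1", "C2")),
               list(precision = 1, recall = 1))
  none <- recovery_metrics(truth, character(0))
  expect_true(is.na(none$precision))
  expect_equal(none$recall, 0)
  all_called <- recovery_metrics(truth, truth$feature_id)
  expect_equal(all_called$precision, 0.5)  # prevalence of contaminants
  expect_equal(all_called$recall, 1)
  no_contam <- truth; no_contam$label <- "true_resident"
  expect_true(is.na(recovery_metrics(no_contam, "C1")$recall))
  expect_error(recovery_metrics(truth, "ghost"),
               class = "asvscreen_validation_error")
})

test_that("the packaged abundance blocks carry the published structure", {
  fx <- table2_fixture()
  expect_length(fx, 5)
  expect_setequal(names(fx), c("Aedes", "Aegypti", "Albopictus",
                               "Anopheles1", "Anopheles2"))
  expect_equal(100 * as.numeric(fx$Aedes$control),
               c(40.06, 19.64, 5.69, 1.11))
  expect_setequal(names(fx$Aedes$tissues), c("gut", "urt", "lrt"))
  expect_setequal(names(fx$Aegypti$tissues), "gut")
  # the Caulobacter ASV is absent from every tissue of its data set
  caulo <- "Anopheles2_Caulobacter_1"
  for (tt in fx$Anopheles2$tissues) expect_equal(as.numeric(tt[caulo]), 0)
  expect_length(fx$Anopheles1$control, 12)
  expect_length(fx$Aegypti$control, 16)
})

test_that("generator configs reject infeasible settings", {
  expect_error(generator_config(n_true_features = 0), class = "asvscreen_spec_error")
  expect_error(generator_config(bleed_mean = 1.2), class = "asvscreen_spec_error")
  expect_error(generator_config(depth_range = c(500, 100)), class = "asvscreen_spec_error")
  expect_error(generator_config(contam_alpha = 0), class = "asvscreen_spec_error")
  expect_error(generate_community(list(seed = 1)), class = "asvscreen_spec_error")
})
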