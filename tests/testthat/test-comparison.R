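test_that("identical arms are degenerate; constant shifts match the closed-form t", {
  x <- c(3.1, 4.2, 5.0, 2.8, 3.9, 4.4)
  res <- paired_compare(x, x)
  expect_identical(res$test_used, "degenerate")
  expect_equal(res$p_value, 1)
  expect_false(res$significant)

  # normal-looking differences: paired t, p equal to the closed form
  withr::local_seed(9)
  y <- x + 0.8 + rnorm(6, 0, 0.1)
  res_t <- paired_compare(y, x)
  expect_identical(res_t$test_used, "paired_t")
  d <- y - x
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res_t$p_value, 2 * pt(-abs(tstat), df = length(d) - 1))
  expect_true(res_t$significant)

  # exactly constant nonzero shift: rank test, all signs agree
  res_c <- paired_compare(x + 1, x)
  expect_identical(res_c$test_used, "wilcoxon_signed_rank")
  expect_true(res_c$significant)
})

test_that("heavy-tailed differences fall through the normality gate to Wilcoxon", {
  withr::local_seed(14)
  x <- rnorm(20)
  y <- x + rcauchy(20)           # Cauchy noise: Shapiro-Wilk rejects
  expect_gt(max(abs(y - x)), 5)  # confirm the fixture really is heavy-tailed
  res <- paired_compare(x, y)
  expect_identical(res$test_used, "wilcoxon_signed_rank")
})

test_that("pairs with missing values are dropped and small inputs error", {
  x <- c(1, 2, NA, 4, 5); y <- c(1.1, NA, 3, 4.2, 5.3)
  res <- paired_compare(x, y)
  expect_equal(res$n_pairs, 3)
  expect_error(paired_compare(1:2, 2:3), class = "asvscreen_data_error")
  expect_error(paired_compare(1:4, 1:3), class = "asvscreen_validation_error")
})

test_that("compare_treatments pairs on id and is invariant to row order", {
  withr::local_seed(33)
  ids <- sprintf("s%02d", 1:12)
  base <- rnorm(12, 5)
  vals <- rbind(
    data.frame(treatment = "none", id = ids, value = base),
    data.frame(treatment = "t1", id = ids, value = base - 0.5 + rnorm(12, 0, 0.05)),
    data.frame(treatment = "t5", id = ids, value = base + rnorm(12, 0, 0.05)))
  cmp <- compare_treatments(vals)
  shuffled <- vals[sample(nrow(vals)), ]
  shuffled$treatment <- factor(shuffled$treatment, levels = c("none", "t1", "t5"))
  cmp2 <- compare_treatments(shuffled)
  expect_equal(cmp$tests$p_value, cmp2$tests$p_value)
  expect_identical(cmp$letters, cmp2$letters)

  # none vs t1 differ; none vs t5 do not
  p_none_t1 <- cmp$tests$p_value[cmp$tests$treatment_a == "none" &
                                 cmp$tests$treatment_b == "t1"]
  expect_lt(p_none_t1, 0.05)
  expect_error(compare_treatments(vals[vals$treatment == "none", ]),
               class = "asvscreen_data_error")
})

test_that("letter displays encode exactly the non-significance graph", {
  trts <- c("none", "full", "t1")
  mk <- function(sig) data.frame(
    treatment_a = c("none", "none", "full"),
    treatment_b = c("full", "t1", "t1"),
    significant = sig)

  # nothing differs: everyone shares one letter
  l <- letter_groups(trts, mk(c(FALSE, FALSE, FALSE)))
  expect_identical(unname(l), c("a", "a", "a"))

  # full differs from both others: unique letter
  l2 <- letter_groups(trts, mk(c(TRUE, FALSE, TRUE)))
  expect_identical(l2[["full"]], "b")
  expect_identical(l2[["none"]], l2[["t1"]])

  # chain: none~t1, t1~full, none!=full -> t1 shares a letter with each
  l3 <- letter_groups(trts, mk(c(TRUE, FALSE, FALSE)))
  expect_identical(l3[["none"]], "a")
  expect_identical(l3[["full"]], "b")
  expect_identical(l3[["t1"]], "ab")

  # everything differs: three distinct letters
  l4 <- letter_groups(trts, mk(c(TRUE, TRUE, TRUE)))
  expect_identical(unname(l4), c("a", "b", "c"))

  # iff property on random graphs: share a letter <=> not significant
  withr::local_seed(61)
  trts5 <- c("none", "full", "t1", "t5", "t10")
  pairs <- t(combn(trts5, 2))
  for (rep in 1:25) {
    sig <- sample(c(TRUE, FALSE), nrow(pairs), replace = TRUE)
    tests <- data.frame(treatment_a = pairs[, 1], treatment_b = pairs[, 2],
                        significant = sig)
    ll <- letter_groups(trts5, tests)
    for (r in seq_len(nrow(tests))) {
      share <- length(intersect(strsplit(ll[[tests$treatment_a[r]]], "")[[1]],
                                strsplit(ll[[tests$treatment_b[r]]], "")[[1]])) > 0
      expect_identical(share, !tests$significant[r])
    }
    expect_true(all(nzchar(ll)))  # every treatment carries at least one letter
  }
})

test_that("alpha and beta long formats pair the right units across treatments", {
  withr::local_seed(71)
  tab <- as_feature_table(random_table(25, 6, lambda = 5))
  tabs <- list(none = tab, trim = tab[-(1:5), ])
  av <- alpha_values_long(tabs, "richness")
  expect_setequal(unique(av$treatment), c("none", "trim"))
  expect_equal(sum(av$treatment == "none"), 6)

  bv <- beta_values_long(tabs, "bray_curtis")
  expect_equal(sum(bv$treatment == "none"), choose(6, 2))
  # the pair key is the unordered sample pair, identical across treatments
  expect_setequal(bv$id[bv$treatment == "none"], bv$id[bv$treatment == "trim"])
  m <- distance_matrix(tabs$trim, "bray_curtis")
  key <- paste(sort(c(colnames(tab)[2], colnames(tab)[5])), collapse = "|")
  expect_equal(bv$value[bv$treatment == "trim" & bv$id == key],
               m[colnames(tab)[2], colnames(tab)[5]])
})
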