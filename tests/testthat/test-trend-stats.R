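test_that("class aggregation sums member species exactly", {
  conc <- matrix(c(60, 40, 5, 30, 20, 2), nrow = 2, byrow = TRUE,
                 dimnames = list(c("s1", "s2"),
                                 c("LPC 18:2", "LPC 16:0", "CE 14:0")))
  agg <- aggregate_by_class(conc)
  expect_equal(agg$totals["s1", "LPC"], 100)
  expect_equal(agg$totals["s2", "LPC"], 50)
  expect_equal(agg$totals[, "CE"], c(s1 = 5, s2 = 2))
  expect_false("FA" %in% agg$classes)  # absent class, absent summary
  # totals equal sums of member species for every subject and class
  expect_equal(rowSums(agg$totals), rowSums(conc))
})

test_that("a planted TG-class slope surfaces as a positive class-total correlation", {
  cfg <- synthetic_config(
    class_composition = c(TG = 40L),
    planted_positive = c("TG 20:4_33:1" = 0.4, "TG 22:6_36:4" = 0.4,
                         "TG 18:3_33:0" = 0.4),
    planted_negative = stats::setNames(numeric(0), character(0)),
    n_latent_clusters = 3L,
    cluster_bmi_effect = 0.4)
  coh <- generate_cohort(cfg, seed = 9)
  agg <- aggregate_by_class(coh$conc)
  expect_gt(cor(agg$totals[, "TG"], coh$meta$bmi, method = "spearman"), 0)
})

test_that("Mann-Whitney matches exact enumeration and symmetry facts", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)  # 2/20 label assignments are as extreme
  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$U, 8)  # nA * nB / 2
  expect_equal(same$p, 1)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("normal-approximation p agrees with exact enumeration on small instances", {
  set.seed(55)
  for (i in 1:50) {
    a <- rnorm(sample(4:9, 1)); b <- rnorm(sample(4:9, 1), mean = runif(1, 0, 2))
    p_exact <- mann_whitney(a, b, exact = TRUE)$p
    p_norm <- mann_whitney(a, b, exact = FALSE)$p
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})

test_that("trend statistic attains its closed-form extremes", {
  up <- jonckheere_terpstra(list(c(1, 2), c(3, 4), c(5, 6)),
                            alternative = "increasing")
  expect_equal(up$statistic, 12)       # maximum = all cross pairs ordered
  expect_equal(up$max_statistic, 12)
  expect_equal(up$p, 1 / 90)
  expect_equal(up$method, "exact")

  down <- jonckheere_terpstra(list(c(5, 6), c(3, 4), c(1, 2)),
                              alternative = "increasing")
  expect_equal(down$statistic, 0)
  expect_gt(down$p, 1 - 1 / 90 - 1e-9)

  tied <- jonckheere_terpstra(list(c(2, 2), c(2, 2), c(2, 2)))
  expect_equal(tied$statistic, 6)      # half the cross-pair count
  expect_equal(tied$z, 0)
  expect_equal(jonckheere_terpstra(list(c(2, 2), c(2, 2), c(2, 2)),
                                   alternative = "increasing")$p, 0.5)
  expect_error(jonckheere_terpstra(list(1:3)), "at least 2")
})

test_that("trend statistic is bounded and complements under group reversal", {
  set.seed(60)
  for (i in 1:25) {
    sizes <- sample(1:5, 3, replace = TRUE)
    groups <- lapply(sizes, function(n) rnorm(n))  # tie-free
    jt <- jonckheere_terpstra(groups)
    expect_gte(jt$statistic, 0)
    expect_lte(jt$statistic, jt$max_statistic)
    rev_jt <- jonckheere_terpstra(rev(groups))
    expect_equal(jt$statistic + rev_jt$statistic, jt$max_statistic)
  }
})

test_that("exact trend p equals the enumeration oracle on all small layouts", {
  set.seed(61)
  layouts <- expand.grid(n1 = 1:3, n2 = 1:3, n3 = 1:3)
  layouts <- layouts[rowSums(layouts) <= 9, ]
  for (r in seq_len(nrow(layouts))) {
    sizes <- as.integer(layouts[r, ])
    groups <- split(rnorm(sum(sizes)), rep(seq_along(sizes), sizes))
    for (alt in c("increasing", "decreasing", "two_sided")) {
      got <- jonckheere_terpstra(groups, alternative = alt, exact_max = 9L)
      expect_equal(got$method, "exact")
      expect_equal(got$p, jt_exact_p_oracle(groups, alt), tolerance = 1e-10,
                   label = sprintf("sizes %s alt %s", toString(sizes), alt))
    }
  }
})

test_that("trend test holds its type-I error under the null", {
  set.seed(62)
  rej <- vapply(1:2000, function(i) {
    groups <- list(rnorm(20), rnorm(20), rnorm(20))
    jonckheere_terpstra(groups)$p < 0.05
  }, logical(1))
  half <- 1.96 * sqrt(0.05 * 0.95 / 2000)
  expect_gt(mean(rej), 0.05 - half)
  expect_lt(mean(rej), 0.05 + half)
})

test_that("class-level statistics table carries the documented columns", {
  coh <- generate_cohort(synthetic_config(
    class_composition = c(CE = 3L, LPC = 2L, TG = 4L),
    planted_positive = c("TG 14:0_28:0" = 0.5),
    planted_negative = c("LPC 14:0" = 0.5),
    n_latent_clusters = 2L), seed = 10)
  tab <- class_stats(coh$conc, coh$meta)
  expect_setequal(tab$lipid_class, c("CE", "LPC", "TG"))
  expect_true(all(c("mean_normal", "sd_obese", "p_normal_vs_obese",
                    "trend_p", "trend_direction", "trend_stars") %in%
                    names(tab)))
  expect_true(all(tab$trend_p >= 0 & tab$trend_p <= 1))
})
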