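make_lsr_fixture <- function(n = 150, seed = 1) {
  set.seed(seed)
  meta <- make_meta(n, bmi = rnorm(n, 27, 4), seed = seed)
  list(meta = meta)
}

test_that("single-candidate accumulation is the reference step", {
  fx <- make_lsr_fixture(seed = 90)
  conc <- matrix(rlnorm(150), 150, 1, dimnames = list(NULL, "sp1"))
  tr <- greedy_accumulate("sp1", conc, fx$meta)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$role, "reference")
  expect_true(tr$accepted)
  expect_equal(attr(tr, "accepted_species"), "sp1")
})

test_that("two complementary halves of a signal are both accepted", {
  set.seed(91)
  n <- 150
  meta <- make_meta(n, bmi = 25, seed = 91)
  s1 <- rlnorm(n); s2 <- rlnorm(n)
  meta$bmi <- 20 + s1 + s2 + rnorm(n, sd = 1.5)
  conc <- cbind(s1 = s1, s2 = s2)
  tr <- greedy_accumulate(c("s1", "s2"), conc, meta)
  expect_true(all(tr$accepted))
  expect_gt(tr$neg_log10_p[2], tr$neg_log10_p[1])
  # the accept decision matches a brute-force refit of both models
  fit1 <- summary(lm(meta$bmi ~ s1 + factor(meta$sex) + meta$age +
                       factor(meta$ethnicity)))$coefficients["s1", 4]
  s12 <- s1 + s2
  fit2 <- summary(lm(meta$bmi ~ s12 + factor(meta$sex) + meta$age +
                       factor(meta$ethnicity)))$coefficients["s12", 4]
  expect_equal(tr$neg_log10_p, -log10(c(fit1, fit2)), tolerance = 1e-10)
  expect_equal(attr(tr, "final_p"), fit2, tolerance = 1e-12)
})

test_that("pure-noise additions to a strong reference are mostly rejected", {
  accepted <- vapply(1:200, function(i) {
    set.seed(5000 + i)
    n <- 120
    meta <- make_meta(n, bmi = 25, seed = 5000 + i)
    ref <- rlnorm(n)
    meta$bmi <- 22 + 2 * ref + rnorm(n)
    conc <- cbind(ref = ref, noise = rlnorm(n))
    tr <- greedy_accumulate(c("ref", "noise"), conc, meta)
    tr$accepted[2]
  }, logical(1))
  expect_lt(mean(accepted), 0.5)
})

test_that("trace bookkeeping: every candidate visited once, best p improves", {
  set.seed(92)
  n <- 136
  meta <- make_meta(n, bmi = rnorm(n, 28, 4), seed = 92)
  conc <- matrix(rlnorm(n * 8), n, 8,
                 dimnames = list(NULL, paste0("sp", 1:8)))
  conc[, 1] <- conc[, 1] * exp(0.05 * meta$bmi)
  tr <- greedy_accumulate(paste0("sp", 1:8), conc, meta)
  expect_equal(nrow(tr), 8L)
  expect_equal(tr$step, 1:8)
  # accepted steps strictly improve on the best -log10(p) before them
  best <- tr$neg_log10_p[1]
  for (i in 2:8) {
    if (tr$accepted[i]) {
      expect_gt(tr$neg_log10_p[i], best)
      best <- tr$neg_log10_p[i]
    }
  }
  expect_equal(-log10(attr(tr, "final_p")), best, tolerance = 1e-12)
  expect_error(greedy_accumulate(character(0), conc, meta), "no candidates")
})

test_that("the ratio follows its defining arithmetic and scale invariance", {
  expect_equal(compute_lsr(5, 5), 1)
  expect_equal(compute_lsr(0, 50), 0)
  expect_error(compute_lsr(2, 0), "undefined")
  set.seed(93)
  pos <- rlnorm(50); neg <- rlnorm(50)
  expect_equal(compute_lsr(3 * pos, 3 * neg), compute_lsr(pos, neg))
})

test_that("per-subject scores drop undefined-ratio subjects with a warning", {
  conc <- matrix(c(1, 2, 3, 4, 5, 0), 3, 2,
                 dimnames = list(paste0("s", 1:3), c("p1", "n1")))
  expect_warning(
    sc <- subject_scores(list(positive = "p1", negative = "n1"), conc),
    "dropped")
  expect_equal(sc$subject, c("s1", "s2"))
  expect_equal(sc$lsr, c(1 / 4, 2 / 5))
})

test_that("LSR association recovers signal and keeps its level under the null", {
  set.seed(94)
  n <- 200
  meta <- make_meta(n, bmi = rnorm(n, 27, 4), seed = 94)
  lsr <- 0.01 * meta$bmi - 0.1
  expect_lt(lsr_association(lsr, meta)$p, 1e-200)
  rej <- vapply(1:400, function(i) {
    lsr_association(rlnorm(n, -3, 0.5), meta)$p < 0.05
  }, logical(1))
  half <- 1.96 * sqrt(0.05 * 0.95 / 400)
  expect_gt(mean(rej), 0.05 - half)
  expect_lt(mean(rej), 0.05 + half)
  expect_error(lsr_association(rep(1, n), meta), "zero-variance")
})

test_that("Youden cut-off separates a perfectly separable toy exactly", {
  co <- roc_youden_cutoff(c(1, 2, 3, 4), c("normal", "normal", "obese", "obese"))
  expect_equal(co$cutoff, 2.5)
  expect_equal(co$sensitivity, 100)
  expect_equal(co$specificity, 100)
  expect_equal(co$youden_j, 1)
  expect_equal(co$direction, ">=")
  expect_error(roc_youden_cutoff(1:4, rep("obese", 4)), "two classes")
})

test_that("Youden maximization equals brute force on random instances", {
  set.seed(95)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    v <- sample(round(rnorm(n, 0, 2), 1))  # ties included
    lab <- sample(c("normal", "obese"), n, TRUE)
    if (length(unique(lab)) < 2) lab[1:2] <- c("normal", "obese")
    got <- roc_youden_cutoff(v, lab)
    expect_equal(got$youden_j, youden_brute_force(v, lab), tolerance = 1e-12)
    expect_equal(got$youden_j,
                 got$sensitivity / 100 + got$specificity / 100 - 1,
                 tolerance = 1e-12)
    expect_gte(got$youden_j, 0)  # direction chosen to make J non-negative
  }
})

test_that("Youden J is invariant under strictly increasing transforms", {
  set.seed(96)
  v <- rlnorm(60)
  lab <- rep(c("normal", "obese"), 30)
  v[lab == "obese"] <- v[lab == "obese"] * 1.8
  a <- roc_youden_cutoff(v, lab)
  b <- roc_youden_cutoff(log(v), lab)
  expect_equal(a$youden_j, b$youden_j, tolerance = 1e-12)
  expect_equal(a$sensitivity, b$sensitivity)
  # the positive calls agree as sets
  call_a <- v >= a$cutoff
  call_b <- log(v) >= b$cutoff
  expect_identical(call_a, call_b)
})

test_that("labels independent of values give a small Youden J", {
  set.seed(97)
  js <- vapply(1:200, function(i) {
    v <- rnorm(400)
    lab <- sample(rep(c("normal", "obese"), 200))
    roc_youden_cutoff(v, lab)$youden_j
  }, numeric(1))
  expect_lt(mean(js), 0.15)
})

test_that("the reference-value report has the documented shape", {
  coh <- generate_cohort(synthetic_config(), seed = 98)
  panel <- list(positive = coh$truth$planted_positive,
                negative = coh$truth$planted_negative)
  sc <- subject_scores(panel, coh$conc)
  rep1 <- reference_value_report(sc, coh$meta)
  rep2 <- reference_value_report(sc, coh$meta)
  expect_identical(rep1, rep2)  # deterministic regeneration
  expect_equal(rep1$variable, c("positive_sum", "negative_sum", "lsr"))
  expect_true(all(c("cutoff", "direction", "sensitivity", "specificity",
                    "youden_j", "mean_normal", "sd_normal", "mean_obese",
                    "sd_obese", "p_mann_whitney") %in% names(rep1)))
  expect_true(all(rep1$youden_j >= -1 & rep1$youden_j <= 1))
  # planted positive panel separates obese upward, negative panel downward
  expect_gt(rep1$mean_obese[1], rep1$mean_normal[1])
  expect_lt(rep1$mean_obese[2], rep1$mean_normal[2])
})
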