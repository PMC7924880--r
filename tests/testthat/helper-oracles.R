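# Independent brute-force oracles used across the suite. These deliberately
# take the slow, obviously-correct route and share no code with the package
# implementations they check.

# all distinct assignments of the pooled values to ordered groups of the
# given sizes; returns the full null distribution of the trend statistic
jt_stat_naive <- function(groups) {
  s <- 0
  k <- length(groups)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      for (x in groups[[i]]) for (y in groups[[j]]) {
        s <- s + (x < y) + 0.5 * (x == y)
      }
    }
  }
  s
}

jt_null_enumerate <- function(pooled, sizes) {
  stats_out <- numeric(0)
  recurse <- function(remaining_idx, gi, acc) {
    if (gi > length(sizes)) {
      stats_out[length(stats_out) + 1] <<- jt_stat_naive(acc)
      return(invisible(NULL))
    }
    if (gi == length(sizes)) {
      recurse(integer(0), gi + 1L, c(acc, list(pooled[remaining_idx])))
      return(invisible(NULL))
    }
    picks <- utils::combn(remaining_idx, sizes[gi], simplify = FALSE)
    for (pk in picks) {
      recurse(setdiff(remaining_idx, pk), gi + 1L,
              c(acc, list(pooled[pk])))
    }
  }
  recurse(seq_along(pooled), 1L, list())
  stats_out
}

jt_exact_p_oracle <- function(groups, alternative = "increasing") {
  pooled <- unlist(groups)
  sizes <- lengths(groups)
  null_stats <- jt_null_enumerate(pooled, sizes)
  obs <- jt_stat_naive(groups)
  p_up <- mean(null_stats >= obs - 1e-9)
  p_dn <- mean(null_stats <= obs + 1e-9)
  switch(alternative,
         increasing = p_up,
         decreasing = p_dn,
         two_sided = min(1, 2 * min(p_up, p_dn)))
}

# exhaustive Youden maximization: every observed value and midpoint, both
# positivity directions
youden_brute_force <- function(values, labels, positive = "obese") {
  is_pos <- labels == positive
  thr <- sort(unique(c(values, (sort(unique(values))[-1] +
                                  rev(rev(sort(unique(values)))[-1])) / 2,
                       -Inf, Inf)))
  best <- -Inf
  for (t in thr) {
    for (dir in c("ge", "lt")) {
      called <- if (dir == "ge") values >= t else values < t
      j <- sum(called & is_pos) / sum(is_pos) +
        sum(!called & !is_pos) / sum(!is_pos) - 1
      best <- max(best, j)
    }
  }
  best
}

# dense angle grid search for the 2-factor varimax optimum
varimax_grid_oracle <- function(L, n_grid = 4000) {
  angles <- seq(0, pi / 2, length.out = n_grid)
  best <- -Inf
  for (a in angles) {
    R <- matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2)
    best <- max(best, varimax_criterion(L %*% R, normalize = TRUE))
  }
  best
}

# tiny cohort builder for regression-based stages: metadata with covariates
make_meta <- function(n, bmi, seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = runif(n, 25, 60),
    sex = sample(c("male", "female"), n, TRUE),
    ethnicity = sample(c("HG", "HR"), n, TRUE),
    bmi = bmi,
    stringsAsFactors = FALSE)
}

# fixture names covering all 13 lipid classes
fixture_names_13 <- c(
  "Cer 18:1;O2/24:0", "CE 14:0", "DG 16:0_18:1", "ACer 18:1;O2/24:0/16:0",
  "FA 16:0", "Hex-Cer 18:1;O2/22:0", "LacCer 18:1;O2/16:0", "LPC 18:2",
  "LPE 18:0", "PC 18:1_18:1", "PE P-16:0/20:3", "SM 18:1;O2/20:0",
  "TG 20:4_33:1")
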