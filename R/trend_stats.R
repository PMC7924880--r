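#' Aggregate species concentrations to lipid-class totals
#'
#' Sums raw (pre-normalization) per-subject concentrations over all species of
#' each lipid class present in the table.
#'
#' @param conc Numeric matrix, subjects x species, columns named by species.
#' @param classes Optional character vector of class codes per column; parsed
#'   from the column names when missing.
#' @return A list with `totals` (subjects x classes matrix, umol/L) and
#'   `classes` (codes, in [lipid_classes()] order, only those present).
#' @export
aggregate_by_class <- function(conc, classes = NULL) {
  stopifnot(is.matrix(conc), !is.null(colnames(conc)))
  if (is.null(classes)) {
    classes <- vapply(colnames(conc), class_of, character(1))
  }
  stopifnot(length(classes) == ncol(conc))
  present <- intersect(lipid_classes()$code, unique(classes))
  totals <- vapply(present, function(cl) {
    rowSums(conc[, classes == cl, drop = FALSE])
  }, numeric(nrow(conc)))
  if (is.null(dim(totals))) totals <- matrix(totals, nrow = 1L,
                                             dimnames = list(NULL, present))
  rownames(totals) <- rownames(conc)
  list(totals = totals, classes = present)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two groups, with mean ranks for ties. The
#' p-value is exact (network enumeration) when `nA * nB <= 400` and the data
#' are tie-free, otherwise a tie-corrected normal approximation is used.
#'
#' @param group_a,group_b Numeric vectors, each non-empty.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) the exact p-value;
#'   `NULL` (default) decides by the size rule above. Exact is never used in
#'   the presence of ties.
#' @return A list with `U` (statistic for `group_a`) and `p` (two-sided).
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
mann_whitney <- function(group_a, group_b, exact = NULL) {
  stopifnot(is.numeric(group_a), is.numeric(group_b))
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(group_a, group_b)) > 0L
  use_exact <- if (is.null(exact)) {
    !ties && length(group_a) * length(group_b) <= 400
  } else {
    exact && !ties
  }
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = use_exact,
                       alternative = "two.sided")
  )
  list(U = unname(wt$statistic), p = unname(wt$p.value))
}

.jt_statistic <- function(groups) {
  k <- length(groups)
  jt <- 0
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      d <- outer(groups[[i]], groups[[j]], "<")
      e <- outer(groups[[i]], groups[[j]], "==")
      jt <- jt + sum(d) + 0.5 * sum(e)
    }
  }
  jt
}

# exact tie-free null pmf of the trend statistic: the statistic decomposes as a
# sum of independent Mann-Whitney statistics of each group against the pooled
# earlier groups, so the null pmf is their convolution (dwilcox supplies each)
.jt_exact_pmf <- function(sizes) {
  pmf <- 1
  cum <- sizes[1L]
  for (j in seq.int(2L, length(sizes))) {
    m <- sizes[j]
    u_pmf <- stats::dwilcox(0:(m * cum), m, cum)
    new <- numeric(length(pmf) + length(u_pmf) - 1L)
    for (u in seq_along(u_pmf)) {
      idx <- seq_along(pmf) + u - 1L
      new[idx] <- new[idx] + pmf * u_pmf[u]
    }
    pmf <- new
    cum <- cum + m
  }
  pmf  # pmf[s + 1] = P(JT = s)
}

#' Jonckheere-Terpstra trend test for ordered groups
#'
#' Tests for a monotone location trend across ordered groups (e.g. BMI
#' categories normal < overweight < obese). The statistic counts, over all
#' ordered group pairs, pairs of observations in the hypothesized order (ties
#' count one half). For tie-free data with total n at most `exact_max` the
#' p-value is exact (convolution of Mann-Whitney null distributions);
#' otherwise a tie-corrected normal approximation is used.
#'
#' @param groups List of numeric vectors in their hypothesized order; at least
#'   2 groups (3 or more for a meaningful trend), each non-empty.
#' @param alternative `"two_sided"` (default), `"increasing"`, or
#'   `"decreasing"`.
#' @param exact_max Largest tie-free total n for which the exact null is used
#'   (default 12; set 0 to force the normal approximation).
#' @return An object of class `jt_test`: a list with `statistic` (JT), `z`,
#'   `p`, `direction` (sign of the observed departure from the null mean, or
#'   `"none"`), `method` (`"exact"` or `"normal"`), and `alternative`.
#' @export
#' @examples
#' jonckheere_terpstra(list(c(1, 2), c(3, 4), c(5, 6)),
#'                     alternative = "increasing")  # JT = 12, p = 1/90
jonckheere_terpstra <- function(groups,
                                alternative = c("two_sided", "increasing",
                                                "decreasing"),
                                exact_max = 12L) {
  alternative <- match.arg(alternative)
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least 2 ordered groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes == 0L)) stop("every group must be non-empty", call. = FALSE)
  pooled <- unlist(groups, use.names = FALSE)
  stopifnot(is.numeric(pooled))
  n_tot <- sum(sizes)
  jt <- .jt_statistic(groups)
  cross_pairs <- (n_tot^2 - sum(sizes^2)) / 2
  mu <- cross_pairs / 2

  ties_tab <- table(pooled)
  has_ties <- any(ties_tab > 1L)

  # tie-corrected null variance (Hollander & Wolfe)
  tj <- as.numeric(ties_tab)
  ni <- as.numeric(sizes)
  A <- n_tot * (n_tot - 1) * (2 * n_tot + 5) -
    sum(ni * (ni - 1) * (2 * ni + 5)) -
    sum(tj * (tj - 1) * (2 * tj + 5))
  B <- sum(ni * (ni - 1) * (ni - 2)) * sum(tj * (tj - 1) * (tj - 2))
  C <- sum(ni * (ni - 1)) * sum(tj * (tj - 1))
  v <- A / 72 + B / (36 * n_tot * (n_tot - 1) * (n_tot - 2)) +
    C / (8 * n_tot * (n_tot - 1))
  z <- if (v > 0) (jt - mu) / sqrt(v) else 0

  if (!has_ties && n_tot <= exact_max) {
    pmf <- .jt_exact_pmf(sizes)
    s <- round(jt)
    p_up <- sum(pmf[(s + 1L):length(pmf)])
    p_dn <- sum(pmf[1L:(s + 1L)])
    method <- "exact"
  } else {
    p_up <- stats::pnorm(z, lower.tail = FALSE)
    p_dn <- stats::pnorm(z)
    method <- "normal"
  }
  p <- switch(alternative,
              increasing = p_up,
              decreasing = p_dn,
              two_sided = min(1, 2 * min(p_up, p_dn)))
  direction <- if (jt > mu) "increasing" else if (jt < mu) "decreasing"
  else "none"
  structure(list(statistic = jt, z = z, p = p, direction = direction,
                 method = method, alternative = alternative,
                 null_mean = mu, null_var = v,
                 max_statistic = cross_pairs),
            class = "jt_test")
}

#' @export
print.jt_test <- function(x, ...) {
  cat(sprintf(
    "Jonckheere-Terpstra trend test (%s)\nJT = %.1f (null mean %.1f), z = %.3f, p = %.4g (%s), direction: %s\n",
    x$method, x$statistic, x$null_mean, x$z, x$p, x$alternative, x$direction))
  invisible(x)
}

.sig_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Class-level group comparison table
#'
#' For each lipid class: per-BMI-category mean and SD of the per-subject class
#' total, pairwise Mann-Whitney p-values, and the ordered-trend test across
#' categories, with three-tier significance labels (0.05 / 0.01 / 0.001).
#' Runs on untransformed concentrations (rank tests are invariant to monotone
#' transforms).
#'
#' @param conc Subjects x species concentration matrix (raw umol/L).
#' @param meta Metadata data frame with a `bmi_category` ordered factor.
#' @param alternative Trend alternative passed to [jonckheere_terpstra()].
#' @return A data frame, one row per class.
#' @export
class_stats <- function(conc, meta, alternative = "two_sided") {
  stopifnot(nrow(conc) == nrow(meta), "bmi_category" %in% names(meta))
  agg <- aggregate_by_class(conc)
  cats <- levels(meta$bmi_category)
  rows <- lapply(agg$classes, function(cl) {
    x <- agg$totals[, cl]
    by_cat <- split(x, meta$bmi_category)
    mw_no <- mann_whitney(by_cat[[1]], by_cat[[2]])
    mw_nb <- mann_whitney(by_cat[[1]], by_cat[[3]])
    mw_ob <- mann_whitney(by_cat[[2]], by_cat[[3]])
    jt <- jonckheere_terpstra(by_cat, alternative = alternative)
    out <- data.frame(lipid_class = cl, stringsAsFactors = FALSE)
    for (ct in cats) {
      out[[paste0("mean_", ct)]] <- mean(by_cat[[ct]])
      out[[paste0("sd_", ct)]] <- stats::sd(by_cat[[ct]])
    }
    out$p_normal_vs_overweight <- mw_no$p
    out$p_normal_vs_obese <- mw_nb$p
    out$p_overweight_vs_obese <- mw_ob$p
    out$trend_p <- jt$p
    out$trend_direction <- jt$direction
    out$trend_stars <- .sig_stars(jt$p)
    out
  })
  do.call(rbind, rows)
}
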