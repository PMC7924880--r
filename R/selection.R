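#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise level (default 0.05).
#' @param k Number of independent analyses, a positive integer.
#' @return `alpha / k`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 9)  # 0.00555..., prints as 0.0055 at 4 decimals
bonferroni_threshold <- function(alpha = 0.05, k) {
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop("'k' must be a positive integer", call. = FALSE)
  }
  alpha / k
}

# one stepwise fit: forward entry / backward removal of candidate columns of
# `cand` predicting `y`, with the covariate design `Xc` forced into every
# model. Deterministic: the entering candidate is the one with the smallest
# p-value (ties broken by column order, i.e. candidate name order).
.stepwise_ols <- function(y, cand, Xc, entry_p = 0.05, removal_p = 0.10) {
  stopifnot(entry_p <= removal_p)
  in_model <- integer(0)
  pool <- seq_len(ncol(cand))
  repeat {
    changed <- FALSE
    # forward entry
    out_pool <- setdiff(pool, in_model)
    if (length(out_pool) > 0L) {
      ps <- vapply(out_pool, function(j) {
        X <- cbind(cand[, c(in_model, j), drop = FALSE], Xc)
        fit <- tryCatch(.ols(y, X), error = function(e) NULL)
        if (is.null(fit)) return(NA_real_)
        unname(fit$p[length(in_model) + 1L])
      }, numeric(1))
      ok <- which(!is.na(ps) & ps < entry_p)
      if (length(ok) > 0L) {
        j_new <- out_pool[ok[which.min(ps[ok])]]
        in_model <- c(in_model, j_new)
        changed <- TRUE
      }
    }
    # backward removal
    repeat {
      if (length(in_model) == 0L) break
      X <- cbind(cand[, in_model, drop = FALSE], Xc)
      fit <- .ols(y, X)
      ps_in <- fit$p[seq_along(in_model)]
      worst <- which.max(ps_in)
      if (ps_in[worst] > removal_p) {
        in_model <- in_model[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  if (length(in_model) == 0L) {
    return(data.frame(species = character(0), beta = numeric(0),
                      p = numeric(0), neg_log10_p = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  }
  X <- cbind(cand[, in_model, drop = FALSE], Xc)
  fit <- .ols(y, X)
  idx <- seq_along(in_model)
  data.frame(
    species = colnames(cand)[in_model],
    beta = unname(fit$coef[idx]),
    p = unname(fit$p[idx]),
    neg_log10_p = -log10(pmax(unname(fit$p[idx]), .Machine$double.xmin)),
    direction = ifelse(fit$coef[idx] >= 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
}

#' Per-cluster stepwise selection of BMI-associated species
#'
#' Within each cluster of the species assignment, runs forward-entry /
#' backward-removal stepwise ordinary least squares of BMI on the cluster's
#' candidate species concentrations, with sex, age and ethnicity forced into
#' every model. Entry requires p < `entry_p`, removal p > `removal_p`
#' (defaults 0.05 / 0.10); the procedure iterates to a fixed point and is
#' deterministic given the data. Candidates that are perfectly collinear with
#' species already in the model can never enter (the rank check rejects them).
#'
#' @param conc Subjects x species matrix of (normalized) concentrations used
#'   for the regressions.
#' @param meta Metadata data frame (`bmi`, `sex`, `age`, `ethnicity`).
#' @param assignment Species assignment data frame from [assign_species()].
#' @param entry_p,removal_p Stepwise thresholds.
#' @return A data frame with one row per selected species: `cluster`,
#'   `species`, `beta`, `p`, `neg_log10_p`, `direction`.
#' @export
stepwise_per_cluster <- function(conc, meta, assignment,
                                 entry_p = 0.05, removal_p = 0.10) {
  stopifnot(nrow(conc) == nrow(meta))
  Xc <- .covariate_design(meta)
  assigned <- assignment[!is.na(assignment$cluster), , drop = FALSE]
  clusters <- unique(assigned$cluster)
  rows <- lapply(clusters, function(cl) {
    sp <- assigned$species[assigned$cluster == cl]
    sel <- .stepwise_ols(meta$bmi, conc[, sp, drop = FALSE], Xc,
                         entry_p = entry_p, removal_p = removal_p)
    if (nrow(sel) == 0L) return(NULL)
    cbind(data.frame(cluster = cl, stringsAsFactors = FALSE), sel)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) {
    return(data.frame(cluster = character(0), species = character(0),
                      beta = numeric(0), p = numeric(0),
                      neg_log10_p = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Partition selected species by significance and rank them per direction
#'
#' Splits the stepwise-selected species into nominally significant (p < 0.05)
#' and Bonferroni-significant (p < `threshold`) sets, and ranks candidates
#' within each direction of association by descending `-log10(p)` (ties broken
#' by species name) — the ordering the greedy ratio construction consumes.
#'
#' @param results Stepwise result data frame from [stepwise_per_cluster()].
#' @param threshold Bonferroni-corrected threshold (see
#'   [bonferroni_threshold()]).
#' @param alpha Nominal level (default 0.05).
#' @return A list with `nominal`, `bonferroni` (data frames), and `ranked`
#'   (list with `positive` and `negative` data frames in accumulation order).
#' @export
classify_candidates <- function(results, threshold, alpha = 0.05) {
  stopifnot(is.data.frame(results))
  nominal <- results[results$p < alpha, , drop = FALSE]
  bonf <- results[results$p < threshold, , drop = FALSE]
  rank_dir <- function(df, dir) {
    d <- df[df$direction == dir, , drop = FALSE]
    d[order(-d$neg_log10_p, d$species), , drop = FALSE]
  }
  list(nominal = nominal,
       bonferroni = bonf,
       ranked = list(positive = rank_dir(bonf, "positive"),
                     negative = rank_dir(bonf, "negative")),
       ranked_nominal = list(positive = rank_dir(nominal, "positive"),
                             negative = rank_dir(nominal, "negative")))
}
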