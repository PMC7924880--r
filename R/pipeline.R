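#' Control parameters of the lipidome analysis pipeline
#'
#' Every default equals the analysis' stated operating point: QC tolerance
#' +/- 20 percent, eigenvalue retention threshold 2.0, absolute-loading
#' threshold 0.5, nominal alpha 0.05, stepwise entry/removal 0.05/0.10,
#' Bonferroni divisor = number of clusters yielding at least one nominally
#' significant species, greedy accumulation restricted to
#' Bonferroni-significant candidates, ROC contrast normal vs obese.
#'
#' @param qc_tolerance Relative QC deviation tolerance.
#' @param eigenvalue_threshold Component retention threshold.
#' @param loading_threshold Species-assignment loading threshold.
#' @param alpha Nominal significance level.
#' @param entry_p,removal_p Stepwise thresholds.
#' @param bonferroni_divisor `"clusters_with_nominal"` (default),
#'   `"clusters_tested"`, or a positive integer.
#' @param candidate_mode `"bonferroni"` (default) or `"nominal"`: which
#'   significance tier feeds the greedy accumulation.
#' @param normalization_gate `"shapiro"` (default) or `"all"`.
#' @param adjusted_accumulation Adjust per-step greedy regressions for sex,
#'   age and ethnicity (default TRUE).
#' @return An `lsr_control` list.
#' @export
lsr_control <- function(qc_tolerance = 0.20,
                        eigenvalue_threshold = 2.0,
                        loading_threshold = 0.5,
                        alpha = 0.05,
                        entry_p = 0.05,
                        removal_p = 0.10,
                        bonferroni_divisor = "clusters_with_nominal",
                        candidate_mode = c("bonferroni", "nominal"),
                        normalization_gate = c("shapiro", "all"),
                        adjusted_accumulation = TRUE) {
  candidate_mode <- match.arg(candidate_mode)
  normalization_gate <- match.arg(normalization_gate)
  stopifnot(qc_tolerance > 0, eigenvalue_threshold >= 0,
            loading_threshold >= 0, alpha > 0, alpha < 1,
            entry_p <= removal_p)
  if (is.numeric(bonferroni_divisor)) {
    stopifnot(bonferroni_divisor >= 1)
  } else {
    stopifnot(bonferroni_divisor %in%
                c("clusters_with_nominal", "clusters_tested"))
  }
  structure(list(
    qc_tolerance = qc_tolerance,
    eigenvalue_threshold = eigenvalue_threshold,
    loading_threshold = loading_threshold,
    alpha = alpha, entry_p = entry_p, removal_p = removal_p,
    bonferroni_divisor = bonferroni_divisor,
    candidate_mode = candidate_mode,
    normalization_gate = normalization_gate,
    adjusted_accumulation = adjusted_accumulation
  ), class = "lsr_control")
}

#' Fit the full lipid-species-ratio pipeline
#'
#' Runs the complete hierarchical analysis on a subjects x species
#' concentration table: per-variable two-step normalization (Shapiro-Wilk
#' gated), class-level trend statistics, principal-component clustering of
#' species with varimax rotation, covariate-adjusted cluster-BMI association,
#' loading-based species assignment, per-cluster stepwise selection with
#' Bonferroni control, greedy sum-accumulation of the positive and negative
#' panels, the per-subject lipid species ratio (LSR), its adjusted
#' association with BMI, and ROC/Youden reference cut-offs contrasting
#' normal-weight against obese subjects. Stage order is fixed.
#'
#' @param conc Numeric matrix, subjects x species, raw concentrations in
#'   umol/L; column names must be parseable lipid shorthand.
#' @param meta Data frame aligned with the rows of `conc`, with columns
#'   `subject_id`, `age`, `sex`, `ethnicity`, `bmi` (and optionally
#'   `bmi_category`, recomputed if absent).
#' @param batches Optional list of [batch_record()] objects; when given, QC
#'   batch filtering and blank correction are applied before analysis.
#' @param control An [lsr_control()] list.
#' @param class_statistics Compute the class-level trend table (default TRUE).
#' @return An object of class `lipid_lsr`; see [print.lipid_lsr()],
#'   [summary.lipid_lsr()], [coef.lipid_lsr()], [predict.lipid_lsr()],
#'   [plot.lipid_lsr()]. Key fields: `epca`, `associations`, `assignment`,
#'   `stepwise`, `classification`, `traces`, `panel`, `scores`,
#'   `lsr_association`, `reference_values`, `counts` (the stage funnel), and
#'   `status` (`"ok"` or `"no LSR constructed"`).
#' @export
lipid_lsr <- function(conc, meta, batches = NULL, control = lsr_control(),
                      class_statistics = TRUE) {
  cl <- match.call()
  stopifnot(is.matrix(conc), nrow(conc) == nrow(meta))
  if (is.null(meta$bmi_category)) meta$bmi_category <- bmi_category(meta$bmi)
  if (anyNA(meta[c("age", "sex", "ethnicity", "bmi")])) {
    stop("subjects with missing metadata must be excluded first",
         call. = FALSE)
  }

  qc <- NULL
  if (!is.null(batches)) {
    qc <- qc_batch_filter(batches, tolerance = control$qc_tolerance)
    keep <- meta$subject_id %in% qc$retained_subjects
    meta <- meta[keep, , drop = FALSE]
    conc <- conc[keep, , drop = FALSE]
    blank <- Reduce(`+`, lapply(batches, `[[`, "blank")) / length(batches)
    if (!is.null(blank)) {
      bsp <- intersect(names(blank), colnames(conc))
      conc[, bsp] <- blank_correct(conc[, bsp, drop = FALSE],
                                   matrix(blank[bsp], nrow(conc),
                                          length(bsp), byrow = TRUE))
    }
  }

  cstats <- if (class_statistics) class_stats(conc, meta) else NULL

  norm <- normalize_cohort(conc, gate = control$normalization_gate,
                           alpha = control$alpha)
  epca <- epca_fit(norm$conc,
                   eigenvalue_threshold = control$eigenvalue_threshold)
  counts <- list(n_subjects = nrow(conc), n_species = ncol(conc),
                 clusters_retained = epca$retained_k)

  if (epca$retained_k == 0L) {
    res <- list(call = cl, control = control, meta = meta, qc = qc,
                class_stats = cstats, normalized = norm$transformed,
                epca = epca, associations = NULL, assignment = NULL,
                stepwise = NULL, classification = NULL, traces = NULL,
                panel = NULL, scores = NULL, lsr_association = NULL,
                reference_values = NULL, counts = counts,
                status = "no LSR constructed")
    return(structure(res, class = "lipid_lsr"))
  }

  assoc <- cluster_bmi_association(epca$scores, meta, alpha = control$alpha)
  assignment <- assign_species(epca, control$loading_threshold)
  counts$species_assigned <- sum(!is.na(assignment$cluster))
  counts$clusters_with_species <-
    length(unique(stats::na.omit(assignment$cluster)))

  sw <- stepwise_per_cluster(conc = norm$conc, meta = meta,
                             assignment = assignment,
                             entry_p = control$entry_p,
                             removal_p = control$removal_p)
  divisor <- control$bonferroni_divisor
  if (identical(divisor, "clusters_with_nominal")) {
    divisor <- max(1L, length(unique(
      sw$cluster[sw$p < control$alpha])))
  } else if (identical(divisor, "clusters_tested")) {
    divisor <- max(1L, counts$clusters_with_species)
  }
  thr <- bonferroni_threshold(control$alpha, divisor)
  cls_cand <- classify_candidates(sw, threshold = thr, alpha = control$alpha)
  counts$nominal <- nrow(cls_cand$nominal)
  counts$bonferroni <- nrow(cls_cand$bonferroni)
  counts$bonferroni_divisor <- divisor
  counts$bonferroni_threshold <- thr

  ranked <- if (control$candidate_mode == "bonferroni") cls_cand$ranked else
    cls_cand$ranked_nominal
  if (nrow(ranked$positive) == 0L || nrow(ranked$negative) == 0L) {
    res <- list(call = cl, control = control, meta = meta, qc = qc,
                class_stats = cstats, normalized = norm$transformed,
                epca = epca, associations = assoc, assignment = assignment,
                stepwise = sw, classification = cls_cand, traces = NULL,
                panel = NULL, scores = NULL, lsr_association = NULL,
                reference_values = NULL, counts = counts,
                status = "no LSR constructed")
    return(structure(res, class = "lipid_lsr"))
  }

  traces <- list(
    positive = greedy_accumulate(ranked$positive$species, conc, meta,
                                 direction = "positive",
                                 adjusted = control$adjusted_accumulation),
    negative = greedy_accumulate(ranked$negative$species, conc, meta,
                                 direction = "negative",
                                 adjusted = control$adjusted_accumulation))
  panel <- list(positive = attr(traces$positive, "accepted_species"),
                negative = attr(traces$negative, "accepted_species"))
  counts$panel_positive <- length(panel$positive)
  counts$panel_negative <- length(panel$negative)

  scores <- subject_scores(panel, conc)
  m_sc <- meta[match(scores$subject, meta$subject_id), , drop = FALSE]
  lsr_a <- lsr_association(scores$lsr, m_sc)
  refs <- reference_value_report(scores, meta)

  res <- list(call = cl, control = control, meta = meta, qc = qc,
              class_stats = cstats, normalized = norm$transformed,
              epca = epca, associations = assoc, assignment = assignment,
              stepwise = sw, classification = cls_cand, traces = traces,
              panel = panel, scores = scores, lsr_association = lsr_a,
              reference_values = refs, counts = counts, status = "ok")
  structure(res, class = "lipid_lsr")
}

#' @rdname lipid_lsr
#' @param x,object A `lipid_lsr` object.
#' @param ... Unused.
#' @export
print.lipid_lsr <- function(x, ...) {
  cat("Lipid species ratio pipeline\n")
  cn <- x$counts
  cat(sprintf("  subjects: %d, species: %d\n", cn$n_subjects, cn$n_species))
  cat(sprintf("  clusters retained (eigenvalue >= %.2g): %d (%.2f%% variance)\n",
              x$control$eigenvalue_threshold, cn$clusters_retained,
              100 * x$epca$variance_explained))
  if (x$status == "ok") {
    cat(sprintf("  species assigned: %d in %d cluster(s)\n",
                cn$species_assigned, cn$clusters_with_species))
    cat(sprintf("  stepwise: %d nominal, %d Bonferroni-significant (p < %.4f)\n",
                cn$nominal, cn$bonferroni, cn$bonferroni_threshold))
    cat(sprintf("  panel: %d positive + %d negative species\n",
                cn$panel_positive, cn$panel_negative))
    cat(sprintf("  LSR ~ BMI (adjusted): beta = %.4g, -log10(p) = %.3f\n",
                x$lsr_association$beta, x$lsr_association$neg_log10_p))
  } else {
    cat("  status:", x$status, "\n")
  }
  invisible(x)
}

#' @rdname lipid_lsr
#' @export
summary.lipid_lsr <- function(object, ...) {
  print(object)
  if (!is.null(object$traces)) {
    cat("\nGreedy accumulation traces:\n")
    for (d in names(object$traces)) {
      tr <- object$traces[[d]]
      cat(sprintf(" %s: accepted steps %s\n", d,
                  paste(tr$step[tr$accepted], collapse = ", ")))
    }
  }
  if (!is.null(object$reference_values)) {
    cat("\nReference cut-offs (normal vs obese):\n")
    print(object$reference_values, digits = 4)
  }
  invisible(object)
}

#' @rdname lipid_lsr
#' @export
coef.lipid_lsr <- function(object, ...) {
  if (object$status != "ok") return(NULL)
  m <- object$meta[match(object$scores$subject, object$meta$subject_id), ,
                   drop = FALSE]
  X <- cbind(lsr = object$scores$lsr, .covariate_design(m))
  fit <- .ols(m$bmi, X)
  stats::setNames(as.numeric(fit$coef), colnames(X))
}

#' @rdname lipid_lsr
#' @export
residuals.lipid_lsr <- function(object, ...) {
  if (object$status != "ok") return(NULL)
  m <- object$meta[match(object$scores$subject, object$meta$subject_id), ,
                   drop = FALSE]
  X <- cbind(lsr = object$scores$lsr, .covariate_design(m))
  .ols(m$bmi, X)$residuals
}

#' @rdname lipid_lsr
#' @param newdata Subjects x species concentration matrix (umol/L) covering
#'   the panel species.
#' @export
predict.lipid_lsr <- function(object, newdata, ...) {
  if (object$status != "ok") {
    stop("no LSR panel was constructed for this fit", call. = FALSE)
  }
  if (missing(newdata)) return(object$scores)
  subject_scores(object$panel, as.matrix(newdata))
}

#' @rdname lipid_lsr
#' @export
plot.lipid_lsr <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  ev <- x$epca$eigenvalues
  graphics::plot(seq_along(ev), ev, type = "h", xlab = "component",
                 ylab = "eigenvalue", main = "Scree")
  graphics::abline(h = x$control$eigenvalue_threshold, lty = 2)
  if (!is.null(x$stepwise) && nrow(x$stepwise) > 0) {
    graphics::plot(seq_len(nrow(x$stepwise)), x$stepwise$neg_log10_p,
                   col = factor(x$stepwise$cluster), pch = 19,
                   xlab = "selected species", ylab = "-log10(p)",
                   main = "Stepwise selection")
    graphics::abline(h = -log10(x$control$alpha), lty = 2)
    if (!is.null(x$counts$bonferroni_threshold)) {
      graphics::abline(h = -log10(x$counts$bonferroni_threshold),
                       lty = 2, col = 2)
    }
  }
  invisible(x)
}

#' Cohort accounting arithmetic
#'
#' Reproduces the recruitment funnel: recruited minus pre-analysis exclusions
#' gives the eligible pool, the randomly selected sample minus QC-excluded
#' subjects gives the analyzed cohort, and representation percentages are
#' reported to two decimals.
#'
#' @param recruited Number recruited.
#' @param excluded Numeric vector of pre-selection exclusion counts.
#' @param selected Number randomly selected for the assay.
#' @param qc_excluded Number dropped by QC batch filtering.
#' @return A list with `eligible`, `analyzed` and the echoed inputs.
#' @export
#' @examples
#' acc <- cohort_accounting(832, c(35, 32), 190, 54)
#' acc$eligible  # 765
#' acc$analyzed  # 136
cohort_accounting <- function(recruited, excluded = 0, selected, qc_excluded) {
  stopifnot(recruited >= 0, all(excluded >= 0), selected >= 0,
            qc_excluded >= 0)
  eligible <- recruited - sum(excluded)
  if (eligible < 0) stop("more exclusions than recruited", call. = FALSE)
  if (selected > eligible) {
    stop("cannot select more subjects than eligible", call. = FALSE)
  }
  analyzed <- selected - qc_excluded
  if (analyzed < 0) stop("more QC exclusions than selected", call. = FALSE)
  list(recruited = recruited, excluded = sum(excluded), eligible = eligible,
       selected = selected, qc_excluded = qc_excluded, analyzed = analyzed)
}

#' Representation percentage
#'
#' Share of a stratum in a whole, in percent to two decimals.
#'
#' @param part,whole Non-negative counts, `whole > 0`.
#' @return `round(100 * part / whole, 2)`.
#' @export
#' @examples
#' representation_pct(57, 136)  # 41.91
representation_pct <- function(part, whole) {
  stopifnot(whole > 0, part >= 0)
  round(100 * part / whole, 2)
}
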