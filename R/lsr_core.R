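# adjusted association of a summed concentration vector with BMI:
# OLS of BMI on {sum, sex, age, ethnicity}; returns the sum coefficient's p
.sum_assoc <- function(sum_vec, meta, Xc = NULL, adjusted = TRUE) {
  if (is.null(Xc)) Xc <- .covariate_design(meta)
  X <- if (adjusted) cbind(s = sum_vec, Xc) else
    cbind(s = sum_vec, `(Intercept)` = 1)
  fit <- .ols(meta$bmi, X)
  list(beta = unname(fit$coef["s"]), p = unname(fit$p["s"]))
}

#' Greedy sum-accumulation of a biomarker panel
#'
#' Builds one direction of the lipid species ratio. The running sum starts at
#' the top-ranked candidate (the reference lipid molecule); each further
#' candidate, taken in rank order, is tentatively added to the sum and the
#' covariate-adjusted regression of BMI on the sum is refitted. The candidate
#' is kept only when the new p-value is strictly smaller than the best p seen
#' so far (a decrease in p = a stronger association); otherwise the sum
#' reverts. Every candidate is visited exactly once.
#'
#' @param candidates Character vector of species names in accumulation order
#'   (strongest individual association first).
#' @param conc Subjects x species concentration matrix in raw umol/L (sums of
#'   concentrations are physical quantities); columns must cover `candidates`.
#' @param meta Metadata data frame (`bmi`, `sex`, `age`, `ethnicity`).
#' @param direction `"positive"` or `"negative"` (recorded in the trace).
#' @param adjusted Adjust the per-step regressions for sex, age and ethnicity
#'   (default TRUE).
#' @return An object of class `greedy_trace`: a data frame with one row per
#'   candidate (`step`, `species`, `neg_log10_p` of the tested sum,
#'   `accepted`, `role`), with attributes `direction`, `accepted_species`,
#'   `final_sum` (per-subject vector) and `final_p`.
#' @export
greedy_accumulate <- function(candidates, conc, meta,
                              direction = c("positive", "negative"),
                              adjusted = TRUE) {
  direction <- match.arg(direction)
  if (length(candidates) == 0L) {
    stop("no candidates to accumulate", call. = FALSE)
  }
  stopifnot(all(candidates %in% colnames(conc)),
            nrow(conc) == nrow(meta))
  Xc <- .covariate_design(meta)

  run_sum <- conc[, candidates[1L]]
  best <- .sum_assoc(run_sum, meta, Xc, adjusted)
  steps <- data.frame(
    step = 1L, species = candidates[1L],
    neg_log10_p = -log10(max(best$p, .Machine$double.xmin)),
    accepted = TRUE, role = "reference", stringsAsFactors = FALSE)
  accepted <- candidates[1L]

  for (i in seq_along(candidates)[-1L]) {
    trial <- run_sum + conc[, candidates[i]]
    a <- .sum_assoc(trial, meta, Xc, adjusted)
    take <- a$p < best$p  # strict improvement; ties reject
    if (take) {
      run_sum <- trial
      best <- a
      accepted <- c(accepted, candidates[i])
    }
    steps <- rbind(steps, data.frame(
      step = i, species = candidates[i],
      neg_log10_p = -log10(max(a$p, .Machine$double.xmin)),
      accepted = take, role = "tested", stringsAsFactors = FALSE))
  }
  structure(steps, class = c("greedy_trace", "data.frame"),
            direction = direction, accepted_species = accepted,
            final_sum = run_sum, final_p = best$p)
}

#' @export
print.greedy_trace <- function(x, ...) {
  cat(sprintf("<greedy_trace> direction %s: %d candidate(s), %d accepted, final -log10(p) = %.3f\n",
              attr(x, "direction"), nrow(x),
              length(attr(x, "accepted_species")),
              -log10(max(attr(x, "final_p"), .Machine$double.xmin))))
  print.data.frame(x, ...)
  invisible(x)
}

#' Lipid species ratio
#'
#' Per-subject ratio of the summed concentrations of the positively
#' BMI-associated panel over the negatively associated panel. Undefined
#' (error) when the denominator is not positive.
#'
#' @param positive_sum,negative_sum Numeric vectors (umol/L), equal length.
#' @return Dimensionless numeric vector.
#' @export
#' @examples
#' compute_lsr(5, 5)   # 1
#' compute_lsr(0, 50)  # 0
compute_lsr <- function(positive_sum, negative_sum) {
  stopifnot(is.numeric(positive_sum), is.numeric(negative_sum),
            length(positive_sum) == length(negative_sum))
  if (any(negative_sum <= 0)) {
    stop("LSR undefined: non-positive denominator sum for subject(s) ",
         paste(which(negative_sum <= 0), collapse = ", "), call. = FALSE)
  }
  positive_sum / negative_sum
}

#' Per-subject panel scores
#'
#' Sums the accepted positive and negative panels per subject and forms the
#' ratio; subjects with a non-positive denominator are dropped with a warning.
#'
#' @param panel A list with `positive` and `negative` character vectors of
#'   species names (accepted panels).
#' @param conc Subjects x species raw concentration matrix (umol/L).
#' @return Data frame: `subject`, `positive_sum`, `negative_sum`, `lsr`.
#' @export
subject_scores <- function(panel, conc) {
  stopifnot(all(c(panel$positive, panel$negative) %in% colnames(conc)))
  pos <- rowSums(conc[, panel$positive, drop = FALSE])
  neg <- rowSums(conc[, panel$negative, drop = FALSE])
  keep <- neg > 0
  if (!all(keep)) {
    warning(sum(!keep), " subject(s) dropped: non-positive denominator sum")
  }
  data.frame(
    subject = (rownames(conc) %||% as.character(seq_len(nrow(conc))))[keep],
    positive_sum = pos[keep], negative_sum = neg[keep],
    lsr = pos[keep] / neg[keep],
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Covariate-adjusted association of the LSR with BMI
#'
#' @param lsr Per-subject LSR values.
#' @param meta Metadata rows aligned with `lsr` (`bmi`, `sex`, `age`,
#'   `ethnicity`).
#' @return A list with `beta`, `p`, `neg_log10_p`.
#' @export
lsr_association <- function(lsr, meta) {
  stopifnot(length(lsr) == nrow(meta))
  if (length(lsr) < 10L) stop("need at least 10 subjects", call. = FALSE)
  if (stats::sd(lsr) == 0) stop("zero-variance LSR", call. = FALSE)
  a <- .sum_assoc(lsr, meta)
  list(beta = a$beta, p = a$p,
       neg_log10_p = -log10(max(a$p, .Machine$double.xmin)))
}

#' Youden-optimal ROC cut-off
#'
#' Evaluates Youden's J = sensitivity + specificity - 1 at every candidate
#' threshold (midpoints between consecutive distinct sorted values, plus the
#' two infinities) and both positivity directions, and returns the maximizing
#' cut-off. When thresholds tie on J, the one with the higher specificity (the
#' more conservative positive call) is returned.
#'
#' @param values Numeric vector of the marker (raw scale).
#' @param labels Factor or character with exactly two classes; `positive_class`
#'   marks the condition being detected (sensitivity refers to it).
#' @param positive_class The label counted as condition-positive (default
#'   `"obese"`).
#' @return An object of class `cutoff_result`: `cutoff`, `sensitivity` and
#'   `specificity` (percent), `youden_j`, `direction` (`">="` when values at
#'   or above the cut-off are called positive, `"<"` otherwise), `n_positive`,
#'   `n_negative`.
#' @export
roc_youden_cutoff <- function(values, labels, positive_class = "obese") {
  stopifnot(is.numeric(values), length(values) == length(labels))
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2L || !positive_class %in% classes) {
    stop("labels must contain exactly two classes incl. the positive class",
         call. = FALSE)
  }
  is_pos <- labels == positive_class
  np <- sum(is_pos); nn <- sum(!is_pos)
  svals <- sort(unique(values))
  cand <- c(-Inf, (svals[-1] + svals[-length(svals)]) / 2, Inf)
  best <- NULL
  for (thr in cand) {
    for (dir in c(">=", "<")) {
      called <- if (dir == ">=") values >= thr else values < thr
      sens <- sum(called & is_pos) / np
      spec <- sum(!called & !is_pos) / nn
      j <- sens + spec - 1
      if (is.null(best) || j > best$youden_j + 1e-12 ||
          (abs(j - best$youden_j) <= 1e-12 && spec > best$specificity / 100)) {
        best <- list(cutoff = thr, sensitivity = 100 * sens,
                     specificity = 100 * spec, youden_j = j, direction = dir)
      }
    }
  }
  best$n_positive <- np
  best$n_negative <- nn
  structure(best, class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf(
    "<cutoff_result> positive when value %s %.4g; sensitivity %.1f%%, specificity %.1f%%, J = %.3f\n",
    x$direction, x$cutoff, x$sensitivity, x$specificity, x$youden_j))
  invisible(x)
}

#' Reference-value report for the panel sums and LSR
#'
#' For each of the three markers (positive-panel sum, negative-panel sum,
#' LSR), contrasts normal-weight against obese subjects (overweight excluded):
#' Youden-optimal cut-off with its positivity direction, per-category mean and
#' SD, and the Mann-Whitney group-difference p-value.
#'
#' @param scores Data frame from [subject_scores()].
#' @param meta Metadata aligned with the *original* cohort rows; matched to
#'   `scores` by `subject_id`.
#' @return Data frame, one row per marker.
#' @export
reference_value_report <- function(scores, meta) {
  stopifnot(all(c("positive_sum", "negative_sum", "lsr") %in% names(scores)))
  m <- meta[match(scores$subject, as.character(meta$subject_id)), , drop = FALSE]
  cat3 <- bmi_category(m$bmi)
  keep <- cat3 != "overweight"
  rows <- lapply(c("positive_sum", "negative_sum", "lsr"), function(v) {
    x <- scores[[v]][keep]
    g <- droplevels(cat3[keep])
    co <- roc_youden_cutoff(x, as.character(g), positive_class = "obese")
    mw <- mann_whitney(x[g == "normal"], x[g == "obese"])
    data.frame(
      variable = v,
      cutoff = co$cutoff,
      direction = co$direction,
      sensitivity = co$sensitivity,
      specificity = co$specificity,
      youden_j = co$youden_j,
      mean_normal = mean(x[g == "normal"]),
      sd_normal = stats::sd(x[g == "normal"]),
      mean_obese = mean(x[g == "obese"]),
      sd_obese = stats::sd(x[g == "obese"]),
      p_mann_whitney = mw$p,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
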