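#' Convert concentrations from nmol/g plasma to umol/L
#'
#' Under the convention that 1 g of plasma occupies 1 mL, 1 nmol/g equals
#' 1 umol/L, so the conversion is numerically the identity; the function exists
#' to make the unit change explicit and to reject physically impossible input.
#'
#' @param value Numeric vector of concentrations in nmol/g plasma.
#' @return The same values in umol/L.
#' @export
convert_units <- function(value) {
  stopifnot(is.numeric(value))
  if (any(value < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  value
}

#' Blank-correct sample concentrations
#'
#' Subtracts the reagent-blank signal from sample concentrations, flooring at
#' zero (a corrected concentration is a physical quantity and cannot be
#' negative).
#'
#' @param sample_conc Numeric, sample concentrations (umol/L).
#' @param blank_conc Numeric, blank concentrations (umol/L), recycled.
#' @return `pmax(sample_conc - blank_conc, 0)`.
#' @export
blank_correct <- function(sample_conc, blank_conc) {
  stopifnot(is.numeric(sample_conc), is.numeric(blank_conc))
  if (any(sample_conc < 0, na.rm = TRUE) || any(blank_conc < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  pmax(sample_conc - blank_conc, 0)
}

#' Construct a batch record
#'
#' One measurement batch: its member subjects plus the per-species QC
#' measurement, QC nominal target and blank levels used for batch acceptance
#' and blank correction.
#'
#' @param batch_id Batch identifier.
#' @param subject_ids Character vector of member subject ids.
#' @param qc_measured Named numeric vector, measured QC concentration per
#'   monitored species (umol/L).
#' @param qc_nominal Named numeric vector, nominal QC concentration per
#'   monitored species (umol/L); must be positive and share names with
#'   `qc_measured`.
#' @param blank Optional named numeric vector of blank levels (umol/L).
#' @return A `batch_record` object.
#' @export
batch_record <- function(batch_id, subject_ids, qc_measured, qc_nominal,
                         blank = NULL) {
  stopifnot(length(batch_id) == 1L, length(subject_ids) >= 1L)
  species <- names(qc_nominal)
  if (is.null(species) || is.null(names(qc_measured))) {
    stop("qc_measured and qc_nominal must be named by species", call. = FALSE)
  }
  if (!all(species %in% names(qc_measured))) {
    stop("qc_measured is missing species present in qc_nominal", call. = FALSE)
  }
  if (any(qc_nominal <= 0)) {
    stop("qc_nominal must be positive for monitored species", call. = FALSE)
  }
  structure(list(batch_id = as.character(batch_id),
                 subject_ids = as.character(subject_ids),
                 qc_measured = qc_measured[species],
                 qc_nominal = qc_nominal,
                 blank = blank),
            class = "batch_record")
}

#' QC-based batch exclusion
#'
#' A batch is excluded when its QC sample deviates from the nominal target by
#' strictly more than the tolerance (default +/- 20 percent) for any monitored
#' species (`rule = "any"`); a deviation of exactly the tolerance passes. All
#' subjects of an excluded batch are dropped.
#'
#' @param batches List of [batch_record()] objects.
#' @param tolerance Relative deviation tolerance (default 0.20).
#' @param rule `"any"` (default, a single violating species excludes the
#'   batch) or `"all"` (every monitored species must violate).
#' @return A list with `retained_subjects`, `excluded_batches`, and `report`,
#'   a data frame listing each batch's decision and violating species.
#' @export
qc_batch_filter <- function(batches, tolerance = 0.20, rule = c("any", "all")) {
  rule <- match.arg(rule)
  if (!is.list(batches) || length(batches) == 0L) {
    stop("'batches' must be a non-empty list of batch records", call. = FALSE)
  }
  stopifnot(tolerance > 0)
  rows <- lapply(batches, function(b) {
    stopifnot(inherits(b, "batch_record"))
    dev <- abs(b$qc_measured - b$qc_nominal) / b$qc_nominal
    viol <- names(dev)[dev > tolerance]
    excl <- if (rule == "any") length(viol) > 0L else
      length(viol) == length(dev)
    data.frame(batch_id = b$batch_id,
               n_subjects = length(b$subject_ids),
               excluded = excl,
               max_deviation = max(dev),
               violating_species = paste(viol, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  excl_ids <- report$batch_id[report$excluded]
  retained <- unlist(lapply(batches, function(b) {
    if (b$batch_id %in% excl_ids) character(0) else b$subject_ids
  }), use.names = FALSE)
  list(retained_subjects = retained,
       excluded_batches = excl_ids,
       report = report)
}

#' Shapiro-Wilk normality gate
#'
#' Flags a variable as non-normal when the Shapiro-Wilk test rejects at
#' `alpha`; such variables are candidates for the two-step normalization.
#'
#' @param values Numeric vector, n between 3 and 5000, non-constant.
#' @param alpha Significance level of the gate (default 0.05).
#' @return A list with `status` (`"normal"` or `"non_normal"`), `p`, and `W`.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  stopifnot(is.numeric(values))
  values <- values[is.finite(values)]
  if (length(values) < 3L) stop("need at least 3 finite values", call. = FALSE)
  if (diff(range(values)) == 0) {
    stop("constant vector: normality is undefined", call. = FALSE)
  }
  sw <- stats::shapiro.test(values)
  list(status = if (sw$p.value < alpha) "non_normal" else "normal",
       p = unname(sw$p.value), W = unname(sw$statistic))
}

#' Two-step rank-based normalization
#'
#' Step 1 maps values to fractional ranks in (0, 1); step 2 applies the inverse
#' standard-normal quantile and rescales the result to the original sample
#' mean and standard deviation. Ties receive mean ranks, so the transform
#' preserves the input's weak ordering. The fractional-rank formula defaults to
#' Blom's (r - 3/8)/(n + 1/4), which keeps every rank strictly inside (0, 1).
#'
#' @param values Numeric vector, length >= 3, non-constant.
#' @param ranks Fractional-rank formula, `"blom"` (default) or `"vanderwaerden"`
#'   (r/(n+1)).
#' @return Numeric vector of the same length, with the sample mean and SD of
#'   the input (exactly, up to floating point, when standardization of the
#'   normal scores is well-defined).
#' @export
#' @examples
#' x <- rexp(200)
#' y <- templeton_two_step(x)
#' c(mean(x) - mean(y), sd(x) - sd(y))   # ~ 0, 0
templeton_two_step <- function(values, ranks = c("blom", "vanderwaerden")) {
  ranks <- match.arg(ranks)
  stopifnot(is.numeric(values))
  if (length(values) < 3L) stop("need at least 3 values", call. = FALSE)
  if (anyNA(values)) stop("missing values not supported", call. = FALSE)
  if (diff(range(values)) == 0) {
    stop("constant input cannot be normalized", call. = FALSE)
  }
  n <- length(values)
  r <- rank(values, ties.method = "average")
  frac <- switch(ranks,
                 blom = (r - 3 / 8) / (n + 1 / 4),
                 vanderwaerden = r / (n + 1))
  z <- stats::qnorm(frac)
  # standardize the normal scores before rescaling so the output reproduces
  # the input's sample mean and SD exactly in the tie-free case
  z <- (z - mean(z)) / stats::sd(z)
  z * stats::sd(values) + mean(values)
}

#' Normalize a concentration matrix variable-by-variable
#'
#' Applies [templeton_two_step()] to each species column that fails the
#' Shapiro-Wilk gate (default), or to all columns.
#'
#' @param conc Numeric matrix, subjects x species.
#' @param gate `"shapiro"` (default: transform only columns with Shapiro-Wilk
#'   p < `alpha`) or `"all"`.
#' @param alpha Gate significance level.
#' @param ranks Passed to [templeton_two_step()].
#' @return A list with `conc` (transformed matrix) and `transformed` (logical
#'   vector per column).
#' @export
normalize_cohort <- function(conc, gate = c("shapiro", "all"), alpha = 0.05,
                             ranks = "blom") {
  gate <- match.arg(gate)
  stopifnot(is.matrix(conc), is.numeric(conc))
  out <- conc
  transformed <- logical(ncol(conc))
  for (j in seq_len(ncol(conc))) {
    x <- conc[, j]
    if (diff(range(x)) == 0) {
      stop(sprintf("species column %s is constant",
                   colnames(conc)[j] %||% j), call. = FALSE)
    }
    do_it <- gate == "all" ||
      normality_gate(x, alpha = alpha)$status == "non_normal"
    if (do_it) {
      out[, j] <- templeton_two_step(x, ranks = ranks)
      transformed[j] <- TRUE
    }
  }
  names(transformed) <- colnames(conc)
  list(conc = out, transformed = transformed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' BMI category from BMI
#'
#' Standard adult categories: normal < 25, overweight 25-29.9, obese >= 30
#' kg/m^2.
#'
#' @param bmi Numeric vector of BMI values (kg/m^2).
#' @return Ordered factor with levels normal < overweight < obese.
#' @export
bmi_category <- function(bmi) {
  stopifnot(is.numeric(bmi), all(bmi > 0))
  cut(bmi, breaks = c(0, 25, 30, Inf), right = FALSE,
      labels = c("normal", "overweight", "obese"), ordered_result = TRUE)
}

#' Read a cohort concentration table
#'
#' Reads a wide CSV/TSV with metadata columns (`subject_id`, `age`, `sex`,
#' `ethnicity`, `bmi`) followed by one column per lipid species, validates the
#' species headers, and returns the cohort container used throughout the
#' pipeline.
#'
#' @param path File path (delimiter inferred from extension, `.tsv` = tab).
#' @param units `"umol_l"` (default) or `"nmol_g"` (converted on read).
#' @return A list with `meta` (data frame incl. `bmi_category`), `conc`
#'   (numeric matrix subjects x species) and `species` (validation table).
#' @export
read_cohort_table <- function(path, units = c("umol_l", "nmol_g")) {
  units <- match.arg(units)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("subject_id", "age", "sex", "ethnicity", "bmi")
  if (!all(meta_cols %in% names(df))) {
    stop("missing metadata columns: ",
         paste(setdiff(meta_cols, names(df)), collapse = ", "), call. = FALSE)
  }
  if (anyNA(df[meta_cols])) {
    stop("subjects with missing metadata are not allowed", call. = FALSE)
  }
  sp_cols <- setdiff(names(df), meta_cols)
  val <- validate_species_names(sp_cols)
  if (any(!val$ok)) {
    stop("unparseable species headers: ",
         paste(val$name[!val$ok], collapse = ", "), call. = FALSE)
  }
  conc <- as.matrix(df[sp_cols])
  rownames(conc) <- df$subject_id
  conc <- convert_units(conc)
  meta <- df[meta_cols]
  meta$bmi_category <- bmi_category(meta$bmi)
  list(meta = meta, conc = conc, species = val)
}
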