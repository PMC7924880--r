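# fast OLS on a fixed design; returns coefficients, two-sided t-test p-values
# and sigma, via the QR decomposition (no formula/model-frame overhead)
.ols <- function(y, X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    stop("design matrix is rank-deficient (collinear predictors)",
         call. = FALSE)
  }
  fit <- qr.coef(qr_x, y)
  res <- y - X %*% fit
  df <- length(y) - ncol(X)
  if (df <= 0) stop("no residual degrees of freedom", call. = FALSE)
  s2 <- sum(res^2) / df
  R <- qr.R(qr_x)
  XtXinv <- chol2inv(R)
  se <- sqrt(diag(XtXinv) * s2)
  tval <- fit / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  list(coef = fit, se = se, t = tval, p = p, df = df,
       sigma = sqrt(s2), residuals = as.numeric(res))
}

# covariate design used throughout: intercept + sex + age + ethnicity
.covariate_design <- function(meta) {
  stopifnot(all(c("sex", "age", "ethnicity") %in% names(meta)))
  cbind(`(Intercept)` = 1,
        sex = as.numeric(factor(meta$sex)) - 1,
        age = meta$age,
        ethnicity = as.numeric(factor(meta$ethnicity)) - 1)
}

#' Varimax rotation of a loading matrix
#'
#' Orthogonal rotation maximizing the varimax simple-structure criterion (the
#' sum over factors of the variance of squared loadings) on Kaiser-normalized
#' loadings, by Kaiser's iterative pairwise planar rotations with the
#' closed-form optimal angle per factor pair. Sweeps continue until the
#' criterion improves by less than `eps` or `max_sweeps` is reached. A single
#' factor is returned unchanged.
#'
#' @param loadings Numeric matrix, variables x k.
#' @param eps Convergence tolerance on the criterion change (default 1e-6).
#' @param max_sweeps Sweep limit (default 1000).
#' @return A list with `loadings` (rotated) and `rotmat` (the orthogonal
#'   rotation applied).
#' @export
varimax_rotate <- function(loadings, eps = 1e-6, max_sweeps = 1000L) {
  L <- as.matrix(loadings)
  k <- ncol(L)
  if (k < 1L) stop("need at least one factor", call. = FALSE)
  if (k == 1L) {
    return(list(loadings = L, rotmat = matrix(1, 1, 1)))
  }
  n <- nrow(L)
  h <- sqrt(rowSums(L^2))
  h[h == 0] <- 1
  Z <- L / h  # Kaiser normalization; undone on exit
  rotmat <- diag(k)
  crit_old <- varimax_criterion(Z, normalize = FALSE)
  for (sweep in seq_len(max_sweeps)) {
    for (j in seq_len(k - 1L)) {
      for (l in seq.int(j + 1L, k)) {
        x <- Z[, j]; y <- Z[, l]
        u <- x^2 - y^2
        v <- 2 * x * y
        A <- sum(u); B <- sum(v)
        num <- sum(2 * u * v) - 2 * A * B / n
        den <- sum(u^2 - v^2) - (A^2 - B^2) / n
        phi <- atan2(num, den) / 4
        if (abs(phi) > 1e-14) {
          cphi <- cos(phi); sphi <- sin(phi)
          Z[, j] <- cphi * x + sphi * y
          Z[, l] <- -sphi * x + cphi * y
          rj <- rotmat[, j]; rl <- rotmat[, l]
          rotmat[, j] <- cphi * rj + sphi * rl
          rotmat[, l] <- -sphi * rj + cphi * rl
        }
      }
    }
    crit_new <- varimax_criterion(Z, normalize = FALSE)
    if (crit_new - crit_old < eps) break
    crit_old <- crit_new
  }
  list(loadings = (Z * h), rotmat = rotmat)
}

#' Varimax simple-structure criterion
#'
#' The quantity [varimax_rotate()] maximizes: with optional Kaiser row
#' normalization, the sum over factors of `n * sum(L^4) - (sum(L^2))^2` (a
#' positive affine transform of the per-factor variance of squared loadings).
#'
#' @param loadings Variables x k loading matrix.
#' @param normalize Kaiser-normalize rows first (default TRUE, matching the
#'   rotation).
#' @return The criterion value.
#' @export
varimax_criterion <- function(loadings, normalize = TRUE) {
  L <- as.matrix(loadings)
  if (normalize) {
    h <- sqrt(rowSums(L^2))
    h[h == 0] <- 1
    L <- L / h
  }
  n <- nrow(L)
  sum(apply(L^2, 2, function(col) n * sum(col^2) - sum(col)^2)) / n^2
}

#' Exploratory principal component clustering of lipid species
#'
#' Eigen-decomposes the species correlation matrix, retains components with
#' eigenvalue at or above `eigenvalue_threshold` (default 2.0), varimax-rotates
#' the retained loadings, and computes subject scores by the regression
#' (Thurstone) method with a pseudo-inverse, which stays well-defined when the
#' correlation matrix is rank-deficient (species outnumbering subjects). Each
#' rotated factor is sign-flipped so its largest-magnitude loading is
#' positive, removing rotation sign indeterminacy.
#'
#' @param conc_normalized Subjects x species numeric matrix (normalized
#'   concentrations); at least 3 subjects, no constant column.
#' @param eigenvalue_threshold Retention threshold on correlation-matrix
#'   eigenvalues (default 2.0).
#' @return An object of class `epca_model`: `eigenvalues` (descending, all),
#'   `retained_k`, `loadings` (species x k, varimax-rotated),
#'   `unrotated_loadings`, `scores` (subjects x k), `variance_explained`
#'   (fraction of total variance carried by retained components), `threshold`.
#' @export
epca_fit <- function(conc_normalized, eigenvalue_threshold = 2.0) {
  X <- as.matrix(conc_normalized)
  n <- nrow(X); p <- ncol(X)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(X)[sds == 0] %||% which(sds == 0)
    stop("constant species column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  Z <- scale(X)
  # eigen-decomposition via SVD of the standardized data: cheaper than a
  # p x p eigendecomposition when species far outnumber subjects, and the
  # correlation matrix is rank-deficient there anyway
  sv <- svd(Z, nu = 0)
  ev_pos <- sv$d^2 / (n - 1)
  eigenvalues <- c(ev_pos, rep(0, max(0L, p - length(ev_pos))))
  retained <- which(eigenvalues >= eigenvalue_threshold)
  k <- length(retained)

  if (k == 0L) {
    model <- list(eigenvalues = eigenvalues, retained_k = 0L,
                  loadings = NULL, unrotated_loadings = NULL, scores = NULL,
                  variance_explained = 0,
                  threshold = eigenvalue_threshold, species = colnames(X))
    return(structure(model, class = "epca_model"))
  }

  V <- sv$v[, retained, drop = FALSE]
  L <- V %*% diag(sqrt(eigenvalues[retained]), k, k)
  rot <- varimax_rotate(L)
  Lr <- rot$loadings
  # deterministic sign convention per factor
  for (j in seq_len(k)) {
    i_max <- which.max(abs(Lr[, j]))
    if (Lr[i_max, j] < 0) Lr[, j] <- -Lr[, j]
  }
  dimnames(Lr) <- list(colnames(X), paste0("cluster", seq_len(k)))

  # Thurstone regression scores: S = Z R^+ L, with R^+ from the truncated SVD
  inv_ev <- ifelse(ev_pos > 1e-8, 1 / ev_pos, 0)
  Rpinv_L <- sv$v %*% (crossprod(sv$v, Lr) * inv_ev)
  scores <- Z %*% Rpinv_L
  dimnames(scores) <- list(rownames(X), colnames(Lr))

  structure(list(
    eigenvalues = eigenvalues,
    retained_k = k,
    loadings = Lr,
    unrotated_loadings = `dimnames<-`(L, dimnames(Lr)),
    scores = scores,
    variance_explained = sum(eigenvalues[retained]) / p,
    threshold = eigenvalue_threshold,
    species = colnames(X)
  ), class = "epca_model")
}

#' @export
print.epca_model <- function(x, ...) {
  cat(sprintf(
    "<epca_model> %d species, %d retained cluster(s) (eigenvalue >= %.2g), %.2f%% variance\n",
    length(x$eigenvalues), x$retained_k, x$threshold,
    100 * x$variance_explained))
  invisible(x)
}

#' Covariate-adjusted association of cluster scores with BMI
#'
#' For each retained cluster, fits ordinary least squares of BMI on the
#' cluster's factor score plus sex, age and ethnicity, and reports the score
#' coefficient, its two-sided p-value and the direction of association.
#'
#' @param scores Subjects x clusters score matrix (from [epca_fit()]).
#' @param meta Metadata data frame aligned with the score rows (`bmi`, `sex`,
#'   `age`, `ethnicity`).
#' @param alpha Significance flag level (default 0.05).
#' @return Data frame: `cluster`, `beta`, `p`, `direction`, `significant`.
#' @export
cluster_bmi_association <- function(scores, meta, alpha = 0.05) {
  stopifnot(nrow(scores) == nrow(meta), "bmi" %in% names(meta))
  Xc <- .covariate_design(meta)
  rows <- lapply(seq_len(ncol(scores)), function(j) {
    fit <- .ols(meta$bmi, cbind(score = scores[, j], Xc))
    data.frame(cluster = colnames(scores)[j] %||% j,
               beta = unname(fit$coef["score"]),
               p = unname(fit$p["score"]),
               direction = if (fit$coef["score"] >= 0) "positive" else
                 "negative",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p < alpha
  out
}

#' Assign species to clusters by their rotated loadings
#'
#' A species is assigned to a cluster when its absolute loading there exceeds
#' `loading_threshold` and does not exceed the threshold on any other retained
#' cluster; otherwise it is excluded with a reason (`low_loading` when no
#' loading qualifies, `multi_cluster` when more than one does). Boundary
#' loadings equal to the threshold do not qualify (strictly greater).
#'
#' @param model An `epca_model`.
#' @param loading_threshold Absolute-loading threshold (default 0.5).
#' @return Data frame: `species`, `cluster` (NA when excluded), `loading`,
#'   `excluded_reason` (NA when assigned).
#' @export
assign_species <- function(model, loading_threshold = 0.5) {
  stopifnot(inherits(model, "epca_model"))
  if (model$retained_k == 0L) {
    return(data.frame(species = model$species, cluster = NA_character_,
                      loading = NA_real_,
                      excluded_reason = "low_loading",
                      stringsAsFactors = FALSE))
  }
  L <- model$loadings
  rows <- lapply(seq_len(nrow(L)), function(i) {
    hits <- which(abs(L[i, ]) > loading_threshold)
    if (length(hits) == 1L) {
      data.frame(species = rownames(L)[i], cluster = colnames(L)[hits],
                 loading = L[i, hits], excluded_reason = NA_character_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(species = rownames(L)[i], cluster = NA_character_,
                 loading = L[i, which.max(abs(L[i, ]))],
                 excluded_reason = if (length(hits) == 0L) "low_loading" else
                   "multi_cluster",
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
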