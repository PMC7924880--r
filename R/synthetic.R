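# truncated-normal draws by rejection (bounds are never in the far tail here)
.rtnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

# deterministic species-name catalogue matching the default class composition;
# the seven default planted panel species are guaranteed members
.species_catalogue <- function(composition) {
  mk <- function(class, chains) paste(class, chains)
  pool <- list()
  pool$Cer <- mk("Cer", paste0("18:1;O2/", c(16, 18, 20, 22, 24, 26), ":0"))
  g <- expand.grid(c = c(14, 16, 18, 20, 22), d = 0:3)
  pool$CE <- mk("CE", paste0(g$c, ":", g$d))
  g <- expand.grid(a = c(16, 18), b = 0:2, c = c(18, 20), d = 0:2)
  pool$DG <- mk("DG", paste0(g$a, ":", g$b, "_", g$c, ":", g$d))
  pool$FA <- mk("FA", c("14:0", "16:0", "16:1", "18:0", "18:1", "18:2",
                        "20:4", "22:6"))
  pool$HexCer <- c("Hex-Cer 18:1;O2/22:0", "Hex-Cer 18:1;O2/24:0")
  pool$LPC <- mk("LPC", c("14:0", "16:0", "16:1", "18:0", "18:1", "18:2",
                          "18:3", "20:3", "20:4"))
  pool$LPE <- mk("LPE", c("16:0", "18:0", "18:1", "18:2", "20:4"))
  g <- expand.grid(a = c(14, 15, 16, 17, 18), b = 0:2,
                   c = c(18, 20, 22), d = 0:3)
  pool$PC <- unique(c("PC 18:1_18:1",
                      mk("PC", paste0(g$a, ":", g$b, "_", g$c, ":", g$d))))
  g <- expand.grid(a = c(16, 18), b = 0:2, c = c(18, 20, 22), d = 0:4)
  pool$PE <- unique(c("PE P-16:0/20:3", "PE P-18:0/20:4",
                      mk("PE", paste0(g$a, ":", g$b, "_", g$c, ":", g$d))))
  pool$SM <- mk("SM", paste0("18:1;O2/", c(16, 18, 20, 24), ":0"))
  g <- expand.grid(a = c(14, 15, 16, 17, 18, 20, 22), b = 0:6,
                   c = 28:40, d = 0:7)
  g <- g[g$b <= g$a - 12 + 4 & g$d <= 7, ]  # keep chemically plausible
  tg <- unique(c("TG 20:4_33:1", "TG 22:6_36:4", "TG 18:3_33:0",
                 mk("TG", paste0(g$a, ":", g$b, "_", g$c, ":", g$d))))
  pool$TG <- tg
  out <- unlist(lapply(names(composition), function(cl) {
    need <- composition[[cl]]
    have <- pool[[cl]]
    if (length(have) < need) {
      stop(sprintf("species pool for class %s has only %d names (need %d)",
                   cl, length(have), need), call. = FALSE)
    }
    have[seq_len(need)]
  }), use.names = FALSE)
  stopifnot(!anyDuplicated(out))
  out
}

#' Configuration of the synthetic lipidomics cohort
#'
#' Defaults emulate the structure the analysis assumes: 136 subjects in three
#' BMI categories (57 normal / 31 overweight / 48 obese), 550 species in 11
#' lipid classes (5 Cer, 14 CE, 12 DG, 8 FA, 2 HexCer, 9 LPC, 4 LPE, 40 PC,
#' 28 PE, 4 SM, 424 TG) whose log-concentrations follow a latent-factor model
#' with 10 clusters (loading 0.8, residual log-SD 0.4, hence right-skewed
#' log-normal concentrations), and a planted panel of 4 positively and 3
#' negatively BMI-associated species at standardized effect 0.4 on the log
#' scale. Class-level location parameters put class totals near typical adult
#' plasma levels (e.g. TG totals in the low thousands of umol/L).
#'
#' @param n_subjects Cohort size (ignored when `category_mode = "fixed"`,
#'   where the category counts decide it).
#' @param class_composition Named integer vector of species counts per class.
#' @param n_latent_clusters Number of latent factors.
#' @param loading_strength Factor loading on the log scale.
#' @param noise_sd Residual log-SD.
#' @param planted_positive,planted_negative Named numeric vectors: species
#'   name -> standardized effect size (positive numbers; the sign of the
#'   association is set by which argument the species appears in).
#' @param cluster_bmi_effect Optional BMI effect carried by the latent factors
#'   of clusters containing planted species (default 0: only the planted
#'   species carry signal).
#' @param bmi_category_counts Named counts for fixed-count sampling.
#' @param category_mode `"fixed"` (default, exact counts) or `"probabilistic"`.
#' @param female_prop,hg_prop Sex and ethnicity proportions.
#' @param batch_size Subjects per measurement batch.
#' @param qc_fail_rate Fraction of batches whose QC deviates beyond 20
#'   percent.
#' @param n_qc_species Number of species monitored in the QC sample.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(
    n_subjects = 136L,
    class_composition = c(Cer = 5L, CE = 14L, DG = 12L, FA = 8L, HexCer = 2L,
                          LPC = 9L, LPE = 4L, PC = 40L, PE = 28L, SM = 4L,
                          TG = 424L),
    n_latent_clusters = 10L,
    loading_strength = 0.8,
    noise_sd = 0.4,
    planted_positive = c("TG 20:4_33:1" = 0.4, "TG 22:6_36:4" = 0.4,
                         "TG 18:3_33:0" = 0.4, "PE P-16:0/20:3" = 0.4),
    planted_negative = c("Hex-Cer 18:1;O2/22:0" = 0.4, "LPC 18:2" = 0.4,
                         "PC 18:1_18:1" = 0.4),
    cluster_bmi_effect = 0,
    bmi_category_counts = c(normal = 57L, overweight = 31L, obese = 48L),
    category_mode = c("fixed", "probabilistic"),
    female_prop = 94 / 136,
    hg_prop = 71 / 136,
    batch_size = 8L,
    qc_fail_rate = 0,
    n_qc_species = 10L) {
  category_mode <- match.arg(category_mode)
  species <- .species_catalogue(class_composition)
  planted <- c(names(planted_positive), names(planted_negative))
  if (anyDuplicated(planted)) {
    stop("planted positive and negative sets must be disjoint", call. = FALSE)
  }
  missing_sp <- setdiff(planted, species)
  if (length(missing_sp) > 0L) {
    stop("planted species not in the catalogue: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(c(planted_positive, planted_negative)))) {
    stop("effect sizes must be finite", call. = FALSE)
  }
  if (category_mode == "fixed") n_subjects <- sum(bmi_category_counts)
  structure(list(
    n_subjects = as.integer(n_subjects),
    class_composition = class_composition,
    species = species,
    n_latent_clusters = as.integer(n_latent_clusters),
    loading_strength = loading_strength,
    noise_sd = noise_sd,
    planted_positive = planted_positive,
    planted_negative = planted_negative,
    cluster_bmi_effect = cluster_bmi_effect,
    bmi_category_counts = bmi_category_counts,
    category_mode = category_mode,
    female_prop = female_prop,
    hg_prop = hg_prop,
    batch_size = as.integer(batch_size),
    qc_fail_rate = qc_fail_rate,
    n_qc_species = as.integer(n_qc_species)
  ), class = "synthetic_config")
}

# class-total targets (umol/L) used to place per-species log-means
.class_total_targets <- c(Cer = 7.3, CE = 2070, DG = 21.6, FA = 100,
                          HexCer = 1.7, LPC = 291, LPE = 4.5, PC = 1504,
                          PE = 62, SM = 77, TG = 2757)

#' Generate a synthetic lipidomics cohort
#'
#' Draws subjects (age truncated-normal 45 +/- 11 on 20-64 years, sex and
#' ethnicity by configured proportions, BMI per category), then species
#' log-concentrations from the latent-factor model
#' `log C_s = mu_s + lambda F_k + gamma_s z(BMI) + sigma eps`, exponentiated
#' to right-skewed concentrations, plus measurement batches of `batch_size`
#' subjects with QC/blank records (a configurable fraction of batches carries
#' a QC deviation beyond 20 percent). Fully reproducible from `seed`.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return A list with `meta` (subject data frame), `conc` (subjects x species
#'   matrix, umol/L), `batches` (list of [batch_record()]), and `truth`
#'   (planted species, effects, and latent cluster membership).
#' @export
generate_cohort <- function(config = synthetic_config(), seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  n <- config$n_subjects
  species <- config$species
  p <- length(species)

  cats <- names(config$bmi_category_counts)
  category <- if (config$category_mode == "fixed") {
    sample(rep(cats, config$bmi_category_counts))
  } else {
    sample(cats, n, replace = TRUE,
           prob = config$bmi_category_counts / sum(config$bmi_category_counts))
  }
  bmi <- numeric(n)
  bmi[category == "normal"] <- .rtnorm(sum(category == "normal"),
                                       22.5, 2.0, 18.5, 24.99)
  bmi[category == "overweight"] <- .rtnorm(sum(category == "overweight"),
                                           27.3, 1.4, 25.0, 29.9)
  bmi[category == "obese"] <- .rtnorm(sum(category == "obese"),
                                      33.5, 3.0, 30.0, 45.0)
  meta <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    age = .rtnorm(n, 45.02, 11.03, 20, 64),
    sex = sample(c("female", "male"), n, replace = TRUE,
                 prob = c(config$female_prop, 1 - config$female_prop)),
    ethnicity = sample(c("HG", "HR"), n, replace = TRUE,
                       prob = c(config$hg_prop, 1 - config$hg_prop)),
    bmi = bmi,
    stringsAsFactors = FALSE)
  meta$bmi_category <- bmi_category(meta$bmi)

  # contiguous cluster blocks over the class-ordered species list: species of
  # a class share clusters, the dominant class (TG) spans several
  K <- config$n_latent_clusters
  cluster_of <- as.integer(cut(seq_len(p), breaks = K, labels = FALSE))
  names(cluster_of) <- species
  # planted species live in distinct clusters (positives and negatives in
  # disjoint sets), mirroring a panel drawn from several co-regulation
  # clusters rather than one
  planted_all <- c(names(config$planted_positive),
                   names(config$planted_negative))
  if (length(planted_all) > K) {
    stop("need at least as many latent clusters as planted species",
         call. = FALSE)
  }
  cluster_of[planted_all] <- seq_along(planted_all)

  gamma <- numeric(p)
  names(gamma) <- species
  gamma[names(config$planted_positive)] <- config$planted_positive
  gamma[names(config$planted_negative)] <- -config$planted_negative

  total_var <- config$loading_strength^2 + config$noise_sd^2
  cls <- vapply(species, class_of, character(1))
  mu <- log(.class_total_targets[cls] / as.numeric(table(cls)[cls])) -
    total_var / 2
  mu <- mu + stats::runif(p, -0.3, 0.3)
  # panel species share a per-direction location scale so each contributes
  # comparably to its panel sum (positive panel ~0.5 umol/L per species as for
  # minor TG species, negative panel ~25 umol/L as for abundant phospholipids)
  mu[match(names(config$planted_positive), species)] <-
    log(0.5) - total_var / 2
  mu[match(names(config$planted_negative), species)] <-
    log(25) - total_var / 2

  z_bmi <- as.numeric(scale(meta$bmi))
  Fmat <- matrix(stats::rnorm(n * K), n, K)
  if (config$cluster_bmi_effect != 0) {
    # clusters hosting planted species inherit a factor-level BMI effect with
    # the sign of their planted species' association
    for (sp in names(config$planted_positive)) {
      k <- cluster_of[sp]
      Fmat[, k] <- Fmat[, k] + config$cluster_bmi_effect * z_bmi
    }
    for (sp in names(config$planted_negative)) {
      k <- cluster_of[sp]
      Fmat[, k] <- Fmat[, k] - config$cluster_bmi_effect * z_bmi
    }
  }
  eps <- matrix(stats::rnorm(n * p), n, p)
  logC <- matrix(mu, n, p, byrow = TRUE) +
    config$loading_strength * Fmat[, cluster_of] +
    outer(z_bmi, gamma) +
    config$noise_sd * eps
  conc <- exp(logC)
  dimnames(conc) <- list(meta$subject_id, species)

  # batches with QC / blank structure
  n_batches <- ceiling(n / config$batch_size)
  batch_idx <- rep(seq_len(n_batches), each = config$batch_size)[seq_len(n)]
  qc_sp <- species[seq_len(min(config$n_qc_species, p))]
  nominal <- exp(mu[match(qc_sp, species)] + total_var / 2)
  names(nominal) <- qc_sp
  fail <- stats::runif(n_batches) < config$qc_fail_rate
  batches <- lapply(seq_len(n_batches), function(b) {
    dev <- stats::runif(length(qc_sp), -0.1, 0.1)
    if (fail[b]) {
      j <- sample(length(qc_sp), 1L)
      dev[j] <- sample(c(-1, 1), 1L) * stats::runif(1L, 0.25, 0.5)
    }
    batch_record(
      batch_id = sprintf("B%02d", b),
      subject_ids = meta$subject_id[batch_idx == b],
      qc_measured = nominal * (1 + dev),
      qc_nominal = nominal,
      blank = nominal * 0.01)
  })

  truth <- list(
    planted_positive = names(config$planted_positive),
    planted_negative = names(config$planted_negative),
    effects = gamma[gamma != 0],
    cluster_of = cluster_of,
    seed = seed)
  list(meta = meta, conc = conc, batches = batches, truth = truth)
}

#' Generate a null cohort (no BMI effects)
#'
#' Same generative model as [generate_cohort()] with every BMI effect set to
#' zero; used for type-I-error and false-discovery characterization.
#'
#' @inheritParams generate_cohort
#' @return As [generate_cohort()]; `truth` records empty planted sets.
#' @export
generate_null_cohort <- function(config = synthetic_config(), seed = 1L) {
  config$planted_positive <- stats::setNames(numeric(0), character(0))
  config$planted_negative <- stats::setNames(numeric(0), character(0))
  config$cluster_bmi_effect <- 0
  generate_cohort(config, seed = seed)
}
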