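test_that("block-correlated variables yield block eigenvalues and full recovery", {
  set.seed(70)
  n <- 40
  f1 <- rnorm(n)
  f2 <- residuals(lm(rnorm(n) ~ f1))  # sample-orthogonal second factor
  X <- cbind(matrix(f1, n, 5), matrix(f2, n, 5)) +
    matrix(rnorm(n * 10, sd = 1e-4), n, 10)  # two near-perfect blocks of 5
  colnames(X) <- paste0("v", 1:10)
  m <- epca_fit(X)
  expect_equal(m$retained_k, 2L)
  expect_equal(sort(m$eigenvalues, decreasing = TRUE)[1:2], c(5, 5),
               tolerance = 1e-3)
  expect_equal(m$variance_explained, 1, tolerance = 1e-3)
  # eigenvalues of a correlation analysis sum to the variable count
  expect_equal(sum(m$eigenvalues), 10, tolerance = 1e-6)
})

test_that("uncorrelated variables retain nothing at the threshold", {
  set.seed(71)
  X <- matrix(rnorm(3000 * 10), 3000, 10)
  colnames(X) <- paste0("v", 1:10)
  m <- epca_fit(X)
  expect_equal(m$retained_k, 0L)
  asg <- assign_species(m)
  expect_true(all(asg$excluded_reason == "low_loading"))
})

test_that("constant columns are rejected by name", {
  X <- cbind(a = rnorm(10), b = rep(1, 10))
  expect_error(epca_fit(X), "constant species column.*b")
})

test_that("varimax preserves communalities and applies an orthogonal rotation", {
  set.seed(72)
  X <- matrix(rnorm(100 * 30), 100, 30) +
    cbind(matrix(rnorm(100), 100, 15), matrix(rnorm(100), 100, 15))
  colnames(X) <- paste0("v", 1:30)
  L <- with(svd(scale(X)), v[, 1:3] %*% diag(d[1:3] / sqrt(99)))
  rot <- varimax_rotate(L)
  expect_equal(rowSums(rot$loadings^2), rowSums(L^2), tolerance = 1e-8)
  expect_equal(crossprod(rot$rotmat), diag(3), tolerance = 1e-10)
  # k = 1 is the identity rotation
  one <- varimax_rotate(L[, 1, drop = FALSE])
  expect_identical(one$loadings, L[, 1, drop = FALSE])
})

test_that("varimax attains the 2-factor grid-search optimum", {
  L <- matrix(c(0.7, 0.7, 0.7, -0.7), 2, 2)
  rot <- varimax_rotate(L)
  # simple structure up to column sign/order
  got <- apply(abs(rot$loadings), 1, max)
  expect_equal(got, c(sqrt(2) * 0.7, sqrt(2) * 0.7), tolerance = 1e-4)
  expect_equal(varimax_criterion(rot$loadings),
               varimax_grid_oracle(L), tolerance = 1e-4)

  set.seed(73)
  for (i in 1:5) {
    Lr <- matrix(rnorm(16), 8, 2)
    rot_i <- varimax_rotate(Lr)
    expect_gte(varimax_criterion(rot_i$loadings) + 1e-4,
               varimax_grid_oracle(Lr))
  }
})

test_that("pairwise varimax agrees with the reference implementation on tall matrices", {
  set.seed(77)
  for (i in 1:5) {
    L <- matrix(rnorm(120 * 4, sd = 0.5), 120, 4)
    mine <- varimax_criterion(varimax_rotate(L)$loadings)
    ref <- varimax_criterion(L %*% stats::varimax(L, normalize = TRUE,
                                                  eps = 1e-8)$rotmat)
    expect_gte(mine + 1e-6, ref)
  }
})

test_that("cluster-BMI association recovers direction and nulls at the level", {
  set.seed(74)
  n <- 200
  meta <- make_meta(n, bmi = runif(n, 20, 40), seed = 74)
  # score that is an exact linear function of BMI and covariates
  s_perfect <- 0.3 * meta$bmi + 0.1 * meta$age
  a <- cluster_bmi_association(cbind(c1 = s_perfect), meta)
  expect_lt(a$p, 1e-12)
  expect_equal(a$direction, "positive")
  a_neg <- cluster_bmi_association(cbind(c1 = -meta$bmi + rnorm(n)), meta)
  expect_equal(a_neg$direction, "negative")
  # null scores reject at about the nominal rate
  rej <- vapply(1:400, function(i) {
    cluster_bmi_association(cbind(c1 = rnorm(n)), meta)$p < 0.05
  }, logical(1))
  half <- 1.96 * sqrt(0.05 * 0.95 / 400)
  expect_gt(mean(rej), 0.05 - half)
  expect_lt(mean(rej), 0.05 + half)
})

test_that("species assignment applies the strict unique-loading rule", {
  m <- structure(list(retained_k = 3L,
                      loadings = matrix(c(0.8, 0.6, 0.5,
                                          0.1, -0.55, 0.1,
                                          0.0, 0.0, 0.1), 3, 3,
                                        dimnames = list(c("a", "b", "c"),
                                                        paste0("cluster", 1:3))),
                      species = c("a", "b", "c")),
                 class = "epca_model")
  asg <- assign_species(m, loading_threshold = 0.5)
  expect_equal(asg$cluster[asg$species == "a"], "cluster1")
  expect_equal(asg$excluded_reason[asg$species == "b"], "multi_cluster")
  # |loading| exactly at the threshold does not qualify
  expect_equal(asg$excluded_reason[asg$species == "c"], "low_loading")
})

test_that("planted cluster structure is recovered on synthetic data", {
  # K clusters of strongly loaded species: retention finds exactly K and the
  # assignment recovers planted memberships
  ok_k <- ok_members <- logical(0)
  for (s in 1:10) {
    set.seed(900 + s)
    n <- 150; K <- 3; per <- 25
    f <- matrix(rnorm(n * K), n, K)
    member <- rep(1:K, each = per)
    X <- 0.8 * f[, member] + 0.6 * matrix(rnorm(n * K * per), n, K * per)
    colnames(X) <- paste0("v", seq_len(ncol(X)))
    m <- epca_fit(X)
    asg <- assign_species(m)
    ok_k <- c(ok_k, m$retained_k == K)
    if (m$retained_k == K) {
      tab <- table(member, asg$cluster[match(colnames(X), asg$species)])
      recovered <- sum(apply(tab, 1, max)) / length(member)
      ok_members <- c(ok_members, recovered >= 0.9)
    } else ok_members <- c(ok_members, FALSE)
  }
  expect_gte(mean(ok_k), 0.9)
  expect_gte(mean(ok_members), 0.9)
})
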