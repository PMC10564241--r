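test_that("constant matrix has the closed-form rank-1 decomposition", {
  s <- 4; g <- 12; cval <- 3
  E <- matrix(cval, s, g, dimnames = list(paste0("s", 1:s), paste0("g", 1:g)))
  d <- decompose_profile(E)
  expect_equal(length(d$lambda), 1L)
  expect_equal(d$lambda[1L], cval * sqrt(s * g), tolerance = 1e-12)
  expect_equal(abs(d$u[, 1L]), rep(1 / sqrt(s), s), tolerance = 1e-12)
})

test_that("decomposition reconstructs and is orthonormal on random matrices", {
  for (seed in 1:3) {
    p <- rand_profile(4, 20, seed = seed)
    d <- decompose_profile(p)
    E_hat <- d$u %*% (d$lambda * t(d$v))
    expect_lt(max(abs(E_hat - p$matrix)) / max(abs(p$matrix)), 1e-8)
    expect_lt(max(abs(crossprod(d$u) - diag(ncol(d$u)))), 1e-8)
    expect_lt(max(abs(crossprod(d$v) - diag(ncol(d$v)))), 1e-8)
    expect_true(all(diff(d$lambda) <= 0))
  }
})

test_that("squared singular values match the eigen oracle on E E^T", {
  p <- rand_profile(3, 5, seed = 11)
  d <- decompose_profile(p)
  ev <- eigen(p$matrix %*% t(p$matrix), symmetric = TRUE)$values
  expect_equal(d$lambda^2, ev[seq_along(d$lambda)], tolerance = 1e-8)
})

test_that("non-finite input and too-few samples are rejected", {
  M <- matrix(1:12, 3, 4, dimnames = list(paste0("s", 1:3), paste0("g", 1:4)))
  M2 <- M; M2[2, 2] <- NA
  expect_error(decompose_profile(M2), "non-finite")
  expect_error(decompose_profile(M[1, , drop = FALSE]), "2 samples")
})

test_that("baseline CV is 0 for a constant matrix and small for shifted baselines", {
  E <- matrix(5, 4, 10, dimnames = list(paste0("s", 1:4), paste0("g", 1:10)))
  expect_equal(baseline_cv(decompose_profile(E))$cv, 0, tolerance = 1e-10)

  # per-sample shifts of sd 0.05 on a baseline mean of 8
  set.seed(42)
  g <- 800; s <- 20
  mat <- outer(rep(1, s), rnorm(g, 8, 0.5)) + outer(rnorm(s, 0, 0.05), rep(1, g))
  dimnames(mat) <- list(paste0("s", 1:s), paste0("gg", 1:g))
  bc <- baseline_cv(decompose_profile(mat))
  expect_lt(bc$cv, 2)
  expect_true(bc$near_constant)
})

test_that("empirical contrast gap vanishes under an exact constant baseline", {
  s <- 6; g <- 30
  u1 <- c(1, 1, 1, -1, -1, -1) / sqrt(6)  # mean-zero contrast
  set.seed(5)
  v1 <- rnorm(g); v1 <- v1 - mean(v1)      # orthogonal to the baseline v
  v1 <- v1 / sqrt(sum(v1^2))
  E <- 7 * outer(rep(1, s), rep(1, g)) + 2 * outer(u1, v1)
  dimnames(E) <- list(paste0("s", 1:s), paste0("g", 1:g))
  d <- decompose_profile(E)
  expect_lt(empirical_contrast_gap(d, 1), 1e-10)
  expect_error(empirical_contrast_gap(d, 0), "baseline")
})

test_that("contrast gap is bounded by sqrt(s) x CV(u0)/100 on simulated data", {
  sim <- simulate_dual_species(small_config(seed = 3))
  d <- decompose_profile(sim$profile_a)
  cv <- baseline_cv(d)$cv
  s <- nrow(sim$profile_a$matrix)
  expect_lte(empirical_contrast_gap(d, 1), sqrt(s) * cv / 100)
})

test_that("polarization follows the reference group and preserves the outer product", {
  E <- outer(c(-.6, -.2, .3, .5), c(1, -1, 2, 0, 1)) +
    outer(rep(2, 4), rep(3, 5))
  dimnames(E) <- list(paste0("s", 1:4), paste0("g", 1:5))
  d <- decompose_profile(E)
  # identify the component whose u matches the planted contrast
  k_con <- 1L
  pc_hi <- polarize(d, k_con, reference = c("s3", "s4"))
  pc_lo <- polarize(d, k_con, reference = c("s1", "s2"))
  expect_false(pc_hi$sign_flipped == pc_lo$sign_flipped)
  expect_gt(mean(pc_hi$loadings[c("s3", "s4")]), 0)
  expect_gt(mean(pc_lo$loadings[c("s1", "s2")]), 0)
  # u and v are negated simultaneously: outer product invariant
  expect_equal(outer(pc_hi$loadings, pc_hi$gene_loadings),
               outer(pc_lo$loadings, pc_lo$gene_loadings),
               tolerance = 1e-12)
  # sorting is a permutation of the loadings
  expect_setequal(pc_hi$sorted$loading, unname(pc_hi$loadings))
})

test_that("contrast test matches the exact enumeration for separated 3 vs 3", {
  res <- contrast_test(c(4, 5, 6, 1, 2, 3), rep(c("a", "b"), each = 3),
                       positive = "a", alternative = "greater")
  expect_equal(res$p.value, 1 / choose(6, 3))
  expect_true(res$exact)
})

test_that("contrast test returns p = 1 for identical loading multisets", {
  res <- contrast_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res$p.value, 1)
  expect_error(contrast_test(1:3, c("a", "a", "a")), "two groups")
})

test_that("contrast test p-values are uniform under the null", {
  set.seed(99)
  n_sim <- 2000
  labels <- rep(c("a", "b"), each = 25)
  ps <- replicate(n_sim, contrast_test(rnorm(50), labels)$p.value)
  expect_gt(min(ps), 0); expect_lte(max(ps), 1)
  D <- suppressWarnings(ks.test(ps, "punif"))$statistic
  expect_lt(unname(D), 0.05)
  expect_gt(mean(ps < 0.05), 0.03)
  expect_lt(mean(ps < 0.05), 0.07)
})

test_that("sum-of-squares identities hold for planted components", {
  s <- 6; g <- 40
  base <- 5 * outer(rep(1, s), rep(1, g))
  u1 <- c(1, 1, 1, -1, -1, -1) / sqrt(6)
  u2 <- c(1, -1, 0, 0, 1, -1) / 2
  set.seed(8)
  v1 <- rnorm(g); v1 <- v1 - mean(v1); v1 <- v1 / sqrt(sum(v1^2))
  v2 <- rnorm(g); v2 <- v2 - mean(v2); v2 <- v2 - v1 * sum(v1 * v2)
  v2 <- v2 / sqrt(sum(v2^2))
  a <- 4; b <- 2.5

  E_one <- base + a * outer(u1, v1)
  dimnames(E_one) <- list(paste0("s", 1:s), paste0("g", 1:g))
  ss1 <- sum_of_squares(decompose_profile(E_one))
  expect_equal(ss1$table$proportion[1L], 1, tolerance = 1e-10)

  E_two <- base + a * outer(u1, v1) + b * outer(u2, v2)
  dimnames(E_two) <- dimnames(E_one)
  ss2 <- sum_of_squares(decompose_profile(E_two))
  expect_equal(ss2$table$proportion[1:2],
               c(a^2 / (a^2 + b^2), b^2 / (a^2 + b^2)), tolerance = 1e-8)
  # per-gene squares of the top contrast sum to lambda_1^2
  expect_equal(sum(ss2$ss_gene), ss2$ss_contrast, tolerance = 1e-8)
  expect_equal(sum(ss2$table$lambda_sq), ss2$frobenius_sq, tolerance = 1e-8)
  expect_equal(sum(ss2$table$proportion), 1, tolerance = 1e-12)
})

test_that("timecourse differentials recover planted per-week differences", {
  sim <- simulate_dual_species(small_config(seed = 21))
  td <- timecourse_differential(sim$profile_a, groups = c("GK", "WST"))
  expect_equal(ncol(td), 5L)
  expect_equal(colnames(td), as.character(c(4, 6, 8, 16, 24)))

  # identical groups give exactly zero
  mat <- sim$profile_a$matrix
  md <- sim$profile_a$metadata
  half <- md$group == "GK"
  mat[!half, ] <- mat[half, ]
  p_same <- expression_profile(mat, metadata = md)
  expect_true(all(timecourse_differential(p_same, groups = c("GK", "WST")) == 0))

  # planted difference at one timepoint approximately recovered
  delta <- 1.5
  genes <- sim$profile_a$gene_ids[1:40]
  mat2 <- sim$profile_a$matrix
  sel <- md$group == "GK" & md$week == 16
  mat2[sel, genes] <- mat2[sel, genes] + delta
  td2 <- timecourse_differential(expression_profile(mat2, metadata = md),
                                 groups = c("GK", "WST"))
  shift <- mean(td2[genes, "16"] - td[genes, "16"])
  expect_equal(shift, delta, tolerance = 3 * sim$config$noise_sd / sqrt(3 * 40))
})

test_that("timecourse errors name the missing design cell", {
  sim <- simulate_dual_species(small_config(seed = 2))
  md <- sim$profile_a$metadata
  keep <- !(md$group == "WST" & md$week == 8)
  p <- subset_profile(sim$profile_a, samples = which(keep))
  expect_error(timecourse_differential(p, groups = c("GK", "WST")),
               "timepoint 8.*WST")
})

test_that("loading-plane stratification implements the four-region rule", {
  st <- stratify_samples(0, 0.03)
  expect_equal(as.character(st$samples$region), "I")
  expect_equal(unname(st$thresholds), c(-0.01, 0.025))

  x <- c(0.1, -0.5, 0.2, -0.3)
  y <- c(0.1, 0.1, -0.1, -0.1)
  st2 <- stratify_samples(x, y, flags = rep(TRUE, 4), covariate = 1:4)
  expect_equal(as.character(st2$samples$region), c("I", "II", "III", "IV"))
  expect_equal(st2$flagged_outside_iv, 0.75)
  expect_equal(st2$regions$covariate_mean, c(1, 2, 3, 4))

  # all flagged samples in IV: union proportion outside IV is 0
  st3 <- stratify_samples(c(-1, -1), c(-1, -1), flags = c(TRUE, TRUE))
  expect_equal(st3$flagged_outside_iv, 0)
})

test_that("dual-eigen gene ranking agrees with the two-sample oracle", {
  # rank-1 contrast data: |v_1| ranking vs |mean group difference| ranking
  sim <- simulate_dual_species(small_config(
    seed = 13, design_a = "group", amplitude_specific = 0))
  d <- decompose_profile(sim$profile_a)
  md <- sim$profile_a$metadata
  pc <- polarize(d, 1, reference = md$group == "GK")
  diff_vec <- colMeans(sim$profile_a$matrix[md$group == "GK", ]) -
    colMeans(sim$profile_a$matrix[md$group == "WST", ])
  rho <- cor(abs(pc$gene_loadings), abs(diff_vec), method = "spearman")
  expect_gt(rho, 0.9)
})
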