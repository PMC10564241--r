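test_that("baseline removal is exact and orthogonal", {
  E <- matrix(4, 5, 20, dimnames = list(paste0("s", 1:5), paste0("g", 1:20)))
  expect_equal(max(abs(remove_baseline(E))), 0, tolerance = 1e-12)

  p <- rand_profile(6, 50, seed = 2)
  d <- decompose_profile(p)
  E1 <- remove_baseline(p, d)
  # orthogonal to the baseline
  expect_lt(sqrt(sum((t(E1) %*% d$u[, 1L])^2)),
            1e-8 * sqrt(sum(p$matrix^2)))
  # Frobenius identity
  expect_equal(sum(E1^2), sum(d$lambda[-1L]^2), tolerance = 1e-8)
  # re-decomposition reproduces lambda_1..lambda_{s-1}
  d1 <- decompose_profile(structure(E1, dimnames = dimnames(p$matrix)))
  expect_equal(d1$lambda, d$lambda[-1L], tolerance = 1e-8)
})

test_that("concatenation aligns homologs and equalizes Frobenius norms", {
  sim <- simulate_dual_species(small_config(seed = 4))
  cc <- concatenate_profiles(sim$profile_a, sim$profile_b, sim$map,
                             equalize = TRUE)
  ia <- cc$block == "A"
  expect_equal(sqrt(sum(cc$matrix[ia, ]^2)), 1, tolerance = 1e-10)
  expect_equal(sqrt(sum(cc$matrix[!ia, ]^2)), 1, tolerance = 1e-10)
  expect_equal(ncol(cc$matrix), nrow(sim$map$pairs))
  expect_equal(nrow(cc$matrix),
               nrow(sim$profile_a$matrix) + nrow(sim$profile_b$matrix))

  # degenerate single-gene map
  m1 <- homology_map(sim$map$pairs$gene_a[1L], sim$map$pairs$gene_b[1L])
  cc1 <- concatenate_profiles(sim$profile_a, sim$profile_b, m1)
  expect_equal(dim(cc1$matrix),
               c(nrow(sim$profile_a$matrix) + nrow(sim$profile_b$matrix), 1L))
})

test_that("equalized and raw runs find the same top gene-eigenvector", {
  sim <- simulate_dual_species(small_config(seed = 8))
  on_ <- concatenate_profiles(sim$profile_a, sim$profile_b, sim$map,
                              equalize = TRUE)
  off <- concatenate_profiles(sim$profile_a, sim$profile_b, sim$map,
                              equalize = FALSE)
  v_on <- svd(on_$matrix)$v[, 1L]
  v_off <- svd(off$matrix)$v[, 1L]
  expect_gt(abs(cor(v_on, v_off)), 0.8)
})

test_that("unified SVD recovers the shared program with per-species contrasts", {
  sim <- simulate_dual_species(small_config(seed = 10))
  cc <- concatenate_profiles(sim$profile_a, sim$profile_b, sim$map)
  md_a <- sim$profile_a$metadata
  md_b <- sim$profile_b$metadata
  ud <- unified_dual_eigen(cc, groups_a = md_a$group,
                           groups_b = ifelse(md_b$abnormal, "AH", "NH"),
                           positive_a = "GK", positive_b = "AH")
  # planted program on the homolog-restricted gene axis
  prog <- sim$truth$program_a[match(cc$map$gene_a, sim$profile_a$gene_ids)]
  expect_gt(abs(cor(ud$v[, 1L], prog)), 0.9)
  p1 <- ud$contrasts$p.value[ud$contrasts$k == 1L]
  expect_lt(p1[1L], 0.01)
  expect_lt(p1[2L], 0.01)
  # polarized: species-A reference group mean loading positive
  expect_gt(mean(ud$loadings_a[md_a$group == "GK", 1L]), 0)
})

test_that("a signal planted in one species leaves the other species' contrast null", {
  n_null <- 0L; n_sim <- 40L
  for (i in seq_len(n_sim)) {
    sim <- simulate_dual_species(synthetic_config(
      seed = 500 + i, amplitude_shared_b = 0, amplitude_specific = 0,
      n_genes_a = 400, n_genes_b = 400, n_shared_homologs = 300,
      program_size = 50, n_decoys = 2))
    cc <- concatenate_profiles(sim$profile_a, sim$profile_b, sim$map)
    md_b <- sim$profile_b$metadata
    ud <- unified_dual_eigen(cc, groups_a = sim$profile_a$metadata$group,
                             groups_b = ifelse(md_b$abnormal, "AH", "NH"),
                             positive_a = "GK", positive_b = "AH",
                             n_components = 1L)
    pB <- ud$contrasts$p.value[ud$contrasts$species == "B"]
    if (pB > 0.05) n_null <- n_null + 1L
  }
  expect_gte(n_null / n_sim, 0.9)
})

test_that("permuting samples within blocks permutes u and leaves lambda, v unchanged", {
  sim <- simulate_dual_species(small_config(seed = 12))
  cc <- concatenate_profiles(sim$profile_a, sim$profile_b, sim$map)
  sv <- svd(cc$matrix)
  set.seed(1)
  ia <- which(cc$block == "A"); ib <- which(cc$block == "B")
  perm <- c(sample(ia), sample(ib))
  sv2 <- svd(cc$matrix[perm, ])
  expect_equal(sv2$d, sv$d, tolerance = 1e-10)
  # compare subspaces via |cor| of leading vectors (sign freedom)
  expect_equal(abs(cor(sv2$v[, 1L], sv$v[, 1L])), 1, tolerance = 1e-8)
  expect_equal(abs(cor(sv2$u[, 1L], sv$u[perm, 1L])), 1, tolerance = 1e-8)
})

test_that("unified analysis is consistent with the species-alone decompositions", {
  sim <- simulate_dual_species(small_config(seed = 19))
  cc <- concatenate_profiles(sim$profile_a, sim$profile_b, sim$map)
  v_unified <- svd(cc$matrix)$v[, 1L]
  va <- decompose_profile(subset_profile(sim$profile_a,
                                         genes = cc$map$gene_a))$v[, 2L]
  vb <- decompose_profile(subset_profile(sim$profile_b,
                                         genes = cc$map$gene_b))$v[, 2L]
  expect_gt(abs(cor(v_unified, va)), 0.8)
  expect_gt(abs(cor(v_unified, vb)), 0.8)
})
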