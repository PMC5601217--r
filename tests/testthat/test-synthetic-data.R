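test_that("latent generation is deterministic, standardized and near-orthogonal", {
  spec <- tiny_spec(n = 500, k = 4)
  z1 <- generate_latents(spec)
  z2 <- generate_latents(spec)
  expect_identical(z1$values, z2$values)
  expect_lt(max(abs(colMeans(z1$values))), 1e-9)
  expect_lt(max(abs(apply(z1$values, 2, sd) - 1)), 1e-9)
  cc <- cor(z1$values)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.15)
})

test_that("spec validation rejects bad dimensions with informative messages", {
  expect_error(tiny_spec(n = 2), "n_subjects")
  expect_error(sim_spec(50, 3, list(modality_spec("m", c(2, 2, 1))),
                        n_active_per_map = 10),
               "n_active_per_map")
  expect_error(tiny_spec(rho = c(0.5, 0.8)), "descending")
  expect_error(clinical_var("x", "binary", prevalence = 1.2), "prevalence")
})

test_that("spatial maps have exact supports, unit norm and disjoint blobs", {
  spec <- tiny_spec(smooth = 0)
  maps <- generate_spatial_maps(spec)
  for (nm in names(maps)) {
    m <- maps[[nm]]
    sup <- attr(m, "supports")
    for (cc in seq_len(ncol(m))) {
      expect_equal(sum(m[, cc] != 0), spec$n_active_per_map)
      expect_equal(sqrt(sum(m[, cc]^2)), 1, tolerance = 1e-9)
    }
    all_sup <- unlist(sup)
    expect_equal(length(all_sup), length(unique(all_sup)))
  }
})

test_that("smoothed maps keep unit norm and widen support", {
  spec <- tiny_spec(smooth = 3)
  maps <- generate_spatial_maps(spec)
  m <- maps[["modA"]]
  for (cc in seq_len(ncol(m))) {
    expect_equal(sqrt(sum(m[, cc]^2)), 1, tolerance = 1e-9)
    expect_gt(sum(m[, cc] != 0), spec$n_active_per_map)
  }
})

test_that("blob placement fails with sizing advice when the mask is too small", {
  mods <- list(modality_spec("m", c(4, 4, 2)))
  expect_error(sim_spec(60, 4, mods, n_active_per_map = 10), "disjoint blobs")
})

test_that("noiseless blocks equal the exact latent-map product", {
  spec <- tiny_spec(noise_sd = 0)
  z <- generate_latents(spec)
  maps <- generate_spatial_maps(spec)
  ds <- generate_multimodal(z, maps, spec)
  for (nm in names(ds$blocks)) {
    ms <- Filter(function(m) m$name == nm, spec$modality_specs)[[1]]
    expected <- ms$signal_scale * (z$values %*% t(maps[[nm]]))
    expect_equal(ds$blocks[[nm]]$data, expected, tolerance = 1e-12)
  }
  expect_equal(length(ds$blocks), 2L)
})

test_that("overwhelming noise drowns the signal correlation", {
  spec <- tiny_spec(noise_sd = 500, n = 200)
  z <- generate_latents(spec)
  maps <- generate_spatial_maps(spec)
  ds <- generate_multimodal(z, maps, spec)
  sig <- spec$modality_specs[[1]]$signal_scale * (z$values %*% t(maps[["modA"]]))
  expect_lt(abs(cor(as.numeric(ds$blocks[["modA"]]$data), as.numeric(sig))),
            0.1)
})

test_that("clinical generation honors links, prevalences and missingness", {
  # perfect link
  mods <- list(modality_spec("m", c(8, 8, 4)))
  spec <- sim_spec(100, 2, mods, n_active_per_map = 5,
                   clinical_spec = list(
                     clinical_var("exact", "continuous", linked_component = 1,
                                  link_strength = 1),
                     clinical_var("noise", "continuous")),
                   seed = 3)
  z <- generate_latents(spec)
  ct <- generate_clinical(z, spec)
  expect_equal(abs(cor(ct$data$exact, z$values[, 1])), 1, tolerance = 1e-12)

  # binomial prevalence bound at large n
  spec2 <- sim_spec(10000, 2, mods, n_active_per_map = 5,
                    clinical_spec = list(
                      clinical_var("b", "binary", prevalence = 0.5),
                      clinical_var("x", "continuous")),
                    seed = 4)
  ct2 <- generate_clinical(generate_latents(spec2), spec2)
  expect_lt(abs(mean(ct2$data$b) - 0.5), 0.02)

  # declared missingness lands exactly
  spec3 <- sim_spec(50, 2, mods, n_active_per_map = 5,
                    clinical_spec = list(
                      clinical_var("a", "continuous"),
                      clinical_var("b", "continuous")),
                    missing_spec = list(a = 3), seed = 5)
  ct3 <- generate_clinical(generate_latents(spec3), spec3)
  expect_equal(sum(is.na(ct3$data$a)), 3L)
})

test_that("planted canonical correlation is recovered by oracle CCA at large n", {
  mods <- list(modality_spec("m", c(8, 8, 4)))
  spec <- sim_spec(2000, 3, mods, n_active_per_map = 5,
                   clinical_spec = c(
                     list(clinical_var("l1", "continuous", linked_component = 1)),
                     lapply(1:3, function(i)
                       clinical_var(paste0("n", i), "continuous"))),
                   planted_rho = 0.9, seed = 6)
  z <- generate_latents(spec)
  ct <- generate_clinical(z, spec)
  cm <- encode_clinical(ct)
  fit <- cca(cm, z$values)
  expect_gt(fit$r[1], 0.85)
  expect_lt(fit$r[1], 0.95)
})

test_that("outcome scores follow the developmental-scale link model", {
  mods <- list(modality_spec("m", c(8, 8, 4)))
  base <- sim_spec(2000, 2, mods, n_active_per_map = 5,
                   outcome_spec = list(list(name = "null_score",
                                            linked_pair = 1L, effect_r = 0)),
                   outcome_missing_frac = 0, seed = 7)
  z <- generate_latents(base)
  sc <- generate_outcomes(z$values, base)
  expect_lt(abs(cor(sc$null_score, z$values[, 1])), 0.1)

  exact <- sim_spec(100, 2, mods, n_active_per_map = 5,
                    outcome_spec = list(list(name = "s", linked_pair = 2L,
                                             effect_r = 1)),
                    outcome_missing_frac = 0, seed = 8)
  z2 <- generate_latents(exact)
  sc2 <- generate_outcomes(z2$values, exact)
  fit <- lm(sc2$s ~ z2$values[, 2])
  expect_equal(suppressWarnings(summary(fit))$r.squared, 1, tolerance = 1e-12)
  expect_error(generate_outcomes(z2$values,
    sim_spec(100, 2, mods, n_active_per_map = 5,
             outcome_spec = list(list(name = "s", linked_pair = 9L,
                                      effect_r = 0.5)), seed = 8)),
    "linked_pair")
})

test_that("default follow-up fraction leaves 425 of 449 subjects scored", {
  spec <- default_sim_spec(n_subjects = 449, seed = 2)
  z <- generate_latents(spec)
  sc <- generate_outcomes(z$values, spec)
  expect_equal(sum(!is.na(sc$cognitive)), 425L)
})

test_that("identical specs give bit-identical cohorts", {
  c1 <- simulate_cohort(tiny_spec(seed = 11))
  c2 <- simulate_cohort(tiny_spec(seed = 11))
  expect_identical(c1$dataset$blocks, c2$dataset$blocks)
  expect_identical(c1$clinical$data, c2$clinical$data)
  expect_identical(c1$outcomes, c2$outcomes)
})

test_that("null-mode cohorts yield calibrated smallest permutation p-values", {
  # all links zero: X independent of Y, so min p should exceed 0.05 in the
  # large majority of replicates
  hits <- 0L
  n_rep <- 100L
  for (i in seq_len(n_rep)) {
    mods <- list(modality_spec("m", c(8, 8, 4), noise_sd = 0.5,
                               signal_scale = 3))
    spec <- sim_spec(80, 3, mods, n_active_per_map = 6,
                     clinical_spec = lapply(1:4, function(j)
                       clinical_var(paste0("x", j), "continuous")),
                     seed = 5000 + i)
    coh <- simulate_cohort(spec)
    cm <- encode_clinical(coh$clinical)
    dec <- suppressWarnings(fit_linked(coh$dataset, max_components = 3,
                                       seed = i))
    pt <- perm_test_pairs(cm, component_features(dec), P = 199, seed = i)
    if (min(pt$p) > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 0.9 * n_rep)
})
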