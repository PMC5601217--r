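# Shared fixtures, all generated in code.

# Minimal two-modality spec for fast structural tests.
tiny_spec <- function(n = 60, k = 3, seed = 1, noise_sd = 0.5,
                      smooth = 0, n_clin = 4, rho = c(0.8, 0.6)) {
  mods <- list(
    modality_spec("modA", c(8, 8, 6), noise_sd = noise_sd,
                  smooth_fwhm_mm = smooth, signal_scale = 4),
    modality_spec("modB", c(8, 8, 6), noise_sd = noise_sd,
                  smooth_fwhm_mm = smooth, signal_scale = 4,
                  kind = "skeleton"))
  cvs <- list(clinical_var("c1", "continuous", linked_component = 1),
              clinical_var("c2", "continuous", linked_component = 2))
  if (n_clin > 2)
    cvs <- c(cvs, lapply(seq_len(n_clin - 2), function(i)
      clinical_var(paste0("noise", i), "continuous")))
  sim_spec(n, k, mods, n_active_per_map = 8, clinical_spec = cvs,
           planted_rho = rho,
           outcome_spec = list(list(name = "score", linked_pair = 1L,
                                    effect_r = 0.4)),
           seed = seed)
}

# Study-shaped spec for the end-to-end recovery checks: 4 modalities,
# k = 8 latent components, planted canonical correlations 0.9/0.7/0.5,
# 12 clinical variables (3 linked continuous, 5 noise continuous, 4 noise
# binary).
recovery_spec <- function(n = 500, seed = 1) {
  mods <- list(
    modality_spec("jacobian", c(16, 16, 12), noise_sd = 1,
                  smooth_fwhm_mm = 4, signal_scale = 6),
    modality_spec("t2w", c(16, 16, 12), noise_sd = 1,
                  smooth_fwhm_mm = 4, signal_scale = 6),
    modality_spec("fa_skeleton", c(16, 16, 12), noise_sd = 1,
                  signal_scale = 6, kind = "skeleton"),
    modality_spec("md_skeleton", c(16, 16, 12), noise_sd = 1,
                  signal_scale = 6, kind = "skeleton"))
  cvs <- c(
    list(clinical_var("ga", "continuous", linked_component = 1),
         clinical_var("bw", "continuous", linked_component = 2),
         clinical_var("mv", "continuous", linked_component = 3)),
    lapply(1:5, function(i) clinical_var(paste0("cn", i), "continuous")),
    lapply(1:4, function(i) clinical_var(paste0("bn", i), "binary",
                                         prevalence = 0.3)))
  sim_spec(n, 8, mods, n_active_per_map = 16, clinical_spec = cvs,
           planted_rho = c(0.9, 0.7, 0.5), seed = seed)
}

# Correlated block pair with population first canonical correlation rho:
# X column 1 tracks a shared latent, Y column 1 is the latent itself.
toy_blocks <- function(n, rho, p = 3, k = 4, seed = 1) {
  with_seed(seed, {
    z <- rnorm(n)
    x <- cbind(rho * z + sqrt(1 - rho^2) * rnorm(n),
               matrix(rnorm(n * (p - 1)), n, p - 1))
    y <- cbind(z, matrix(rnorm(n * (k - 1)), n, k - 1))
    list(X = x, Y = y)
  })
}

# Brute-force CCA oracle: direct eigendecomposition of
# Sxx^-1 Sxy Syy^-1 Syx.
cca_oracle <- function(X, Y) {
  cx <- scale(X, scale = FALSE); cy <- scale(Y, scale = FALSE)
  n <- nrow(cx)
  sxx <- crossprod(cx) / (n - 1)
  syy <- crossprod(cy) / (n - 1)
  sxy <- crossprod(cx, cy) / (n - 1)
  m <- solve(sxx) %*% sxy %*% solve(syy) %*% t(sxy)
  ev <- eigen(m)
  ord <- order(Re(ev$values), decreasing = TRUE)
  r <- sqrt(pmax(Re(ev$values[ord]), 0))
  a <- Re(ev$vectors[, ord, drop = FALSE])
  list(r = r, a = a)
}
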