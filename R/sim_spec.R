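#' Describe one imaging modality for simulation
#'
#' @param name modality label (e.g. \code{"jacobian"}, \code{"t2w"},
#'   \code{"fa_skeleton"}).
#' @param grid_dims 3 positive integers, voxel grid.
#' @param voxel_size_mm 3 positive reals, voxel edge lengths in mm.
#' @param noise_sd standard deviation of additive voxel noise.
#' @param smooth_fwhm_mm full width at half maximum of the Gaussian spatial
#'   smoothing applied to component maps, in mm (0 disables smoothing).
#' @param signal_scale multiplier applied to the signal part of the block,
#'   emulating modality-specific units.
#' @param kind \code{"volume"} (mask covers the whole grid) or
#'   \code{"skeleton"} (mask restricted to a one-voxel-thick mid-axial sheet,
#'   emulating tract/gray-matter skeleton projections).
#' @return a list of class \code{"modality_spec"}.
#' @export
modality_spec <- function(name, grid_dims, voxel_size_mm = c(1, 1, 1),
                          noise_sd = 1, smooth_fwhm_mm = 0,
                          signal_scale = 1, kind = c("volume", "skeleton")) {
  kind <- match.arg(kind)
  if (length(grid_dims) != 3L || any(grid_dims < 1))
    stop2("modality '", name, "': grid_dims must be 3 positive integers")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop2("modality '", name, "': voxel_size_mm must be 3 positive reals")
  if (noise_sd < 0) stop2("modality '", name, "': noise_sd must be >= 0")
  if (smooth_fwhm_mm < 0) stop2("modality '", name, "': smooth_fwhm_mm must be >= 0")
  structure(list(name = name, grid_dims = as.integer(grid_dims),
                 voxel_size_mm = voxel_size_mm, noise_sd = noise_sd,
                 smooth_fwhm_mm = smooth_fwhm_mm, signal_scale = signal_scale,
                 kind = kind),
            class = "modality_spec")
}

#' Describe one clinical variable for simulation
#'
#' @param name variable name.
#' @param kind \code{"continuous"} or \code{"binary"}.
#' @param prevalence for binary variables, the population positive fraction
#'   in (0, 1).
#' @param linked_component index of the latent component this variable tracks,
#'   or \code{NA} for an unlinked (pure noise) variable.
#' @param link_strength correlation in [0, 1] between the variable (or its
#'   latent liability, for binary variables) and the linked component;
#'   \code{NA} requests automatic calibration from the spec's
#'   \code{planted_rho} (see \code{\link{sim_spec}}).
#' @param mean,sd location and scale used to map the standardized value onto
#'   a plausible clinical range (continuous only).
#' @param unit display unit label.
#' @param center \code{"median"} or \code{"mean"}: which central value the
#'   cohort summary reports for this variable.
#' @return a list of class \code{"clinical_var_spec"}.
#' @export
clinical_var <- function(name, kind = c("continuous", "binary"),
                         prevalence = NA_real_, linked_component = NA_integer_,
                         link_strength = NA_real_, mean = 0, sd = 1,
                         unit = "", center = c("median", "mean")) {
  kind <- match.arg(kind)
  center <- match.arg(center)
  if (kind == "binary") {
    if (!is.finite(prevalence) || prevalence <= 0 || prevalence >= 1)
      stop2("variable '", name, "': prevalence must be in (0, 1)")
  }
  if (!is.na(link_strength) && (link_strength < 0 || link_strength > 1))
    stop2("variable '", name, "': link_strength must be in [0, 1]")
  structure(list(name = name, kind = kind, prevalence = prevalence,
                 linked_component = linked_component,
                 link_strength = link_strength, mean = mean, sd = sd,
                 unit = unit, center = center),
            class = "clinical_var_spec")
}

#' Simulation specification for a synthetic multimodal cohort
#'
#' Defines the full generative model used to validate the pipeline: latent
#' subject components shared across modalities, blob-shaped spatial maps per
#' modality, a clinical table linearly linked to a subset of components at
#' prescribed canonical-correlation levels, and outcome scores linked to
#' chosen canonical pairs.
#'
#' Link strengths left \code{NA} are calibrated so that the population
#' canonical correlation between the clinical block and the latent block for
#' pair \eqn{j} equals \code{planted_rho[j]}: with \eqn{k} variables linked to
#' component \eqn{j}, each receives strength \eqn{s} solving
#' \eqn{k s^2/(1-s^2) = \rho_j^2/(1-\rho_j^2)}. For binary variables the
#' calibration holds on the latent liability scale; thresholding attenuates
#' the observable correlation.
#'
#' @param n_subjects number of subjects.
#' @param k_components number of latent components.
#' @param modality_specs list of \code{\link{modality_spec}} objects.
#' @param n_active_per_map number of contiguous signal voxels per component
#'   spatial map (pre-smoothing).
#' @param clinical_spec list of \code{\link{clinical_var}} objects.
#' @param planted_rho target canonical correlations, strictly descending,
#'   each in (0, 1]; entry \eqn{j} governs component \eqn{j}.
#' @param outcome_spec list of lists \code{(name, linked_pair, effect_r)};
#'   \code{linked_pair} indexes a canonical pair (or \code{NA}),
#'   \code{effect_r} in [-1, 1].
#' @param missing_spec named list \code{variable = n_missing} of clinical
#'   entries to blank out.
#' @param outcome_missing_frac fraction of subjects without outcome scores
#'   (default 24/449, matching loss to follow-up of 24 in a cohort of 449).
#' @param seed integer seed controlling all randomness.
#' @return a validated list of class \code{"sim_spec"}.
#' @export
sim_spec <- function(n_subjects, k_components, modality_specs,
                     n_active_per_map = 20, clinical_spec = list(),
                     planted_rho = numeric(0), outcome_spec = list(),
                     missing_spec = list(), outcome_missing_frac = 24 / 449,
                     seed = 1L) {
  if (n_subjects < 3) stop2("n_subjects must be >= 3")
  if (k_components < 1) stop2("k_components must be >= 1")
  if (n_active_per_map < 1) stop2("n_active_per_map must be >= 1")
  if (length(planted_rho)) {
    if (any(planted_rho <= 0 | planted_rho > 1))
      stop2("planted_rho entries must lie in (0, 1]")
    if (length(planted_rho) > 1 && any(diff(planted_rho) >= 0))
      stop2("planted_rho must be strictly descending")
    if (length(planted_rho) > k_components)
      stop2("planted_rho longer than k_components")
  }
  for (ms in modality_specs) {
    mask_n <- if (ms$kind == "skeleton") prod(ms$grid_dims[1:2]) else prod(ms$grid_dims)
    if (mask_n < n_active_per_map * k_components)
      stop2("modality '", ms$name, "': mask (", mask_n,
            " voxels) cannot hold ", k_components,
            " disjoint blobs of ", n_active_per_map,
            " voxels; enlarge grid_dims or reduce n_active_per_map")
  }
  for (cv in clinical_spec) {
    if (!is.na(cv$linked_component) &&
        (cv$linked_component < 1 || cv$linked_component > k_components))
      stop2("variable '", cv$name, "': linked_component ", cv$linked_component,
            " outside 1..k_components")
  }
  if (n_subjects <= length(clinical_spec) + k_components)
    stop2("n_subjects (", n_subjects, ") must exceed the number of clinical ",
          "variables plus k_components (",
          length(clinical_spec) + k_components, ") for CCA identifiability")
  for (os in outcome_spec) {
    if (abs(os$effect_r %||% 0) > 1)
      stop2("outcome '", os$name, "': effect_r must be in [-1, 1]")
  }
  spec <- structure(list(n_subjects = as.integer(n_subjects),
                         k_components = as.integer(k_components),
                         modality_specs = modality_specs,
                         n_active_per_map = as.integer(n_active_per_map),
                         clinical_spec = clinical_spec,
                         planted_rho = planted_rho,
                         outcome_spec = outcome_spec,
                         missing_spec = missing_spec,
                         outcome_missing_frac = outcome_missing_frac,
                         seed = as.integer(seed)),
                    class = "sim_spec")
  calibrate_links(spec)
}

# Fill NA link strengths from planted_rho (equal split within a component).
calibrate_links <- function(spec) {
  if (!length(spec$clinical_spec)) return(spec)
  linked <- vapply(spec$clinical_spec,
                   function(v) as.integer(v$linked_component %||% NA), 1L)
  for (j in unique(linked[!is.na(linked)])) {
    idx <- which(!is.na(linked) & linked == j)
    need <- idx[vapply(spec$clinical_spec[idx],
                       function(v) is.na(v$link_strength), logical(1))]
    if (!length(need)) next
    if (j > length(spec$planted_rho))
      stop2("variable(s) linked to component ", j,
            " have no link_strength and planted_rho has no entry ", j)
    rho <- spec$planted_rho[j]
    if (rho == 1) { s <- 1 } else {
      q <- rho^2 / (1 - rho^2)
      s <- sqrt((q / length(idx)) / (1 + q / length(idx)))
    }
    for (i in need) spec$clinical_spec[[i]]$link_strength <- s
  }
  spec
}

#' Default study-scale simulation spec
#'
#' A ready-made \code{\link{sim_spec}} emulating the statistical shape of a
#' preterm-cohort multimodal MRI study: 449 subjects, four modality blocks
#' (volume-change maps, T2w intensity, FA skeleton, cortical/deep-gray MD
#' skeleton), 30 clinical variables (7 continuous, 23 binary with prevalences
#' from under 1\% to 65\%, one variable with a single missing entry), three
#' planted clinical-imaging associations at canonical correlations 0.9, 0.7
#' and 0.5, and three outcome scores on the developmental-scale calibration
#' (mean 100, sd 15) linked to canonical pairs.
#'
#' @param n_subjects cohort size (default 449).
#' @param seed integer seed.
#' @param grid_dims grid for the volumetric modalities; skeleton modalities
#'   use a mid-axial sheet of the same in-plane size.
#' @return a \code{"sim_spec"}.
#' @export
default_sim_spec <- function(n_subjects = 449, seed = 1L,
                             grid_dims = c(16, 16, 12)) {
  mods <- list(
    modality_spec("jacobian", grid_dims, c(1, 1, 1), noise_sd = 1,
                  smooth_fwhm_mm = 4, signal_scale = 6),
    modality_spec("t2w", grid_dims, c(1, 1, 1), noise_sd = 1,
                  smooth_fwhm_mm = 4, signal_scale = 6),
    modality_spec("fa_skeleton", grid_dims, c(1, 1, 1), noise_sd = 1,
                  smooth_fwhm_mm = 0, signal_scale = 6, kind = "skeleton"),
    modality_spec("md_skeleton", grid_dims, c(1, 1, 1), noise_sd = 1,
                  smooth_fwhm_mm = 0, signal_scale = 6, kind = "skeleton"))
  cont <- list(
    clinical_var("gestational_age", "continuous", linked_component = 1L,
                 mean = 30.1, sd = 2.3, unit = "weeks", center = "median"),
    clinical_var("birth_weight", "continuous", linked_component = 2L,
                 mean = 1305, sd = 450, unit = "g", center = "median"),
    clinical_var("mech_ventilation_days", "continuous", linked_component = 3L,
                 mean = 2.89, sd = 6, unit = "days", center = "mean"),
    clinical_var("cpap_days", "continuous", mean = 16.74, sd = 18,
                 unit = "days", center = "mean"),
    clinical_var("tpn_days", "continuous", mean = 8.92, sd = 14,
                 unit = "days", center = "mean"),
    clinical_var("imd_score", "continuous", mean = 17.57, sd = 12, unit = "",
                 center = "median"),
    clinical_var("maternal_age", "continuous", mean = 32.75, sd = 5.8,
                 unit = "years", center = "median"))
  bin_prev <- c(male = 0.5033, nonsingleton = 0.3207,
                preg_hypertension = 0.1849, hypertension = 0.0489,
                prom = 0.1604, antenatal_hemorrhage = 0.1314,
                accidental_hemorrhage = 0.0379, uti = 0.0245,
                gest_diabetes = 0.0445, oligohydramnios = 0.0757,
                polyhydramnios = 0.0045, drug_abuse = 0.0133, ivf = 0.1447,
                bacterial_infection = 0.0579, caesarean = 0.6503,
                elective_caesarean = 0.0869, twin_twin_transfusion = 0.0200,
                chorioamnionitis = 0.0668, iugr = 0.1470,
                incomplete_steroids = 0.1514, surfactant = 0.5278,
                pda = 0.0512, nec_surgery = 0.0200)
  bins <- lapply(names(bin_prev), function(nm)
    clinical_var(nm, "binary", prevalence = bin_prev[[nm]]))
  sim_spec(
    n_subjects = n_subjects, k_components = 8L, modality_specs = mods,
    n_active_per_map = 16L, clinical_spec = c(cont, bins),
    planted_rho = c(0.9, 0.7, 0.5),
    outcome_spec = list(
      list(name = "cognitive", linked_pair = 2L, effect_r = 0.16),
      list(name = "motor", linked_pair = 2L, effect_r = 0.21),
      list(name = "language", linked_pair = 1L, effect_r = 0.10)),
    missing_spec = list(tpn_days = 1L),
    seed = seed)
}
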