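#' Generate latent subject components
#'
#' Draws the shared subject courses that drive between-subject variation in
#' every modality: independent standard-normal columns, exactly standardized
#' (mean 0, sample sd 1) per column.
#'
#' @param spec a \code{\link{sim_spec}}.
#' @param seed optional override of the spec's seed.
#' @return list of class \code{"latent_matrix"} with \code{values}
#'   (n_subjects x k_components) and \code{seed}.
#' @export
generate_latents <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "sim_spec"))
  n <- spec$n_subjects; k <- spec$k_components
  z <- with_seed(child_seed(seed, "latents"),
                 matrix(rnorm(n * k), n, k))
  z <- standardize_columns(z, "latent matrix")
  colnames(z) <- paste0("comp", seq_len(k))
  structure(list(values = z, seed = as.integer(seed)),
            class = "latent_matrix")
}

# Mask (linear indices) implied by a modality spec.
modality_mask <- function(ms) {
  d <- ms$grid_dims
  if (ms$kind == "skeleton") {
    z <- ceiling(d[3] / 2)
    ij <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]))
    as.integer(ij$i + (ij$j - 1L) * d[1] + (z - 1L) * d[1] * d[2])
  } else seq_len(prod(d))
}

# 6-connected neighbors of linear voxel index v within the grid.
voxel_neighbors <- function(v, dims) {
  nxy <- dims[1] * dims[2]
  k <- (v - 1L) %/% nxy
  r <- (v - 1L) %% nxy
  j <- r %/% dims[1]; i <- r %% dims[1]
  nb <- integer(0)
  if (i > 0) nb <- c(nb, v - 1L)
  if (i < dims[1] - 1) nb <- c(nb, v + 1L)
  if (j > 0) nb <- c(nb, v - dims[1])
  if (j < dims[2] - 1) nb <- c(nb, v + dims[1])
  if (k > 0) nb <- c(nb, v - nxy)
  if (k < dims[3] - 1) nb <- c(nb, v + nxy)
  nb
}

# Connected components (6-connectivity) of a set of linear voxel indices.
conn_components <- function(avail_set, dims) {
  avail <- logical(prod(dims))
  avail[avail_set] <- TRUE
  comps <- list()
  for (v0 in avail_set) {
    if (!avail[v0]) next
    comp <- integer(0)
    queue <- v0
    avail[v0] <- FALSE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- voxel_neighbors(v, dims)
      nb <- nb[avail[nb]]
      avail[nb] <- FALSE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- comp
  }
  comps
}

# Grow one contiguous blob of `size` voxels inside `avail_set` (linear
# indices), 6-connectivity, randomized growth. Growth happens inside a
# connected region of at least `size` voxels, so it cannot stall.
grow_blob <- function(avail_set, size, dims) {
  comps <- conn_components(avail_set, dims)
  big <- comps[vapply(comps, length, 1L) >= size]
  if (!length(big)) return(NULL)
  region <- big[[sample.int(length(big), 1L)]]
  in_region <- logical(prod(dims)); in_region[region] <- TRUE
  start <- region[sample.int(length(region), 1L)]
  blob <- start
  in_region[start] <- FALSE
  frontier <- start                        # blob voxels that may still grow
  while (length(blob) < size) {
    if (!length(frontier)) {               # blob filled a pocket: widen via
      frontier <- blob                     # full re-scan (region guarantees
      cand_any <- FALSE                    # an escape exists only if some
      for (v in frontier) {                # blob voxel touches the region)
        if (any(in_region[voxel_neighbors(v, dims)])) { cand_any <- TRUE; break }
      }
      if (!cand_any) return(NULL)
    }
    pick <- sample.int(length(frontier), 1L)
    v <- frontier[pick]
    nb <- voxel_neighbors(v, dims)
    nb <- nb[in_region[nb]]
    if (!length(nb)) { frontier <- frontier[-pick]; next }
    u <- nb[sample.int(length(nb), 1L)]
    blob <- c(blob, u)
    in_region[u] <- FALSE
    frontier <- c(frontier, u)
  }
  blob
}

#' Generate component spatial maps per modality
#'
#' Each latent component receives, per modality, a contiguous blob of
#' \code{n_active_per_map} signal voxels; blobs of different components are
#' disjoint within a modality, so the planted maps are spatially independent
#' by construction. Maps are then Gaussian-smoothed at the modality's FWHM
#' (sigma = FWHM / sqrt(8 ln 2)) and rescaled to unit Euclidean norm.
#'
#' @param spec a \code{\link{sim_spec}}.
#' @param seed optional seed override.
#' @return named list (per modality) of V_m x k map matrices; each carries
#'   an attribute \code{"supports"} with the pre-smoothing voxel indices per
#'   component (positions within the mask) and \code{"mask_idx"}.
#' @export
generate_spatial_maps <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "sim_spec"))
  k <- spec$k_components
  with_seed(child_seed(seed, "maps"), {
    out <- list()
    for (ms in spec$modality_specs) {
      mask <- modality_mask(ms)
      pos_of <- integer(prod(ms$grid_dims))
      pos_of[mask] <- seq_along(mask)
      used <- integer(0)
      supports <- vector("list", k)
      for (cc in seq_len(k)) {
        avail <- setdiff(mask, used)
        if (length(avail) < spec$n_active_per_map)
          stop2("modality '", ms$name, "': cannot place ", k,
                " disjoint blobs of ", spec$n_active_per_map,
                " voxels; enlarge the grid or reduce n_active_per_map")
        blob <- grow_blob(avail, spec$n_active_per_map, ms$grid_dims)
        if (is.null(blob))
          stop2("modality '", ms$name, "': no contiguous region of ",
                spec$n_active_per_map, " free voxels remains for component ",
                cc, "; enlarge the grid or reduce n_active_per_map")
        supports[[cc]] <- pos_of[blob]
        used <- c(used, blob)
      }
      m <- matrix(0, length(mask), k)
      for (cc in seq_len(k)) {
        if (ms$smooth_fwhm_mm > 0) {
          vol <- array(0, ms$grid_dims)
          vol[mask[supports[[cc]]]] <- 1
          sig <- fwhm_to_sigma(ms$smooth_fwhm_mm) / ms$voxel_size_mm
          vol <- smooth_gaussian_3d(vol, sig)
          m[, cc] <- vol[mask]
        } else {
          m[supports[[cc]], cc] <- 1
        }
        m[, cc] <- m[, cc] / sqrt(sum(m[, cc]^2))
      }
      attr(m, "supports") <- supports
      attr(m, "mask_idx") <- mask
      out[[ms$name]] <- m
    }
    out
  })
}

#' Assemble noisy multimodal blocks from latents and spatial maps
#'
#' Block model: \code{B_m = s_m * Z A_m' + noise_sd_m * E_m} with independent
#' Gaussian voxel noise.
#'
#' @param latents a \code{"latent_matrix"}.
#' @param maps output of \code{\link{generate_spatial_maps}}.
#' @param spec the \code{\link{sim_spec}}.
#' @param seed optional seed override.
#' @return a \code{\link{multimodal_dataset}}.
#' @export
generate_multimodal <- function(latents, maps, spec, seed = spec$seed) {
  stopifnot(inherits(latents, "latent_matrix"), inherits(spec, "sim_spec"))
  z <- latents$values
  if (ncol(z) != spec$k_components)
    stop2("latents have ", ncol(z), " columns but spec$k_components is ",
          spec$k_components)
  with_seed(child_seed(seed, "imaging"), {
    blocks <- list()
    for (ms in spec$modality_specs) {
      a <- maps[[ms$name]]
      if (is.null(a)) stop2("no spatial maps for modality '", ms$name, "'")
      if (ncol(a) != ncol(z))
        stop2("modality '", ms$name, "': maps are ", nrow(a), "x", ncol(a),
              " but latents are ", nrow(z), "x", ncol(z))
      b <- ms$signal_scale * (z %*% t(a))
      if (ms$noise_sd > 0)
        b <- b + ms$noise_sd * matrix(rnorm(length(b)), nrow(b), ncol(b))
      blocks[[ms$name]] <- list(data = b, grid_dims = ms$grid_dims,
                                voxel_size_mm = ms$voxel_size_mm,
                                mask_idx = attr(a, "mask_idx"),
                                kind = ms$kind)
    }
    multimodal_dataset(blocks)
  })
}

#' Generate the raw clinical table
#'
#' Linked variables follow \code{s * Z_j + sqrt(1 - s^2) * noise} (on the
#' latent liability scale for binary variables, thresholded at the quantile
#' matching the stated prevalence); unlinked variables are independent noise.
#' Continuous variables are shifted/scaled to a plausible clinical range.
#' Entries declared in \code{missing_spec} are blanked.
#'
#' @param latents a \code{"latent_matrix"}.
#' @param spec the \code{\link{sim_spec}}.
#' @param seed optional seed override.
#' @return a \code{\link{clinical_table}}.
#' @export
generate_clinical <- function(latents, spec, seed = spec$seed) {
  stopifnot(inherits(latents, "latent_matrix"), inherits(spec, "sim_spec"))
  z <- latents$values
  n <- nrow(z)
  with_seed(child_seed(seed, "clinical"), {
    cols <- list(); meta <- list()
    for (cv in spec$clinical_spec) {
      s <- cv$link_strength
      if (!is.na(cv$linked_component) && !is.na(s) && s > 0) {
        base <- s * z[, cv$linked_component] + sqrt(1 - s^2) * rnorm(n)
      } else {
        base <- rnorm(n)
      }
      if (cv$kind == "continuous") {
        val <- cv$mean + cv$sd * base
      } else {
        val <- as.integer(base > qnorm(1 - cv$prevalence))
      }
      cols[[cv$name]] <- val
      meta[[cv$name]] <- cv
    }
    df <- as.data.frame(cols, check.names = FALSE)
    for (nm in names(spec$missing_spec)) {
      if (!nm %in% names(df)) stop2("missing_spec names unknown variable '", nm, "'")
      nmiss <- spec$missing_spec[[nm]]
      df[sample.int(n, nmiss), nm] <- NA
    }
    clinical_table(df, meta = meta,
                   subject_ids = sprintf("sub-%04d", seq_len(n)))
  })
}

#' Generate outcome scores linked to canonical variates
#'
#' Scores follow the developmental-scale calibration (mean 100, sd 15):
#' \code{100 + 15 * (effect_r * z + sqrt(1 - effect_r^2) * noise)} where
#' \code{z} is the standardized variate of the linked pair. A fixed fraction
#' of subjects (shared across outcomes, emulating loss to follow-up) has
#' missing scores.
#'
#' @param variates n x m matrix of canonical variates or latent components
#'   (at generation time the latent components play the role of the
#'   population canonical variates).
#' @param spec the \code{\link{sim_spec}}.
#' @param seed optional seed override.
#' @return data.frame of scores (one column per outcome, NA where missing)
#'   with rownames = subject ids and attribute \code{"missing_ids"}.
#' @export
generate_outcomes <- function(variates, spec, seed = spec$seed) {
  stopifnot(inherits(spec, "sim_spec"))
  v <- as.matrix(variates)
  n <- nrow(v)
  with_seed(child_seed(seed, "outcomes"), {
    n_miss <- round(spec$outcome_missing_frac * n)
    miss <- if (n_miss > 0) sort(sample.int(n, n_miss)) else integer(0)
    out <- list()
    for (os in spec$outcome_spec) {
      r <- os$effect_r
      if (!is.na(os$linked_pair %||% NA)) {
        if (os$linked_pair < 1 || os$linked_pair > ncol(v))
          stop2("outcome '", os$name, "': linked_pair ", os$linked_pair,
                " outside 1..", ncol(v))
        zz <- as.numeric(scale(v[, os$linked_pair]))
        sc <- 100 + 15 * (r * zz + sqrt(1 - r^2) * rnorm(n))
      } else {
        sc <- 100 + 15 * rnorm(n)
      }
      sc[miss] <- NA
      out[[os$name]] <- sc
    }
    df <- as.data.frame(out, check.names = FALSE)
    rownames(df) <- sprintf("sub-%04d", seq_len(n))
    attr(df, "missing_ids") <- rownames(df)[miss]
    df
  })
}

#' Simulate a complete synthetic cohort
#'
#' Runs all generator stages under per-stage child seeds and returns the full
#' bundle. Identical specs (including seed) yield bit-identical bundles.
#'
#' @param spec a \code{\link{sim_spec}}.
#' @return list of class \code{"sim_cohort"}: \code{spec}, \code{latents},
#'   \code{maps}, \code{dataset}, \code{clinical}, \code{outcomes}.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  latents <- generate_latents(spec)
  maps <- generate_spatial_maps(spec)
  dataset <- generate_multimodal(latents, maps, spec)
  clinical <- if (length(spec$clinical_spec)) generate_clinical(latents, spec)
  outcomes <- if (length(spec$outcome_spec))
    generate_outcomes(latents$values, spec)
  structure(list(spec = spec, latents = latents, maps = maps,
                 dataset = dataset, clinical = clinical, outcomes = outcomes),
            class = "sim_cohort")
}
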