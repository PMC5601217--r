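#' Pipeline configuration
#'
#' Parameters and sensitivity-analysis switches for the end-to-end analysis.
#' All randomness derives from the single \code{seed}, expanded into
#' per-stage child seeds so toggling one stage does not perturb another's
#' random stream.
#'
#' @param max_components upper limit for the linked decomposition.
#' @param perms permutations for pair and loading significance.
#' @param boot bootstrap replicates.
#' @param alpha_pairs significance level for canonical pairs.
#' @param alpha_maps voxelwise FWE significance level.
#' @param report_pairs number of pairs reported in tables.
#' @param include_icv append an intracranial-volume column to the clinical
#'   block (sensitivity analysis).
#' @param drop_lesion_ids subject ids removed entirely before analysis.
#' @param remove_pathology_components component indices excluded from the
#'   imaging feature matrix.
#' @param transforms named vector of skew transforms passed to
#'   \code{\link{transform_skewed}}.
#' @param rare_factor_threshold drop binary factors below this prevalence
#'   (0 disables the filter).
#' @param reject_threshold explained-variance share below which components
#'   are rejected.
#' @param scale_binary z-score binary columns instead of centering only.
#' @param map_pairs canonical pair indices for which voxelwise loading maps
#'   are computed (empty = skip the mapping stage).
#' @param map_perms permutations for voxelwise FWE correction.
#' @param loading_family multiplicity handling for loading tests
#'   (\code{"max"} or \code{"per_variable"}).
#' @param seed integer master seed.
#' @return validated list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(max_components = 100, perms = 1000, boot = 1000,
                            alpha_pairs = 0.05, alpha_maps = 0.01,
                            report_pairs = 10, include_icv = FALSE,
                            drop_lesion_ids = character(0),
                            remove_pathology_components = integer(0),
                            transforms = NULL, rare_factor_threshold = 0,
                            reject_threshold = 1e-4, scale_binary = FALSE,
                            map_pairs = integer(0), map_perms = 1000,
                            loading_family = "max", seed = 1L) {
  stopifnot(max_components >= 1, perms >= 1, boot >= 100,
            alpha_pairs > 0, alpha_pairs < 1, alpha_maps > 0, alpha_maps < 1,
            report_pairs >= 1, rare_factor_threshold >= 0,
            rare_factor_threshold < 1, reject_threshold >= 0)
  loading_family <- match.arg(loading_family, c("max", "per_variable"))
  structure(list(max_components = as.integer(max_components),
                 perms = as.integer(perms), boot = as.integer(boot),
                 alpha_pairs = alpha_pairs, alpha_maps = alpha_maps,
                 report_pairs = as.integer(report_pairs),
                 include_icv = isTRUE(include_icv),
                 drop_lesion_ids = as.character(drop_lesion_ids),
                 remove_pathology_components =
                   as.integer(remove_pathology_components),
                 transforms = transforms,
                 rare_factor_threshold = rare_factor_threshold,
                 reject_threshold = reject_threshold,
                 scale_binary = isTRUE(scale_binary),
                 map_pairs = as.integer(map_pairs),
                 map_perms = as.integer(map_perms),
                 loading_family = loading_family,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' @param config a \code{"pipeline_config"}.
#' @param path JSON file path.
#' @return \code{write_config} invisibly returns the path;
#'   \code{read_config} returns the restored \code{"pipeline_config"}.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  # named atomic vectors serialize as arrays (dropping names); keep the
  # transform assignments as a JSON object instead
  if (!is.null(x$transforms)) x$transforms <- as.list(x$transforms)
  jsonlite::write_json(x, path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  x <- x[!vapply(x, is.null, logical(1))]
  for (nm in c("drop_lesion_ids", "map_pairs",
               "remove_pathology_components", "transforms"))
    if (!is.null(x[[nm]])) x[[nm]] <- unlist(x[[nm]])
  do.call(pipeline_config, x)
}

#' Run the full multimodal association analysis
#'
#' Executes encode -> (variance-normalize, linked decomposition, component
#' rejection) -> CCA -> permutation and bootstrap inference -> optional
#' voxelwise loading maps -> outcome regression, under one master seed.
#' The returned bundle carries a manifest (package version, configuration,
#' derived stage seeds, stage dimensions) sufficient to re-run the analysis.
#'
#' @param inputs list with \code{dataset} (\code{\link{multimodal_dataset}}),
#'   \code{clinical} (\code{\link{clinical_table}}), optionally
#'   \code{outcomes} (data.frame) and \code{icv} (numeric vector used when
#'   \code{include_icv = TRUE}; defaults to the subject mean of the first
#'   volumetric block as a crude total-volume proxy). A \code{"sim_cohort"}
#'   is accepted directly.
#' @param config a \code{\link{pipeline_config}}.
#' @return object of class \code{"neocca_result"}: \code{clinical_matrix},
#'   \code{decomp}, \code{model}, \code{inference}, \code{maps} (or NULL),
#'   \code{outcome_table} (or NULL), \code{manifest}.
#' @export
run_pipeline <- function(inputs, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(inputs, "sim_cohort"))
    inputs <- list(dataset = inputs$dataset, clinical = inputs$clinical,
                   outcomes = inputs$outcomes)
  dataset <- inputs$dataset
  clinical <- inputs$clinical
  outcomes <- inputs$outcomes
  if (is.null(dataset) || is.null(clinical))
    stop2("inputs must provide at least a dataset and a clinical table")
  stage <- "subject filtering"
  res <- tryCatch({
    if (length(config$drop_lesion_ids)) {
      dataset <- drop_subjects(dataset, config$drop_lesion_ids)
      clinical <- drop_subjects(clinical, config$drop_lesion_ids)
      if (!is.null(outcomes))
        outcomes <- drop_subjects(outcomes, config$drop_lesion_ids)
    }
    stage <- "clinical encoding"
    dropped_rare <- character(0)
    if (config$rare_factor_threshold > 0) {
      clinical <- filter_rare(clinical, config$rare_factor_threshold)
      dropped_rare <- attr(clinical, "dropped")
    }
    cm <- encode_clinical(clinical, scale_binary = config$scale_binary)
    if (!is.null(config$transforms))
      cm <- transform_skewed(cm, config$transforms)
    if (config$include_icv) {
      icv <- inputs$icv %||% rowMeans(dataset$blocks[[1]]$data)
      icv <- (icv - mean(icv)) / sd(icv)
      cm$values <- cbind(cm$values, icv = icv)
      cm$meta <- rbind(cm$meta, data.frame(name = "icv", kind = "continuous",
                                           transform = "none", n_imputed = 0L))
    }
    stage <- "linked decomposition"
    kmax <- min(config$max_components, dataset$n - 1L, sum(n_voxels(dataset)) - 1L)
    decomp <- fit_linked(dataset, max_components = kmax,
                         seed = child_seed(config$seed, "decomposition"))
    decomp <- reject_components(decomp, config$reject_threshold)
    if (length(config$remove_pathology_components)) {
      bad <- config$remove_pathology_components
      if (any(bad < 1 | bad > length(decomp$rejected)))
        stop2("remove_pathology_components index outside 1..",
              length(decomp$rejected))
      decomp$rejected[bad] <- TRUE
    }
    yy <- component_features(decomp)
    stage <- "canonical correlation analysis"
    model <- cca_fit(cm, yy)
    stage <- "inference"
    inference <- cca_inference(cm, yy, P = config$perms, B = config$boot,
                               seed = child_seed(config$seed, "inference"),
                               loading_family = config$loading_family,
                               model = model)
    stage <- "voxel maps"
    maps <- NULL
    if (length(config$map_pairs)) {
      maps <- list()
      for (pk in config$map_pairs) {
        lm <- voxel_loadings(dataset, model$V[, pk])
        lm <- fwe_correct(lm, dataset, P = config$map_perms,
                          seed = child_seed(config$seed, paste0("maps", pk)),
                          alpha = config$alpha_maps)
        maps[[paste0("pair", pk)]] <- threshold_maps(lm, config$alpha_maps)
      }
    }
    stage <- "outcome regression"
    outcome_table <- NULL
    if (!is.null(outcomes)) {
      np <- min(config$report_pairs, model$m)
      outcome_table <- outcome_association(model$V[, seq_len(np), drop = FALSE],
                                           outcomes)
      outcome_table <- correct_multiple(outcome_table, alpha = 0.05)
    }
    manifest <- list(
      package = "neocca",
      version = as.character(utils::packageVersion("neocca")),
      config = unclass(config),
      stage_seeds = list(
        decomposition = child_seed(config$seed, "decomposition"),
        inference = child_seed(config$seed, "inference")),
      n_subjects = dataset$n,
      n_clinical = ncol(cm$values),
      n_components_kept = ncol(yy),
      n_components_rejected = sum(decomp$rejected),
      dropped_rare_factors = dropped_rare,
      modalities = names(dataset$blocks))
    structure(list(clinical_matrix = cm, decomp = decomp, model = model,
                   inference = inference, maps = maps,
                   outcome_table = outcome_table, manifest = manifest),
              class = "neocca_result")
  }, error = function(e) {
    stop2("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })
  res
}

#' @export
print.neocca_result <- function(x, ...) {
  cat("Multimodal CCA analysis result\n")
  cat("  subjects:", x$manifest$n_subjects,
      " clinical variables:", x$manifest$n_clinical,
      " imaging components:", x$manifest$n_components_kept, "\n")
  np <- min(5, nrow(x$inference$pairs_table))
  print(round(x$inference$pairs_table[seq_len(np), ], 4), row.names = FALSE)
  if (!is.null(x$outcome_table)) {
    cat("Outcome associations (corrected):\n")
    sig <- x$outcome_table[x$outcome_table$significant, , drop = FALSE]
    if (nrow(sig)) print(sig, row.names = FALSE) else cat("  none\n")
  }
  invisible(x)
}
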