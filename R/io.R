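#' Write a multimodal cohort to standard formats
#'
#' One 4D NIfTI per modality (subjects on the 4th axis, off-mask voxels
#' zero), a 3D NIfTI mask per modality, clinical and outcome tables as TSV
#' (empty cell = missing) with a JSON column-metadata sidecar.
#'
#' @param cohort list with \code{dataset} (\code{\link{multimodal_dataset}})
#'   and optionally \code{clinical} (\code{\link{clinical_table}}) and
#'   \code{outcomes} (data.frame).
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- cohort$dataset
  files <- character(0)
  for (nm in names(ds$blocks)) {
    b <- ds$blocks[[nm]]
    arr <- array(0, c(b$grid_dims, ds$n))
    nvox <- prod(b$grid_dims)
    for (i in seq_len(ds$n))
      arr[(i - 1L) * nvox + b$mask_idx] <- b$data[i, ]
    img <- RNifti::asNifti(arr, pixdim = c(b$voxel_size_mm, 1))
    f <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(img, f, datatype = "double")
    msk <- array(0L, b$grid_dims)
    msk[b$mask_idx] <- 1L
    fm <- file.path(dir, paste0(nm, "_mask.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(msk, pixdim = c(b$voxel_size_mm, 1)), fm)
    files <- c(files, f, fm)
  }
  sid <- ds$subject_ids
  f <- file.path(dir, "subjects.tsv")
  utils::write.table(data.frame(subject_id = sid), f, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  if (!is.null(cohort$clinical)) {
    ct <- cohort$clinical
    df <- cbind(data.frame(subject_id = ct$subject_ids), ct$data)
    f <- file.path(dir, "clinical.tsv")
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    meta <- lapply(ct$meta, function(m) m[c("kind", "unit", "center")])
    fj <- file.path(dir, "clinical_meta.json")
    jsonlite::write_json(meta, fj, auto_unbox = TRUE, pretty = TRUE)
    files <- c(files, f, fj)
  }
  if (!is.null(cohort$outcomes)) {
    df <- cbind(data.frame(subject_id = rownames(cohort$outcomes)),
                cohort$outcomes)
    f <- file.path(dir, "outcomes.tsv")
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    files <- c(files, f)
  }
  invisible(files)
}

#' Read a multimodal cohort written by \code{\link{write_cohort}}
#'
#' Validates geometry (mask voxel count against matrix columns) and aligns
#' clinical/outcome rows to the imaging subject order by explicit subject id,
#' with a message when reordering was needed.
#'
#' @param dir directory containing the files.
#' @param modalities character vector of modality names; by default inferred
#'   from the \code{*_mask.nii.gz} files present.
#' @return list with \code{dataset}, \code{clinical} (or NULL),
#'   \code{outcomes} (or NULL).
#' @export
read_cohort <- function(dir, modalities = NULL) {
  if (is.null(modalities)) {
    mf <- list.files(dir, pattern = "_mask\\.nii\\.gz$")
    modalities <- sub("_mask\\.nii\\.gz$", "", mf)
  }
  if (!length(modalities)) stop2("no modality masks found in ", dir)
  sid <- utils::read.delim(file.path(dir, "subjects.tsv"),
                           stringsAsFactors = FALSE)$subject_id
  blocks <- list()
  for (nm in modalities) {
    arr <- as.array(RNifti::readNifti(file.path(dir, paste0(nm, ".nii.gz"))))
    msk <- as.array(RNifti::readNifti(file.path(dir, paste0(nm, "_mask.nii.gz"))))
    idx <- which(msk > 0)
    d <- dim(arr)
    if (length(d) != 4L) stop2("modality '", nm, "': expected a 4D image")
    if (!identical(dim(msk), d[1:3]))
      stop2("modality '", nm, "': mask grid ", paste(dim(msk), collapse = "x"),
            " does not match image grid ", paste(d[1:3], collapse = "x"))
    n <- d[4]
    nvox <- prod(d[1:3])
    m <- matrix(0, n, length(idx))
    for (i in seq_len(n)) m[i, ] <- arr[(i - 1L) * nvox + idx]
    pd <- attr(RNifti::readNifti(file.path(dir, paste0(nm, ".nii.gz"))),
               "pixdim") %||% c(1, 1, 1)
    blocks[[nm]] <- list(data = m, grid_dims = d[1:3],
                         voxel_size_mm = pd[1:3], mask_idx = idx,
                         kind = "volume")
  }
  ds <- multimodal_dataset(blocks, subject_ids = sid)
  clinical <- NULL
  fc <- file.path(dir, "clinical.tsv")
  if (file.exists(fc)) {
    df <- utils::read.delim(fc, stringsAsFactors = FALSE, na.strings = "")
    df <- align_by_id(df, sid, "clinical table")
    meta <- NULL
    fj <- file.path(dir, "clinical_meta.json")
    if (file.exists(fj)) meta <- jsonlite::read_json(fj, simplifyVector = FALSE)
    clinical <- clinical_table(df[setdiff(names(df), "subject_id")],
                               meta = meta, subject_ids = df$subject_id)
  }
  outcomes <- NULL
  fo <- file.path(dir, "outcomes.tsv")
  if (file.exists(fo)) {
    df <- utils::read.delim(fo, stringsAsFactors = FALSE, na.strings = "")
    df <- align_by_id(df, sid, "outcome table")
    outcomes <- df[setdiff(names(df), "subject_id")]
    rownames(outcomes) <- df$subject_id
  }
  list(dataset = ds, clinical = clinical, outcomes = outcomes)
}

align_by_id <- function(df, sid, label) {
  if (!"subject_id" %in% names(df)) stop2(label, " lacks a subject_id column")
  idx <- match(sid, df$subject_id)
  if (anyNA(idx))
    stop2(label, ": subject id '", sid[which(is.na(idx))[1]],
          "' missing from the table")
  if (!identical(idx, seq_len(nrow(df))))
    message(label, ": rows reordered to match imaging subject order")
  df[idx, , drop = FALSE]
}

#' Write an analysis result bundle
#'
#' Serializes the pair and loading tables, manifest and variates to
#' JSON/TSV, and (when present) the voxelwise statistic maps of each mapped
#' pair as 3D NIfTI volumes (r map, t map, 1 - p_fwe map, thresholded sign
#' mask).
#'
#' @param result a \code{"neocca_result"} from \code{\link{run_pipeline}}.
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
write_bundle <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wj <- function(x, f) {
    jsonlite::write_json(x, file.path(dir, f), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, na = "null")
    files <<- c(files, file.path(dir, f))
  }
  wt <- function(x, f) {
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    files <<- c(files, file.path(dir, f))
  }
  wj(result$manifest, "manifest.json")
  wj(list(r = result$model$r,
          clinical_weights = apply(result$model$a, 2, as.list),
          imaging_weights = apply(result$model$b, 2, as.list),
          x_center = as.list(result$model$x_center),
          y_center = as.list(result$model$y_center),
          sign_convention = "largest-|loading| clinical variable positive"),
     "model.json")
  wt(result$inference$pairs_table, "canonical_pairs.tsv")
  wt(result$inference$loadings_table, "clinical_loadings.tsv")
  wt(data.frame(subject_id = rownames(result$model$U) %||%
                  sprintf("sub-%04d", seq_len(result$model$n)),
                result$model$U, result$model$V, check.names = FALSE),
     "variates.tsv")
  if (!is.null(result$outcome_table)) wt(result$outcome_table, "outcomes.tsv")
  if (!is.null(result$maps)) {
    for (pk in names(result$maps)) {
      lm <- result$maps[[pk]]
      for (nm in names(lm$maps)) {
        m <- lm$maps[[nm]]
        put <- function(vals, suffix) {
          vol <- array(0, m$grid_dims)
          vol[m$mask_idx] <- ifelse(is.na(vals), 0, vals)
          f <- file.path(dir, sprintf("%s_%s_%s.nii.gz", pk, nm, suffix))
          RNifti::writeNifti(RNifti::asNifti(vol,
            pixdim = c(m$voxel_size_mm, 1)), f)
          files <<- c(files, f)
        }
        put(m$r, "r")
        put(m$t, "t")
        if (!is.null(m$p_fwe)) put(1 - m$p_fwe, "1minusp")
        if (!is.null(m$sign_map)) put(m$sign_map, "sigmask")
      }
    }
  }
  invisible(files)
}
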