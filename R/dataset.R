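#' Multimodal imaging dataset
#'
#' Container for aligned per-modality subject-by-voxel matrices with their
#' mask geometry. All blocks must share the subject dimension; the mask index
#' list of each block must match its matrix column count.
#'
#' @param blocks named list; each element a list with components
#'   \code{data} (n x V numeric matrix), \code{grid_dims} (3 positive
#'   integers), \code{voxel_size_mm} (3 positive reals), \code{mask_idx}
#'   (linear voxel indices into the grid, length V) and \code{kind}
#'   (\code{"volume"} or \code{"skeleton"}).
#' @param subject_ids optional character vector of subject identifiers.
#' @return an object of class \code{"multimodal_dataset"}.
#' @export
multimodal_dataset <- function(blocks, subject_ids = NULL) {
  if (is.null(names(blocks)) || any(names(blocks) == ""))
    stop2("blocks must be a named list of modalities")
  ns <- vapply(blocks, function(b) nrow(b$data), integer(1))
  if (length(unique(ns)) != 1L)
    stop2("all modality blocks must share the subject count; got ",
          paste(ns, collapse = ", "))
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if (!all(is.finite(b$data)))
      stop2("non-finite values in block '", nm, "'")
    if (length(b$mask_idx) != ncol(b$data))
      stop2("block '", nm, "': mask has ", length(b$mask_idx),
            " voxels but matrix has ", ncol(b$data), " columns")
    if (length(b$grid_dims) != 3L || any(b$grid_dims < 1))
      stop2("block '", nm, "': grid_dims must be 3 positive integers")
    if (any(b$mask_idx < 1 | b$mask_idx > prod(b$grid_dims)))
      stop2("block '", nm, "': mask indices outside grid")
    b$kind <- match.arg(b$kind %||% "volume", c("volume", "skeleton"))
    blocks[[nm]] <- b
  }
  n <- ns[[1]]
  if (is.null(subject_ids)) subject_ids <- sprintf("sub-%04d", seq_len(n))
  if (length(subject_ids) != n) stop2("subject_ids length must equal n")
  structure(list(blocks = blocks, subject_ids = subject_ids, n = n),
            class = "multimodal_dataset")
}

#' @export
print.multimodal_dataset <- function(x, ...) {
  cat("Multimodal dataset:", x$n, "subjects,", length(x$blocks),
      "modality blocks\n")
  for (nm in names(x$blocks)) {
    b <- x$blocks[[nm]]
    cat(sprintf("  %-12s %6d voxels  grid %s  kind %s\n", nm,
                ncol(b$data), paste(b$grid_dims, collapse = "x"), b$kind))
  }
  invisible(x)
}

#' Number of voxels per modality
#' @param dataset a \code{multimodal_dataset}.
#' @return named integer vector.
#' @export
n_voxels <- function(dataset) {
  vapply(dataset$blocks, function(b) ncol(b$data), integer(1))
}
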