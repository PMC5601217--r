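#' Variance-normalize a modality block
#'
#' Centers each voxel column across subjects and rescales the whole block so
#' its total variance (sum of voxel variances) is 1, putting modalities with
#' different units and smoothness on a common footing before joint
#' decomposition. The scale factor is recorded as attribute \code{"scale"}.
#'
#' @param block n x V numeric matrix.
#' @return normalized matrix with attributes \code{"scale"} (divisor applied)
#'   and \code{"center"} (column means).
#' @export
variance_normalize <- function(block) {
  stopifnot(is.matrix(block), nrow(block) > 1, ncol(block) > 0)
  mu <- colMeans(block)
  b <- sweep(block, 2, mu, "-")
  tot <- sum(b^2) / (nrow(b) - 1)
  if (tot == 0) stop2("block has zero variance; cannot normalize")
  s <- sqrt(tot)
  out <- b / s
  attr(out, "scale") <- s
  attr(out, "center") <- mu
  out
}

# Deflation FastICA (tanh contrast) on pre-whitened K x V data.
# Rows of x are uncorrelated with unit variance across columns.
# Returns list(w = K x K orthogonal unmixing matrix, converged flag).
fastica_deflation <- function(x, max_iterations = 500, tol = 1e-6) {
  k <- nrow(x); nv <- ncol(x)
  w <- matrix(0, k, k)
  converged <- TRUE
  for (cc in seq_len(k)) {
    wv <- rnorm(k)
    if (cc > 1) {
      prev <- w[seq_len(cc - 1), , drop = FALSE]
      wv <- wv - t(prev) %*% (prev %*% wv)
    }
    wv <- wv / sqrt(sum(wv^2))
    ok <- FALSE
    for (it in seq_len(max_iterations)) {
      u <- drop(crossprod(wv, x))          # 1 x V projections
      g <- tanh(u)
      gp <- 1 - g^2
      wnew <- drop(x %*% g) / nv - mean(gp) * wv
      if (cc > 1) {
        prev <- w[seq_len(cc - 1), , drop = FALSE]
        wnew <- wnew - t(prev) %*% (prev %*% wnew)
      }
      nrm <- sqrt(sum(wnew^2))
      if (nrm < 1e-12) { wnew <- rnorm(k); wnew <- wnew / sqrt(sum(wnew^2)) }
      else wnew <- wnew / nrm
      if (abs(abs(sum(wnew * wv)) - 1) < tol) { wv <- wnew; ok <- TRUE; break }
      wv <- wnew
    }
    if (!ok) converged <- FALSE
    w[cc, ] <- wv
  }
  list(w = w, converged = converged)
}

#' Fit a linked multimodal decomposition
#'
#' Reduces the dataset to at most \code{max_components} multimodal
#' components, each a set of per-modality spatial maps tied to a single
#' shared subject course. The estimator is deterministic given the seed:
#' per-block variance normalization, feature-wise concatenation, SVD
#' whitening to the component subspace, then a fixed-point
#' independence-contrast rotation (deflation ICA with a tanh nonlinearity)
#' applied on the spatial side so that component maps are as independent as
#' possible. Subject courses are rescaled to unit variance and components
#' ordered by explained variance; per-modality maps are obtained by
#' regressing each normalized block onto the courses. Component sign is fixed
#' so the largest-magnitude spatial-map entry across modalities is positive.
#'
#' @param dataset a \code{\link{multimodal_dataset}}.
#' @param max_components upper limit on the number of components.
#' @param max_iterations fixed-point iteration cap per component; hitting it
#'   sets \code{converged = FALSE} (with a warning) rather than failing.
#' @param seed integer seed for the rotation initialization.
#' @return object of class \code{"linked_decomp"}: \code{subject_courses}
#'   (n x K, unit variance), \code{spatial_maps} (per modality V_m x K),
#'   \code{modality_weights} (modality x K map norms),
#'   \code{ev_share} (explained-variance share per component),
#'   \code{rejected} (logical K), \code{converged}, \code{n_iterations},
#'   \code{block_scales}, \code{dataset_geometry}.
#' @export
fit_linked <- function(dataset, max_components = 100, max_iterations = 500,
                       seed = 1L) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  n <- dataset$n
  vtot <- sum(n_voxels(dataset))
  if (max_components >= n)
    stop2("max_components must be < n subjects (", n, ")")
  if (max_components >= vtot)
    stop2("max_components must be < total voxel count (", vtot, ")")
  norm_blocks <- lapply(dataset$blocks, function(b) variance_normalize(b$data))
  scales <- vapply(norm_blocks, attr, numeric(1), "scale")
  m <- do.call(cbind, norm_blocks)
  sv <- svd(m, nu = max_components, nv = max_components)
  tol <- 1e-10 * sv$d[1]
  k <- min(max_components, sum(sv$d > tol))
  u <- sv$u[, seq_len(k), drop = FALSE]
  d <- sv$d[seq_len(k)]
  v <- sv$v[, seq_len(k), drop = FALSE]
  # whitened spatial data: rows orthonormal * sqrt(V) -> unit-variance rows
  xw <- sqrt(ncol(m)) * t(v)
  ica <- with_seed(child_seed(seed, "ica-rotation"),
                   fastica_deflation(xw, max_iterations = max_iterations))
  if (!ica$converged)
    warning("independence rotation did not fully converge within ",
            max_iterations, " iterations; returning current estimate")
  s <- ica$w %*% xw                        # K x V independent spatial signals
  # courses: m ~ C %*% s with s s' = V * I  =>  C = m s' / V
  courses <- m %*% t(s) / ncol(m)
  ev <- colSums(courses^2) * ncol(m)       # energy captured per component
  ev_share <- ev / sum(m^2)
  ord <- order(ev_share, decreasing = TRUE)
  courses <- courses[, ord, drop = FALSE]
  ev_share <- ev_share[ord]
  csd <- apply(courses, 2, sd)
  csd[csd == 0] <- 1
  courses <- sweep(courses, 2, csd, "/")
  # per-modality maps by least squares of each normalized block on courses
  g <- solve(crossprod(courses), t(courses))
  maps <- lapply(norm_blocks, function(b) t(g %*% b))
  # sign convention: largest |map| entry across modalities positive
  allmaps <- do.call(rbind, maps)
  for (cc in seq_len(k)) {
    j <- which.max(abs(allmaps[, cc]))
    if (allmaps[j, cc] < 0) {
      courses[, cc] <- -courses[, cc]
      for (nm in names(maps)) maps[[nm]][, cc] <- -maps[[nm]][, cc]
      allmaps[, cc] <- -allmaps[, cc]
    }
  }
  colnames(courses) <- paste0("IC", seq_len(k))
  mw <- do.call(cbind, lapply(maps, function(a)
    sqrt(colSums(a^2 * 1))))                # K x modality map norms
  if (is.null(dim(mw))) mw <- matrix(mw, nrow = k)
  dimnames(mw) <- list(colnames(courses), names(maps))
  geom <- lapply(dataset$blocks, function(b)
    b[c("grid_dims", "voxel_size_mm", "mask_idx", "kind")])
  structure(list(subject_courses = courses, spatial_maps = maps,
                 modality_weights = mw, ev_share = ev_share,
                 rejected = rep(FALSE, k), converged = ica$converged,
                 n_iterations = max_iterations, block_scales = scales,
                 dataset_geometry = geom, seed = as.integer(seed)),
            class = "linked_decomp")
}

#' @export
print.linked_decomp <- function(x, ...) {
  k <- ncol(x$subject_courses)
  cat("Linked decomposition:", k, "components,",
      nrow(x$subject_courses), "subjects\n")
  cat("  explained-variance share (top 5):",
      paste(signif(head(x$ev_share, 5), 3), collapse = ", "), "\n")
  if (any(x$rejected))
    cat("  rejected components:", sum(x$rejected), "\n")
  if (!x$converged) cat("  note: rotation not fully converged\n")
  invisible(x)
}

#' Reject components unsupported by the data
#'
#' Flags components whose explained-variance share falls below the threshold;
#' rejected components are excluded from the exported feature matrix
#' (\code{\link{component_features}}).
#'
#' @param decomp a \code{"linked_decomp"}.
#' @param criterion_threshold minimum explained-variance share (default 1e-4).
#' @return the decomposition with updated \code{rejected} flags.
#' @export
reject_components <- function(decomp, criterion_threshold = 1e-4) {
  stopifnot(inherits(decomp, "linked_decomp"))
  rej <- decomp$ev_share < criterion_threshold
  if (all(rej))
    stop2("threshold ", criterion_threshold, " rejects every component; ",
          "largest explained-variance share is ", signif(max(decomp$ev_share), 3),
          " - lower the threshold")
  decomp$rejected <- rej
  decomp
}

#' Exported imaging feature matrix Y
#'
#' Unit-variance subject courses of the retained components: the imaging
#' block entering canonical correlation analysis.
#'
#' @param decomp a \code{"linked_decomp"}.
#' @return n x K_kept matrix.
#' @export
component_features <- function(decomp) {
  stopifnot(inherits(decomp, "linked_decomp"))
  decomp$subject_courses[, !decomp$rejected, drop = FALSE]
}

#' Reconstruction error of a linked decomposition
#'
#' Relative squared reconstruction error per modality block, computed on the
#' variance-normalized data from the retained components.
#'
#' @param decomp a \code{"linked_decomp"}.
#' @param dataset the \code{\link{multimodal_dataset}} it was fitted to.
#' @return named numeric vector of relative errors in [0, 1].
#' @export
reconstruction_error <- function(decomp, dataset) {
  keep <- !decomp$rejected
  courses <- decomp$subject_courses[, keep, drop = FALSE]
  out <- numeric(0)
  for (nm in names(dataset$blocks)) {
    b <- variance_normalize(dataset$blocks[[nm]]$data)
    fit <- courses %*% t(decomp$spatial_maps[[nm]][, keep, drop = FALSE])
    out[nm] <- sum((b - fit)^2) / sum(b^2)
  }
  out
}
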