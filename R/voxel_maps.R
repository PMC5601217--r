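#' Voxelwise loading maps for a canonical variate
#'
#' Correlates each voxel of every modality block with a canonical imaging
#' variate, projecting the variate back into voxel space. The t-statistic
#' map is derived entrywise as \eqn{t = r \sqrt{(n-2)/(1-r^2)}}.
#' Zero-variance voxels are recorded as NA and counted.
#'
#' @param dataset a \code{\link{multimodal_dataset}}.
#' @param variate numeric n-vector (one canonical variate), non-constant.
#' @return object of class \code{"loading_maps"}: per modality a list with
#'   \code{r}, \code{t}, \code{n_undefined}, and the mask geometry; plus
#'   \code{n} and the variate.
#' @export
voxel_loadings <- function(dataset, variate) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  v <- as.numeric(variate)
  if (length(v) != dataset$n)
    stop2("variate length ", length(v), " but dataset has ", dataset$n,
          " subjects")
  if (sd(v) == 0) stop2("variate is constant")
  n <- dataset$n
  maps <- lapply(dataset$blocks, function(b) {
    sds <- apply(b$data, 2, sd)
    r <- rep(NA_real_, ncol(b$data))
    ok <- sds > 0
    r[ok] <- as.numeric(cor(b$data[, ok, drop = FALSE], v))
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
    tt[abs(r) >= 1 - 1e-15] <- sign(r[abs(r) >= 1 - 1e-15]) * Inf
    list(r = r, t = tt, n_undefined = sum(!ok),
         grid_dims = b$grid_dims, voxel_size_mm = b$voxel_size_mm,
         mask_idx = b$mask_idx, kind = b$kind)
  })
  structure(list(maps = maps, n = n, variate = v), class = "loading_maps")
}

#' @export
print.loading_maps <- function(x, ...) {
  cat("Voxelwise loading maps (", x$n, " subjects )\n", sep = "")
  for (nm in names(x$maps)) {
    m <- x$maps[[nm]]
    cat(sprintf("  %-12s %6d voxels  |r| max %.3f%s%s\n", nm, length(m$r),
                max(abs(m$r), na.rm = TRUE),
                if (m$n_undefined) sprintf("  (%d undefined)", m$n_undefined) else "",
                if (!is.null(m$p_fwe)) "  [FWE-corrected]" else ""))
  }
  invisible(x)
}

#' Family-wise-error correction of loading maps by max-statistic permutation
#'
#' For each permutation the variate's subject rows are shuffled and the
#' maximum absolute voxel statistic across the modality recorded; each
#' voxel's corrected p-value is
#' \eqn{p_{fwe}(v) = (1 + \#\{max^{perm} \ge |t_{obs}(v)|\})/(P+1)}.
#' Modalities are corrected separately by default; \code{joint = TRUE} pools
#' the maximum across all four modalities. Undefined (zero-variance) voxels
#' are excluded from the max statistic.
#'
#' @param maps a \code{"loading_maps"} object, or a dataset (with
#'   \code{variate}) from which observed maps are computed.
#' @param dataset the \code{\link{multimodal_dataset}} the maps came from.
#' @param P number of permutations (>= 100).
#' @param seed integer seed.
#' @param joint correct across modalities jointly.
#' @param alpha reference level used only to warn when \code{1/(P+1)} exceeds
#'   it (no voxel could ever pass).
#' @return the \code{"loading_maps"} object with a \code{p_fwe} vector added
#'   to each modality entry.
#' @export
fwe_correct <- function(maps, dataset, P = 5000, seed = 1L, joint = FALSE,
                        alpha = 0.01) {
  stopifnot(inherits(maps, "loading_maps"),
            inherits(dataset, "multimodal_dataset"))
  if (P < 100) stop2("P must be >= 100")
  if (1 / (P + 1) > alpha)
    warning("P = ", P, " is too small for alpha = ", alpha,
            ": the smallest attainable p is ", signif(1 / (P + 1), 3),
            "; no voxel can pass")
  v <- maps$variate
  n <- length(v)
  zc <- v - mean(v)
  zc <- zc / sqrt(sum(zc^2))
  prep <- lapply(dataset$blocks, function(b) {
    bc <- sweep(b$data, 2, colMeans(b$data), "-")
    nrm <- sqrt(colSums(bc^2))
    ok <- nrm > 0
    bc[, ok] <- sweep(bc[, ok, drop = FALSE], 2, nrm[ok], "/")
    list(bc = bc, ok = ok)
  })
  null_max <- with_seed(child_seed(seed, "fwe"), {
    sapply(seq_len(P), function(b) {
      zp <- zc[sample.int(n)]
      vapply(prep, function(pp) {
        rv <- abs(crossprod(pp$bc[, pp$ok, drop = FALSE], zp))
        max(rv)
      }, numeric(1))
    })
  })
  if (is.null(dim(null_max))) null_max <- matrix(null_max, nrow = 1)
  if (joint) null_max <- matrix(apply(null_max, 2, max),
                                nrow = length(prep), ncol = P, byrow = TRUE)
  for (i in seq_along(maps$maps)) {
    robs <- abs(maps$maps[[i]]$r)
    nm <- null_max[i, ]
    pf <- rep(NA_real_, length(robs))
    okv <- !is.na(robs)
    pf[okv] <- vapply(robs[okv], function(x) (1 + sum(nm >= x)) / (P + 1),
                      numeric(1))
    maps$maps[[i]]$p_fwe <- pf
    maps$maps[[i]]$P <- as.integer(P)
  }
  maps$joint <- joint
  maps
}

#' Threshold corrected loading maps
#'
#' @param maps a FWE-corrected \code{"loading_maps"} object.
#' @param alpha significance level (default 0.01).
#' @return the object with, per modality, \code{sig_mask} (logical: p_fwe
#'   <= alpha) and \code{sign_map} (+1/-1/0 from r, separating positive and
#'   negative associations for display).
#' @export
threshold_maps <- function(maps, alpha = 0.01) {
  stopifnot(inherits(maps, "loading_maps"))
  for (i in seq_along(maps$maps)) {
    m <- maps$maps[[i]]
    if (is.null(m$p_fwe)) stop2("run fwe_correct() before thresholding")
    sig <- !is.na(m$p_fwe) & m$p_fwe <= alpha
    maps$maps[[i]]$sig_mask <- sig
    maps$maps[[i]]$sign_map <- ifelse(sig, sign(m$r), 0)
  }
  maps$alpha <- alpha
  maps
}
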