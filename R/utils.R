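#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor sd rnorm qnorm runif var median pf p.adjust quantile
#' @importFrom utils head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' Derive a reproducible child seed for a named pipeline stage
#'
#' A single user-facing seed is expanded into per-stage seeds so that toggling
#' one stage of the pipeline does not perturb the random stream of another.
#' The stage name is hashed (polynomial rolling hash over UTF-8 code points)
#' and folded into the parent seed modulo 2^31 - 1.
#'
#' @param seed integer parent seed.
#' @param stage character stage label.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 131 + cp) %% m
  as.integer((as.numeric(seed) %% m + h) %% m)
}

# Run `expr` under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# FWHM (mm) -> Gaussian sigma (mm)
fwhm_to_sigma <- function(fwhm) fwhm / sqrt(8 * log(2))

# Separable 3D Gaussian smoothing of an array; sigma_vox per axis (voxels).
# Kernel truncated at 3 sigma. sigma_vox entries of 0 skip that axis.
smooth_gaussian_3d <- function(arr, sigma_vox) {
  stopifnot(length(dim(arr)) == 3L, length(sigma_vox) == 3L)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    rad <- max(1L, ceiling(3 * s))
    k <- exp(-((-rad:rad)^2) / (2 * s^2))
    k <- k / sum(k)
    arr <- convolve_axis(arr, k, ax)
  }
  arr
}

# 1D convolution along one axis of a 3D array, zero-padded boundaries.
convolve_axis <- function(arr, k, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  x <- aperm(arr, perm)
  dm <- dim(x)
  m <- matrix(x, nrow = dm[1])
  rad <- (length(k) - 1L) %/% 2L
  out <- matrix(0, nrow = dm[1], ncol = ncol(m))
  for (j in seq_along(k)) {
    off <- j - rad - 1L
    src <- seq_len(dm[1]) + off
    ok <- src >= 1L & src <= dm[1]
    out[ok, ] <- out[ok, ] + k[j] * m[src[ok], ]
  }
  x <- array(out, dm)
  aperm(x, order(perm))
}

# Column-standardize a matrix exactly (sample sd); errors on zero variance.
standardize_columns <- function(m, what = "matrix") {
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  if (any(sdv == 0))
    stop2("zero-variance column in ", what, ": ",
          paste(which(sdv == 0), collapse = ", "))
  sweep(sweep(m, 2, mu, "-"), 2, sdv, "/")
}
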