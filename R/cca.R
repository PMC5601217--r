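#' Canonical correlation analysis between clinical and imaging blocks
#'
#' Fits CCA between an encoded clinical matrix \eqn{X} (n x p) and an imaging
#' feature matrix \eqn{Y} (n x K): paired linear combinations
#' \eqn{U = X_c a}, \eqn{V = Y_c b} maximizing \eqn{cor(U_i, V_i)}, each
#' successive pair uncorrelated with the preceding ones. The solution is
#' computed in closed form from the singular value decomposition of the
#' whitened cross-covariance, which is numerically stable and deterministic.
#' The sign of each pair is fixed so the clinical variable with the largest
#' absolute loading has a positive loading.
#'
#' @param X clinical block: a \code{"clinical_matrix"} or numeric matrix.
#' @param Y imaging block: a \code{"linked_decomp"} (its retained subject
#'   courses are used) or numeric matrix.
#' @param m number of canonical pairs to retain, or \code{"max"} (default)
#'   for \code{min(rank X, rank Y, n - 1)}.
#' @param ridge nonnegative ridge penalty added to each block's covariance
#'   (default 0 = exact solve; required when a block is rank deficient).
#' @return object of class \code{"cca"}: weights \code{a} (p x m) and
#'   \code{b} (K x m) scaled for unit-variance variates, canonical
#'   correlations \code{r}, variates \code{U}, \code{V}, stored column means
#'   \code{x_center}, \code{y_center}, dimensions and variable names.
#' @seealso \code{\link{cca_loadings}}, \code{\link{perm_test_pairs}},
#'   \code{\link{bootstrap_cca}}
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200), 50, 4)
#' Y <- cbind(X[, 1] + rnorm(50, sd = 0.5), matrix(rnorm(150), 50, 3))
#' fit <- cca(X, Y)
#' fit$r
#' @export
cca <- function(X, Y, m = "max", ridge = 0) {
  xm <- as_block(X, "X")
  ym <- as_block(Y, "Y")
  if (nrow(xm) != nrow(ym))
    stop2("X has ", nrow(xm), " rows but Y has ", nrow(ym))
  n <- nrow(xm)
  if (n < 3) stop2("need at least 3 subjects")
  xc <- colMeans(xm); yc <- colMeans(ym)
  cx <- sweep(xm, 2, xc, "-")
  cy <- sweep(ym, 2, yc, "-")
  wx <- whiten_block(cx, ridge, "X")
  wy <- whiten_block(cy, ridge, "Y")
  mm <- crossprod(wx$u, wy$u)
  sv <- svd(mm)
  mmax <- min(wx$rank, wy$rank, n - 1L)
  nm <- if (identical(m, "max")) mmax else min(as.integer(m), mmax)
  r <- pmin(pmax(sv$d[seq_len(nm)], 0), 1)
  a <- wx$back %*% sv$u[, seq_len(nm), drop = FALSE] * sqrt(n - 1)
  b <- wy$back %*% sv$v[, seq_len(nm), drop = FALSE] * sqrt(n - 1)
  u <- cx %*% a
  v <- cy %*% b
  # sign convention: largest-|loading| clinical variable loads positively
  lx <- suppressWarnings(cor(xm, u))
  for (i in seq_len(nm)) {
    j <- which.max(abs(lx[, i]))
    if (!is.na(lx[j, i]) && lx[j, i] < 0) {
      a[, i] <- -a[, i]; b[, i] <- -b[, i]
      u[, i] <- -u[, i]; v[, i] <- -v[, i]
    }
  }
  xn <- colnames(xm) %||% paste0("x", seq_len(ncol(xm)))
  yn <- colnames(ym) %||% paste0("y", seq_len(ncol(ym)))
  dimnames(a) <- list(xn, paste0("pair", seq_len(nm)))
  dimnames(b) <- list(yn, paste0("pair", seq_len(nm)))
  colnames(u) <- colnames(v) <- paste0("pair", seq_len(nm))
  structure(list(a = a, b = b, r = r, U = u, V = v, m = nm, n = n,
                 x_center = xc, y_center = yc, x_names = xn, y_names = yn,
                 ridge = ridge),
            class = "cca")
}

as_block <- function(x, label) {
  if (inherits(x, "clinical_matrix")) return(x$values)
  if (inherits(x, "linked_decomp")) return(component_features(x))
  if (is.data.frame(x)) return(as.matrix(x))
  if (!is.matrix(x)) stop2(label, " must be a matrix or a known block object")
  x
}

# Whiten a centered block; returns orthonormal basis u (n x rank) such that
# columns have unit norm, plus the back-transform from whitened coordinates
# to variable weights. With ridge > 0 the covariance is inflated by
# ridge * I before whitening (and rank deficiency is tolerated).
whiten_block <- function(cx, ridge, label) {
  n <- nrow(cx)
  sv <- svd(cx)
  tol <- 1e-10 * max(sv$d, 1e-300)
  rank <- sum(sv$d > tol)
  if (rank < ncol(cx) && ridge <= 0)
    stop2("block ", label, " is rank deficient (rank ", rank, " < ",
          ncol(cx), " columns); enable ridge regularization or drop ",
          "collinear columns")
  if (ridge > 0) {
    d2 <- sqrt(sv$d^2 + (n - 1) * ridge)
    u <- cx %*% sv$v %*% diag(1 / d2, length(d2))
    back <- sv$v %*% diag(1 / d2, length(d2))
    rank <- ncol(cx)
  } else {
    u <- sv$u[, seq_len(rank), drop = FALSE]
    back <- sv$v[, seq_len(rank), drop = FALSE] %*%
      diag(1 / sv$d[seq_len(rank)], rank)
  }
  list(u = u, back = back, rank = rank)
}

#' @export
print.cca <- function(x, digits = 3, ...) {
  cat("Canonical correlation analysis:", x$n, "subjects,",
      length(x$x_names), "clinical x", length(x$y_names),
      "imaging variables,", x$m, "pairs\n")
  cat("  canonical correlations:",
      paste(round(x$r, digits), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cca <- function(object, n_pairs = min(object$m, 10), ...) {
  out <- list(r = object$r[seq_len(n_pairs)], m = object$m, n = object$n,
              loadings = cca_loadings(object), n_pairs = n_pairs)
  class(out) <- "summary.cca"
  out
}

#' @export
print.summary.cca <- function(x, digits = 3, ...) {
  cat("Canonical pairs (first", x$n_pairs, "of", x$m, "):\n")
  print(round(data.frame(pair = seq_len(x$n_pairs), r = x$r), digits),
        row.names = FALSE)
  top <- apply(abs(x$loadings$clinical), 2, which.max)[seq_len(x$n_pairs)]
  cat("top clinical loading per pair:",
      paste(rownames(x$loadings$clinical)[top], collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.cca <- function(object, side = c("both", "clinical", "imaging"), ...) {
  side <- match.arg(side)
  switch(side, both = list(a = object$a, b = object$b),
         clinical = object$a, imaging = object$b)
}

#' Canonical variates for (new) data
#'
#' Applies the fitted weights to data centered with the training means:
#' \code{U = (X - x_center) a}, \code{V = (Y - y_center) b}. With no new data
#' the stored training variates are returned.
#'
#' @param object a fitted \code{"cca"}.
#' @param X,Y optional new clinical / imaging blocks with the training
#'   columns.
#' @param ... unused.
#' @return list with matrices \code{U} and/or \code{V}.
#' @export
predict.cca <- function(object, X = NULL, Y = NULL, ...) {
  if (is.null(X) && is.null(Y)) return(list(U = object$U, V = object$V))
  out <- list()
  if (!is.null(X)) {
    xm <- as_block(X, "X")
    if (ncol(xm) != length(object$x_center))
      stop2("X has ", ncol(xm), " columns; model expects ",
            length(object$x_center))
    if (!is.null(colnames(xm)) && !identical(colnames(xm), object$x_names))
      stop2("X column names do not match the training block")
    out$U <- sweep(xm, 2, object$x_center, "-") %*% object$a
  }
  if (!is.null(Y)) {
    ym <- as_block(Y, "Y")
    if (ncol(ym) != length(object$y_center))
      stop2("Y has ", ncol(ym), " columns; model expects ",
            length(object$y_center))
    if (!is.null(colnames(ym)) && !identical(colnames(ym), object$y_names))
      stop2("Y column names do not match the training block")
    out$V <- sweep(ym, 2, object$y_center, "-") %*% object$b
  }
  out
}

#' Canonical loadings
#'
#' Correlation of each original variable with the canonical variate of its
#' own block. Loadings measure the marginal association of a variable with a
#' pair; they can disagree in sign with the canonical weights, which measure
#' unique contributions conditional on the other variables.
#'
#' @param model a fitted \code{"cca"}.
#' @param X,Y optional data blocks (default: training data variates are
#'   correlated with the training blocks reconstructed from the stored
#'   variates; pass blocks explicitly to compute loadings on other data).
#' @return list of class \code{"cca_loadings"} with matrices
#'   \code{clinical} (p x m) and \code{imaging} (K x m); zero-variance
#'   variables yield NA with a warning.
#' @export
cca_loadings <- function(model, X = NULL, Y = NULL) {
  stopifnot(inherits(model, "cca"))
  if (is.null(X)) X <- attr(model, "train_x")
  if (is.null(Y)) Y <- attr(model, "train_y")
  if (is.null(X) || is.null(Y))
    stop2("training blocks not stored; pass X and Y explicitly")
  xm <- as_block(X, "X"); ym <- as_block(Y, "Y")
  pr <- predict(model, X = xm, Y = ym)
  lx <- safe_cor(xm, pr$U, "clinical")
  ly <- safe_cor(ym, pr$V, "imaging")
  rownames(lx) <- model$x_names
  rownames(ly) <- model$y_names
  structure(list(clinical = lx, imaging = ly), class = "cca_loadings")
}

safe_cor <- function(block, variates, label) {
  sds <- apply(block, 2, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance ", label,
            " variable(s); loadings recorded as NA")
    out <- matrix(NA_real_, ncol(block), ncol(variates))
    ok <- sds > 0
    out[ok, ] <- cor(block[, ok, drop = FALSE], variates)
    return(out)
  }
  cor(block, variates)
}

#' Fit CCA retaining the training blocks
#'
#' Convenience wrapper around \code{\link{cca}} that stores the training
#' blocks on the returned object so \code{\link{cca_loadings}} and the
#' resampling routines can be called without re-supplying the data.
#'
#' @inheritParams cca
#' @return a \code{"cca"} with attributes \code{train_x}, \code{train_y}.
#' @export
cca_fit <- function(X, Y, m = "max", ridge = 0) {
  model <- cca(X, Y, m = m, ridge = ridge)
  attr(model, "train_x") <- as_block(X, "X")
  attr(model, "train_y") <- as_block(Y, "Y")
  model
}

#' @export
plot.cca <- function(x, pair = 1L, ...) {
  if (pair > x$m) stop2("pair ", pair, " not available (m = ", x$m, ")")
  graphics::plot(x$U[, pair], x$V[, pair],
                 xlab = sprintf("clinical variate U%d", pair),
                 ylab = sprintf("imaging variate V%d", pair),
                 main = sprintf("Canonical pair %d (r = %.3f)", pair,
                                x$r[pair]), ...)
  graphics::abline(stats::lm(x$V[, pair] ~ x$U[, pair]), col = "red3")
  invisible(x)
}
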