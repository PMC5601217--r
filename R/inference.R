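#' Permutation test for canonical pairs (max-statistic null)
#'
#' Assesses the canonical pairs sequentially: the rows of the clinical block
#' are randomly reordered against the imaging block \code{P} times, the CCA
#' refitted, and the maximum canonical correlation of each permuted fit
#' recorded. Pair \eqn{k} receives
#' \eqn{p_k = (1 + \#\{max_r^{perm} \ge r_k\}) / (P + 1)}, so p-values are
#' strictly positive, valid, and non-decreasing across pairs. An alternative
#' step-down variant that residualizes both blocks on the preceding pairs
#' before permuting is available via \code{method = "residual"}.
#'
#' @param X clinical block (matrix or \code{"clinical_matrix"}).
#' @param Y imaging block (matrix or \code{"linked_decomp"}).
#' @param P number of permutations (>= 1).
#' @param seed integer seed.
#' @param method \code{"maxstat"} (default) or \code{"residual"}.
#' @param model optional pre-fitted \code{"cca"} on (X, Y).
#' @return object of class \code{"cca_perm"}: \code{p} (per pair),
#'   \code{r_obs}, \code{null_max} (the P permuted maxima, maxstat method),
#'   \code{P}, \code{method}, \code{seed}.
#' @export
perm_test_pairs <- function(X, Y, P = 10000, seed = 1L,
                            method = c("maxstat", "residual"), model = NULL) {
  method <- match.arg(method)
  if (P < 1) stop2("P must be >= 1")
  xm <- as_block(X, "X"); ym <- as_block(Y, "Y")
  n <- nrow(xm)
  if (n < 8) stop2("n = ", n, " is too small for a meaningful permutation test")
  if (is.null(model)) model <- cca(xm, ym)
  r_obs <- model$r
  if (method == "maxstat") {
    cx <- sweep(xm, 2, colMeans(xm), "-")
    cy <- sweep(ym, 2, colMeans(ym), "-")
    ux <- whiten_block(cx, 0, "X")$u
    uy <- whiten_block(cy, 0, "Y")$u
    null_max <- with_seed(child_seed(seed, "perm-pairs"), {
      vapply(seq_len(P), function(b) {
        idx <- sample.int(n)
        # ux columns are centered, and a row permutation preserves the
        # column means, so no re-centering is needed
        svd(crossprod(ux[idx, , drop = FALSE], uy), nu = 0, nv = 0)$d[1]
      }, numeric(1))
    })
    p <- vapply(r_obs, function(rk) (1 + sum(null_max >= rk)) / (P + 1),
                numeric(1))
  } else {
    null_max <- NULL
    p <- numeric(model$m)
    rx <- xm; ry <- ym
    for (k in seq_len(model$m)) {
      if (k > 1) {
        rx <- resid_on(rx, model$U[, seq_len(k - 1), drop = FALSE])
        ry <- resid_on(ry, model$V[, seq_len(k - 1), drop = FALSE])
      }
      nullk <- with_seed(child_seed(seed, paste0("perm-pairs-step", k)), {
        vapply(seq_len(P), function(b) {
          idx <- sample.int(n)
          cca(rx[idx, , drop = FALSE], ry, ridge = 1e-8)$r[1]
        }, numeric(1))
      })
      p[k] <- (1 + sum(nullk >= r_obs[k])) / (P + 1)
    }
    p <- cummax(p)
  }
  structure(list(p = p, r_obs = r_obs, null_max = null_max, P = as.integer(P),
                 method = method, seed = as.integer(seed)),
            class = "cca_perm")
}

resid_on <- function(mat, basis) {
  q <- qr.Q(qr(cbind(1, basis)))
  mat - q %*% crossprod(q, mat)
}

#' @export
print.cca_perm <- function(x, ...) {
  cat("Permutation test (", x$P, " permutations, ", x$method,
      " null)\n", sep = "")
  print(round(data.frame(pair = seq_along(x$p), r = x$r_obs, p = x$p), 4),
        row.names = FALSE)
  invisible(x)
}

#' Permutation test for canonical loadings
#'
#' Builds a null distribution for the loadings of one block by permuting its
#' subject rows against the canonical variates. By default the null statistic
#' is the maximum |r| across the block's variables within each pair
#' (family-wise control over the block); \code{family = "per_variable"}
#' switches to per-variable nulls.
#'
#' @param block the variable block whose loadings are tested (n x p matrix or
#'   \code{"clinical_matrix"}).
#' @param variates n x m matrix of canonical variates for the other role of
#'   the loadings (i.e. the block's own-side variates).
#' @param P permutations (>= 1).
#' @param seed integer seed.
#' @param family \code{"max"} (default) or \code{"per_variable"}.
#' @return list of class \code{"loading_perm"}: \code{loadings} (observed),
#'   \code{p} (variables x pairs), \code{P}, \code{family}, \code{seed}.
#' @export
perm_test_loadings <- function(block, variates, P = 10000, seed = 1L,
                               family = c("max", "per_variable")) {
  family <- match.arg(family)
  if (P < 1) stop2("P must be >= 1")
  bm <- as_block(block, "block")
  v <- as.matrix(variates)
  n <- nrow(bm)
  if (n < 8) stop2("n = ", n, " is too small for a meaningful permutation test")
  obs <- abs(cor(bm, v))
  counts <- matrix(0, nrow(obs), ncol(obs))
  with_seed(child_seed(seed, "perm-loadings"), {
    for (b in seq_len(P)) {
      rp <- abs(cor(bm[sample.int(n), , drop = FALSE], v))
      if (family == "max") {
        mx <- apply(rp, 2, max)
        counts <- counts + (matrix(mx, nrow(obs), ncol(obs), byrow = TRUE) >= obs)
      } else {
        counts <- counts + (rp >= obs)
      }
    }
  })
  p <- (1 + counts) / (P + 1)
  dimnames(p) <- list(colnames(bm), colnames(v))
  lo <- cor(bm, v)
  dimnames(lo) <- dimnames(p)
  structure(list(loadings = lo, p = p, P = as.integer(P), family = family,
                 seed = as.integer(seed)),
            class = "loading_perm")
}

#' Bootstrap confidence intervals for a CCA model
#'
#' Resamples subjects with replacement jointly across both blocks, refits the
#' CCA model on each replicate, aligns the replicate pairs to the original
#' model (greedy matching on the absolute correlation between replicate and
#' original variates over the resampled subjects; sign fixed to positive
#' correlation with the original variate) and forms percentile intervals for
#' the canonical correlations, weights and loadings. Replicates that lose
#' rank (degenerate resamples) are dropped and counted; more than 10\%
#' dropped aborts.
#'
#' @param X,Y data blocks.
#' @param B bootstrap replicates (>= 100 for interval output).
#' @param level confidence level in (0.5, 1).
#' @param seed integer seed.
#' @param model optional pre-fitted \code{"cca"}.
#' @return object of class \code{"cca_boot"}: \code{r_ci} (m x 2),
#'   \code{a_ci}, \code{b_ci}, \code{clinical_loading_ci},
#'   \code{imaging_loading_ci} (arrays var x pair x 2), \code{r_boot}
#'   (replicate draws), diagnostics \code{frac_reordered},
#'   \code{frac_flipped}, \code{n_dropped}, \code{B}, \code{level},
#'   \code{seed}.
#' @export
bootstrap_cca <- function(X, Y, B = 10000, level = 0.95, seed = 1L,
                          model = NULL) {
  if (B < 100) stop2("B must be >= 100 for interval output")
  if (level <= 0.5 || level >= 1) stop2("level must be in (0.5, 1)")
  xm <- as_block(X, "X"); ym <- as_block(Y, "Y")
  n <- nrow(xm)
  if (is.null(model)) model <- cca(xm, ym)
  m <- model$m
  p <- ncol(xm); k <- ncol(ym)
  r_b <- matrix(NA_real_, B, m)
  a_b <- array(NA_real_, c(p, m, B))
  b_b <- array(NA_real_, c(k, m, B))
  lx_b <- array(NA_real_, c(p, m, B))
  ly_b <- array(NA_real_, c(k, m, B))
  reordered <- flipped <- logical(B)
  dropped <- logical(B)
  with_seed(child_seed(seed, "bootstrap"), {
    for (bb in seq_len(B)) {
      idx <- sample.int(n, replace = TRUE)
      xb <- xm[idx, , drop = FALSE]; yb <- ym[idx, , drop = FALSE]
      fit <- tryCatch(cca(xb, yb, m = m), error = function(e) NULL)
      if (is.null(fit) || fit$m < m) { dropped[bb] <- TRUE; next }
      # align to original pairs via variate correlations on the resample
      uo <- sweep(xm[idx, , drop = FALSE], 2, model$x_center, "-") %*% model$a
      cc <- suppressWarnings(cor(fit$U, uo))
      if (anyNA(cc)) { dropped[bb] <- TRUE; next }
      ord <- integer(m); used <- logical(m)
      for (i in seq_len(m)) {
        cand <- abs(cc[, i]); cand[used] <- -Inf
        ord[i] <- which.max(cand); used[ord[i]] <- TRUE
      }
      sgn <- sign(cc[cbind(ord, seq_len(m))])
      sgn[sgn == 0] <- 1
      reordered[bb] <- !identical(ord, seq_len(m))
      flipped[bb] <- any(sgn < 0)
      r_b[bb, ] <- fit$r[ord]
      a_b[, , bb] <- sweep(fit$a[, ord, drop = FALSE], 2, sgn, "*")
      b_b[, , bb] <- sweep(fit$b[, ord, drop = FALSE], 2, sgn, "*")
      ub <- sweep(fit$U[, ord, drop = FALSE], 2, sgn, "*")
      vb <- sweep(fit$V[, ord, drop = FALSE], 2, sgn, "*")
      lx_b[, , bb] <- suppressWarnings(cor(xb, ub))
      ly_b[, , bb] <- suppressWarnings(cor(yb, vb))
    }
  })
  n_dropped <- sum(dropped)
  if (n_dropped > 0.10 * B)
    stop2(n_dropped, " of ", B, " bootstrap replicates were degenerate ",
          "(rank loss); the data are too small or collinear for this model")
  keep <- !dropped
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qci <- function(x) quantile(x, probs, na.rm = TRUE, names = FALSE)
  r_ci <- t(apply(r_b[keep, , drop = FALSE], 2, qci))
  ci_arr <- function(arr) {
    out <- array(NA_real_, c(dim(arr)[1], m, 2))
    for (i in seq_len(dim(arr)[1])) for (j in seq_len(m))
      out[i, j, ] <- qci(arr[i, j, keep])
    out
  }
  structure(list(r_ci = r_ci, a_ci = ci_arr(a_b), b_ci = ci_arr(b_b),
                 clinical_loading_ci = ci_arr(lx_b),
                 imaging_loading_ci = ci_arr(ly_b),
                 r_boot = r_b[keep, , drop = FALSE],
                 frac_reordered = mean(reordered[keep]),
                 frac_flipped = mean(flipped[keep]),
                 n_dropped = n_dropped, B = as.integer(B), level = level,
                 seed = as.integer(seed)),
            class = "cca_boot")
}

#' @export
print.cca_boot <- function(x, ...) {
  cat("Bootstrap (", x$B, " replicates, ", 100 * x$level, "% percentile ",
      "intervals)\n", sep = "")
  df <- data.frame(pair = seq_len(nrow(x$r_ci)),
                   lower = round(x$r_ci[, 1], 3),
                   upper = round(x$r_ci[, 2], 3))
  print(df, row.names = FALSE)
  cat(sprintf("  alignment: %.1f%% reordered, %.1f%% sign-flipped, %d dropped\n",
              100 * x$frac_reordered, 100 * x$frac_flipped, x$n_dropped))
  invisible(x)
}

#' Full inference report for a CCA model
#'
#' Bundles the pair-level permutation test, loading permutation tests for
#' both blocks, and bootstrap confidence intervals into per-pair and
#' per-variable tables.
#'
#' @param X,Y data blocks.
#' @param P permutations for significance tests.
#' @param B bootstrap replicates.
#' @param level CI level.
#' @param seed integer seed (per-task child seeds are derived from it).
#' @param loading_family multiplicity handling for loading tests.
#' @param model optional pre-fitted model.
#' @return object of class \code{"cca_inference"} with elements
#'   \code{model}, \code{perm}, \code{boot}, \code{clinical_loadings},
#'   \code{imaging_loadings}, \code{pairs_table} (pair, r, CI, p) and
#'   \code{loadings_table} (variable, pair, weight + CI, loading + CI, p).
#' @export
cca_inference <- function(X, Y, P = 10000, B = 10000, level = 0.95,
                          seed = 1L, loading_family = c("max", "per_variable"),
                          model = NULL) {
  loading_family <- match.arg(loading_family)
  xm <- as_block(X, "X"); ym <- as_block(Y, "Y")
  if (is.null(model)) model <- cca(xm, ym)
  perm <- perm_test_pairs(xm, ym, P = P, seed = child_seed(seed, "pairs"),
                          model = model)
  lp_x <- perm_test_loadings(xm, model$U, P = P,
                             seed = child_seed(seed, "load-x"),
                             family = loading_family)
  lp_y <- perm_test_loadings(ym, model$V, P = P,
                             seed = child_seed(seed, "load-y"),
                             family = loading_family)
  boot <- bootstrap_cca(xm, ym, B = B, level = level,
                        seed = child_seed(seed, "boot"), model = model)
  pairs_table <- data.frame(pair = seq_len(model$m), r = model$r,
                            ci_lower = boot$r_ci[, 1],
                            ci_upper = boot$r_ci[, 2], p = perm$p)
  lt <- do.call(rbind, lapply(seq_len(model$m), function(i) {
    data.frame(variable = model$x_names, pair = i,
               weight = model$a[, i],
               weight_lower = boot$a_ci[, i, 1],
               weight_upper = boot$a_ci[, i, 2],
               loading = lp_x$loadings[, i],
               loading_lower = boot$clinical_loading_ci[, i, 1],
               loading_upper = boot$clinical_loading_ci[, i, 2],
               p = lp_x$p[, i], row.names = NULL)
  }))
  structure(list(model = model, perm = perm, boot = boot,
                 clinical_loadings = lp_x, imaging_loadings = lp_y,
                 pairs_table = pairs_table, loadings_table = lt,
                 seed = as.integer(seed)),
            class = "cca_inference")
}

#' @export
print.cca_inference <- function(x, ...) {
  cat("CCA inference report\n")
  print(round(x$pairs_table, 4), row.names = FALSE)
  invisible(x)
}
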