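#' Linear regression of an outcome score on a canonical variate
#'
#' Complete-case simple linear regression of the score on the variate.
#' The slope F statistic is computed in the conventional closed form
#' \eqn{F = (n-2) R^2 / (1 - R^2)} with denominator degrees of freedom
#' \eqn{n-2}; because published tables sometimes print the denominator df as
#' \eqn{n-1}, the p-value under that df convention is stored alongside the
#' conventional one, clearly labelled.
#'
#' @param variate numeric n-vector.
#' @param scores numeric n-vector with NA for missing outcomes.
#' @return list of class \code{"outcome_fit"}: \code{slope},
#'   \code{intercept}, \code{r2}, \code{F}, \code{p} (df (1, n-2)),
#'   \code{p_df_n1} (same F evaluated against df (1, n-1)), \code{df2},
#'   \code{df2_printed}, \code{n_used}, \code{n_missing}.
#' @export
regress_outcome <- function(variate, scores) {
  v <- as.numeric(variate); s <- as.numeric(scores)
  if (length(v) != length(s))
    stop2("variate and scores differ in length (", length(v), " vs ",
          length(s), ")")
  ok <- !is.na(v) & !is.na(s)
  n <- sum(ok)
  if (n < 3) stop2("need at least 3 complete (variate, score) pairs; have ", n)
  v <- v[ok]; s <- s[ok]
  if (sd(v) == 0) stop2("variate has zero variance on complete cases")
  if (sd(s) == 0) stop2("scores have zero variance on complete cases")
  r <- cor(v, s)
  r2 <- r^2
  slope <- r * sd(s) / sd(v)
  intercept <- mean(s) - slope * mean(v)
  if (r2 >= 1 - 1e-15) {
    f <- Inf
    p <- .Machine$double.xmin
    p1 <- .Machine$double.xmin
  } else {
    f <- (n - 2) * r2 / (1 - r2)
    p <- pf(f, 1, n - 2, lower.tail = FALSE)
    p1 <- pf(f, 1, n - 1, lower.tail = FALSE)
  }
  structure(list(slope = slope, intercept = intercept, r2 = r2, F = f,
                 p = p, p_df_n1 = p1, df2 = n - 2L, df2_printed = n - 1L,
                 n_used = n, n_missing = sum(!ok)),
            class = "outcome_fit")
}

#' @export
print.outcome_fit <- function(x, ...) {
  cat(sprintf("Outcome regression: slope %.3f, F(1,%d) = %.3f, p = %.4g (n = %d)\n",
              x$slope, x$df2, x$F, x$p, x$n_used))
  invisible(x)
}

#' Regress every outcome on every canonical variate
#'
#' @param variates n x m matrix of imaging variates.
#' @param outcomes data.frame of outcome scores (NA = missing).
#' @return data.frame of class \code{"outcome_table"}: variate, outcome,
#'   slope, F, p, p_df_n1, n_used.
#' @export
outcome_association <- function(variates, outcomes) {
  v <- as.matrix(variates)
  rows <- list()
  for (i in seq_len(ncol(v))) for (nm in names(outcomes)) {
    fit <- regress_outcome(v[, i], outcomes[[nm]])
    rows[[length(rows) + 1L]] <-
      data.frame(variate = i, outcome = nm, slope = fit$slope, F = fit$F,
                 p = fit$p, p_df_n1 = fit$p_df_n1, n_used = fit$n_used)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("outcome_table", "data.frame")
  out
}

#' Multiple-comparison correction over the variate-by-outcome grid
#'
#' Default Bonferroni over all tested cells; Holm and Benjamini-Hochberg
#' available. Flags tests significant at \code{alpha} after correction and
#' reports the Bonferroni-adjusted per-test threshold.
#'
#' @param tab an \code{"outcome_table"} (or any data.frame with a \code{p}
#'   column), or a numeric p-value matrix.
#' @param method \code{"bonferroni"} (default), \code{"holm"} or \code{"BH"}.
#' @param alpha family-wise (or FDR) level.
#' @return the table with columns \code{p_adj} and \code{significant} added
#'   (attribute \code{"threshold"} holds the Bonferroni per-test cutoff);
#'   for matrix input, a logical matrix of flags with the same attribute.
#' @export
correct_multiple <- function(tab, method = c("bonferroni", "holm", "BH"),
                             alpha = 0.05) {
  method <- match.arg(method)
  if (is.matrix(tab)) {
    padj <- matrix(p.adjust(tab, method = method), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
    flags <- padj <= alpha
    attr(flags, "threshold") <- alpha / length(tab)
    return(flags)
  }
  stopifnot("p" %in% names(tab))
  tab$p_adj <- p.adjust(tab$p, method = method)
  tab$significant <- tab$p_adj <= alpha
  attr(tab, "threshold") <- alpha / nrow(tab)
  attr(tab, "method") <- method
  tab
}
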