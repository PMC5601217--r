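#' Raw clinical table
#'
#' Holds per-subject clinical variables before numeric encoding. Binary
#' variables may take only 0, 1 or missing; all variables share the subject
#' dimension.
#'
#' @param data data.frame of clinical values (NA = missing).
#' @param meta optional named list of per-variable metadata; each entry may
#'   carry \code{kind} ("continuous"/"binary"), \code{unit} and \code{center}
#'   ("median"/"mean", the central value the cohort summary reports). Kinds
#'   are inferred from the values when absent.
#' @param subject_ids character subject identifiers (default sub-0001...).
#' @return object of class \code{"clinical_table"}.
#' @export
clinical_table <- function(data, meta = NULL, subject_ids = NULL) {
  stopifnot(is.data.frame(data), ncol(data) >= 1)
  n <- nrow(data)
  if (is.null(subject_ids)) subject_ids <- sprintf("sub-%04d", seq_len(n))
  if (length(subject_ids) != n) stop2("subject_ids length must equal nrow(data)")
  m <- list()
  for (nm in names(data)) {
    v <- data[[nm]]
    if (!is.numeric(v)) stop2("variable '", nm, "' is not numeric")
    info <- meta[[nm]] %||% list()
    kind <- info$kind %||%
      (if (all(v %in% c(0, 1, NA))) "binary" else "continuous")
    if (kind == "binary" && !all(v %in% c(0, 1, NA)))
      stop2("binary variable '", nm, "' has values outside {0, 1, NA}")
    m[[nm]] <- list(name = nm, kind = kind, unit = info$unit %||% "",
                    center = info$center %||% "median")
  }
  structure(list(data = data, meta = m, subject_ids = subject_ids),
            class = "clinical_table")
}

#' @export
print.clinical_table <- function(x, ...) {
  kinds <- vapply(x$meta, `[[`, "", "kind")
  cat("Clinical table:", nrow(x$data), "subjects,", ncol(x$data),
      "variables (", sum(kinds == "continuous"), "continuous,",
      sum(kinds == "binary"), "binary )\n")
  nmiss <- vapply(x$data, function(v) sum(is.na(v)), integer(1))
  if (any(nmiss > 0))
    cat("  missing entries:",
        paste(sprintf("%s=%d", names(nmiss)[nmiss > 0], nmiss[nmiss > 0]),
              collapse = ", "), "\n")
  invisible(x)
}

#' Encode a clinical table into the numeric CCA design matrix
#'
#' Continuous variables are z-scored (sample sd); binary variables are kept
#' on their 0/1 scale and centered (retaining prevalence information in the
#' column scale) unless \code{scale_binary = TRUE}. Missing entries are
#' imputed (column mean for continuous, mode for binary) and the imputation
#' count recorded per column. Constant columns are rejected: a zero-variance
#' variable carries no correlation information.
#'
#' Applying the encoding to an already-encoded matrix reproduces it (the
#' stored kinds are reused, so the map is idempotent).
#'
#' @param table a \code{\link{clinical_table}} or \code{"clinical_matrix"}.
#' @param scale_binary also divide centered binary columns by their sd.
#' @return object of class \code{"clinical_matrix"}: \code{values} (n x p),
#'   \code{meta} (data.frame: name, kind, transform, n_imputed),
#'   \code{raw} (imputed pre-standardization data), \code{subject_ids},
#'   \code{scale_binary}.
#' @export
encode_clinical <- function(table, scale_binary = FALSE) {
  if (inherits(table, "clinical_matrix")) {
    # re-encoding: reuse stored kinds, bypass the raw-table 0/1 validation
    # (binary columns are already centered off the 0/1 scale)
    meta <- lapply(table$meta$kind, function(k) list(kind = k))
    names(meta) <- table$meta$name
    tb <- structure(list(data = as.data.frame(table$values), meta = meta,
                         subject_ids = table$subject_ids),
                    class = "clinical_table")
    return(encode_frame(tb, scale_binary = table$scale_binary,
                        assume_encoded = TRUE))
  }
  stopifnot(inherits(table, "clinical_table"))
  if (ncol(table$data) < 2) stop2("need at least 2 variables")
  if (nrow(table$data) < 3) stop2("need at least 3 subjects")
  encode_frame(table, scale_binary = scale_binary, assume_encoded = FALSE)
}

encode_frame <- function(table, scale_binary, assume_encoded) {
  df <- table$data
  n <- nrow(df)
  vals <- matrix(NA_real_, n, ncol(df))
  colnames(vals) <- names(df)
  meta <- data.frame(name = names(df),
                     kind = vapply(table$meta, `[[`, "", "kind"),
                     transform = "none",
                     n_imputed = 0L, stringsAsFactors = FALSE)
  raw <- df
  for (i in seq_along(df)) {
    v <- df[[i]]
    kind <- meta$kind[i]
    miss <- is.na(v)
    if (any(miss)) {
      fill <- if (kind == "continuous" || assume_encoded) mean(v, na.rm = TRUE)
              else as.numeric(names(sort(table(v), decreasing = TRUE))[1])
      v[miss] <- fill
      meta$n_imputed[i] <- sum(miss)
    }
    raw[[i]] <- v
    if (sd(v) == 0)
      stop2("variable '", names(df)[i], "' is constant after imputation; ",
            "zero variance breaks correlation analysis")
    if (kind == "continuous") {
      vals[, i] <- (v - mean(v)) / sd(v)
    } else {
      vals[, i] <- v - mean(v)
      if (scale_binary) vals[, i] <- vals[, i] / sd(v)
    }
  }
  structure(list(values = vals, meta = meta, raw = raw,
                 subject_ids = table$subject_ids,
                 scale_binary = scale_binary),
            class = "clinical_matrix")
}

#' @export
print.clinical_matrix <- function(x, ...) {
  cat("Encoded clinical matrix:", nrow(x$values), "x", ncol(x$values), "\n")
  if (any(x$meta$n_imputed > 0))
    cat("  imputed:", paste(sprintf("%s=%d",
        x$meta$name[x$meta$n_imputed > 0],
        x$meta$n_imputed[x$meta$n_imputed > 0]), collapse = ", "), "\n")
  tr <- x$meta$transform != "none"
  if (any(tr))
    cat("  transforms:", paste(sprintf("%s=%s", x$meta$name[tr],
                                       x$meta$transform[tr]), collapse = ", "), "\n")
  invisible(x)
}

#' Apply skew-reducing transforms before re-standardization
#'
#' Re-derives selected columns of an encoded clinical matrix from the raw
#' (imputed) values with a cube-root, square-root or square transform applied
#' first, then re-standardizes. The applied transform is recorded in the
#' column metadata.
#'
#' @param cm a \code{"clinical_matrix"}.
#' @param assignments named character vector mapping variable names to one of
#'   \code{"cbrt"}, \code{"sqrt"}, \code{"square"}, \code{"none"}.
#' @return a new \code{"clinical_matrix"}.
#' @export
transform_skewed <- function(cm, assignments) {
  stopifnot(inherits(cm, "clinical_matrix"))
  for (nm in names(assignments)) {
    tr <- match.arg(assignments[[nm]], c("cbrt", "sqrt", "square", "none"))
    i <- match(nm, cm$meta$name)
    if (is.na(i)) stop2("unknown variable '", nm, "'")
    v <- cm$raw[[nm]]
    if (tr == "sqrt" && any(v < 0))
      stop2("sqrt transform on variable '", nm, "': negative value ",
            v[which(v < 0)[1]], " at row ", which(v < 0)[1])
    w <- switch(tr, cbrt = sign(v) * abs(v)^(1 / 3), sqrt = sqrt(v),
                square = v^2, none = v)
    if (sd(w) == 0)
      stop2("variable '", nm, "' is constant after ", tr, " transform")
    if (cm$meta$kind[i] == "continuous") {
      cm$values[, i] <- (w - mean(w)) / sd(w)
    } else {
      cm$values[, i] <- w - mean(w)
      if (cm$scale_binary) cm$values[, i] <- cm$values[, i] / sd(w)
    }
    cm$meta$transform[i] <- tr
  }
  cm
}

#' Drop rare binary factors
#'
#' Removes binary variables whose positive-case fraction (among non-missing
#' entries) falls below \code{min_prevalence}; continuous variables are never
#' touched. Dropped names are attached as attribute \code{"dropped"}.
#'
#' @param table a \code{\link{clinical_table}}.
#' @param min_prevalence threshold in (0, 1); use 0 for a no-op.
#' @return filtered \code{clinical_table}.
#' @export
filter_rare <- function(table, min_prevalence = 0.10) {
  stopifnot(inherits(table, "clinical_table"))
  if (min_prevalence < 0 || min_prevalence >= 1)
    stop2("min_prevalence must be in [0, 1)")
  drop <- character(0)
  for (nm in names(table$data)) {
    if (table$meta[[nm]]$kind != "binary") next
    prev <- mean(table$data[[nm]] == 1, na.rm = TRUE)
    if (prev < min_prevalence) drop <- c(drop, nm)
  }
  keep <- setdiff(names(table$data), drop)
  if (!length(keep))
    warning("all variables dropped by rare-factor filter")
  out <- clinical_table(table$data[keep],
                        meta = table$meta[keep],
                        subject_ids = table$subject_ids)
  attr(out, "dropped") <- drop
  out
}

#' Summarize a cohort clinical table
#'
#' Binary variables are reported as positive count and percentage (2 decimal
#' places, denominator = non-missing count); continuous variables as their
#' central value (median by default, mean when the variable's metadata flags
#' it) with the observed range.
#'
#' @param table a \code{\link{clinical_table}}.
#' @return data.frame of class \code{"cohort_summary"} with columns
#'   variable, kind, n, count, percent, central, central_kind, min, max,
#'   n_missing.
#' @export
cohort_summary <- function(table) {
  stopifnot(inherits(table, "clinical_table"))
  rows <- lapply(names(table$data), function(nm) {
    v <- table$data[[nm]]
    info <- table$meta[[nm]]
    nn <- sum(!is.na(v))
    if (info$kind == "binary") {
      cnt <- sum(v == 1, na.rm = TRUE)
      data.frame(variable = nm, kind = "binary", n = nn, count = cnt,
                 percent = round(100 * cnt / nn, 2), central = NA_real_,
                 central_kind = NA_character_, min = NA_real_, max = NA_real_,
                 n_missing = sum(is.na(v)))
    } else {
      cen <- if (identical(info$center, "mean")) mean(v, na.rm = TRUE)
             else median(v, na.rm = TRUE)
      data.frame(variable = nm, kind = "continuous", n = nn, count = NA_integer_,
                 percent = NA_real_, central = cen,
                 central_kind = info$center %||% "median",
                 min = min(v, na.rm = TRUE), max = max(v, na.rm = TRUE),
                 n_missing = sum(is.na(v)))
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (", max(x$n + x$n_missing), " subjects )\n", sep = "")
  for (i in seq_len(nrow(x))) {
    if (x$kind[i] == "binary") {
      cat(sprintf("  %-28s %4d (%.2f%%)\n", x$variable[i], x$count[i],
                  x$percent[i]))
    } else {
      cat(sprintf("  %-28s %s %.2f (range %.2f-%.2f)\n", x$variable[i],
                  x$central_kind[i], x$central[i], x$min[i], x$max[i]))
    }
    if (x$n_missing[i] > 0)
      cat(sprintf("  %-28s   [%d missing]\n", "", x$n_missing[i]))
  }
  invisible(x)
}

#' Remove subjects consistently from analysis structures
#'
#' @param x a \code{clinical_table}, \code{multimodal_dataset}, outcome
#'   data.frame or \code{sim_cohort}.
#' @param ids character subject ids (or integer positions) to drop.
#' @return the same type with the rows removed.
#' @export
drop_subjects <- function(x, ids) UseMethod("drop_subjects")

resolve_drop <- function(all_ids, ids) {
  if (is.numeric(ids)) {
    if (any(ids < 1 | ids > length(all_ids)))
      stop2("subject index out of range: ",
            ids[which(ids < 1 | ids > length(all_ids))[1]])
    idx <- as.integer(ids)
  } else {
    idx <- match(ids, all_ids)
    if (anyNA(idx)) stop2("unknown subject id: ", ids[which(is.na(idx))[1]])
  }
  if (length(unique(idx)) >= length(all_ids))
    stop2("cannot drop all subjects")
  unique(idx)
}

#' @export
drop_subjects.clinical_table <- function(x, ids) {
  idx <- resolve_drop(x$subject_ids, ids)
  clinical_table(x$data[-idx, , drop = FALSE], meta = x$meta,
                 subject_ids = x$subject_ids[-idx])
}

#' @export
drop_subjects.multimodal_dataset <- function(x, ids) {
  idx <- resolve_drop(x$subject_ids, ids)
  blocks <- lapply(x$blocks, function(b) {
    b$data <- b$data[-idx, , drop = FALSE]; b
  })
  multimodal_dataset(blocks, subject_ids = x$subject_ids[-idx])
}

#' @export
drop_subjects.data.frame <- function(x, ids) {
  idx <- resolve_drop(rownames(x), ids)
  x[-idx, , drop = FALSE]
}

#' @export
drop_subjects.sim_cohort <- function(x, ids) {
  idx <- resolve_drop(x$dataset$subject_ids, ids)
  x$latents$values <- x$latents$values[-idx, , drop = FALSE]
  x$dataset <- drop_subjects(x$dataset, idx)
  if (!is.null(x$clinical)) x$clinical <- drop_subjects(x$clinical, idx)
  if (!is.null(x$outcomes)) x$outcomes <- x$outcomes[-idx, , drop = FALSE]
  x
}
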