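make_table <- function() {
  clinical_table(data.frame(
    ga = c(28, 30, 32, 29, 31, 27),
    vent = c(0, 5, 1, 12, 0, 2),
    male = c(1, 0, 1, 1, 0, 0),
    rare = c(0, 0, 0, 1, 0, 0)),
    meta = list(ga = list(center = "median"),
                vent = list(center = "mean")))
}

test_that("encoding z-scores continuous and centers binary columns", {
  cm <- encode_clinical(make_table())
  expect_lt(max(abs(colMeans(cm$values))), 1e-12)
  expect_equal(sd(cm$values[, "ga"]), 1, tolerance = 1e-12)
  # binary columns keep the 0/1 scale (centered only)
  expect_equal(sort(unique(cm$values[, "male"])), c(-0.5, 0.5))
  expect_identical(cm$meta$kind, c("continuous", "continuous", "binary",
                                   "binary"))
  # explicit worked example: {1,2,3} -> {-1,0,1}/sd
  tb <- clinical_table(data.frame(a = c(1, 2, 3), b = c(0, 1, 1)))
  cm2 <- encode_clinical(tb)
  expect_equal(cm2$values[, "a"], c(-1, 0, 1) / sd(c(1, 2, 3)),
               tolerance = 1e-12)
})

test_that("missing entries are imputed and counted", {
  df <- data.frame(tpn = c(3, NA, 5, 9, 2, 1), other = c(1, 2, 1, 3, 2, 4))
  cm <- encode_clinical(clinical_table(df))
  expect_equal(cm$meta$n_imputed, c(1L, 0L))
  expect_equal(cm$raw$tpn[2], mean(df$tpn, na.rm = TRUE))
  expect_false(anyNA(cm$values))
  # binary mode imputation
  dfb <- data.frame(b = c(1, 0, 0, NA, 0, 0), x = c(1, 5, 2, 4, 3, 6))
  cmb <- encode_clinical(clinical_table(dfb))
  expect_equal(cmb$raw$b[4], 0)
})

test_that("constant columns are rejected by name", {
  df <- data.frame(ok = c(1, 2, 3), flat = c(2, 2, 2))
  expect_error(encode_clinical(clinical_table(df)), "flat")
})

test_that("encoding is idempotent on already-encoded data", {
  cm <- encode_clinical(make_table())
  cm2 <- encode_clinical(cm)
  expect_equal(cm2$values, cm$values, tolerance = 1e-12)
})

test_that("skew transforms apply to raw values before re-standardization", {
  df <- data.frame(x = c(-8, 0, 8), y = c(1, 4, 9), s = c(-1, 0, 1))
  cm <- encode_clinical(clinical_table(df))
  tr <- transform_skewed(cm, c(x = "cbrt"))
  expect_equal(tr$values[, "x"],
               (c(-2, 0, 2) - 0) / sd(c(-2, 0, 2)), tolerance = 1e-12)
  expect_equal(tr$meta$transform[1], "cbrt")
  tr2 <- transform_skewed(cm, c(s = "square"))
  w <- c(1, 0, 1)
  expect_equal(tr2$values[, "s"], (w - mean(w)) / sd(w), tolerance = 1e-12)
  expect_error(transform_skewed(cm, c(x = "sqrt")), "negative")
})

test_that("cube root strictly reduces the skewness of a log-normal sample", {
  skew <- function(v) mean((v - mean(v))^3) / sd(v)^3
  x <- with_seed(5, exp(rnorm(500)))
  cm <- encode_clinical(clinical_table(data.frame(x = x, y = rnorm(500))))
  before <- skew(cm$raw$x)
  after <- skew(sign(cm$raw$x) * abs(cm$raw$x)^(1 / 3))
  expect_lt(after, before)
})

test_that("rare-factor filtering drops below-threshold binaries only", {
  n <- 449
  df <- data.frame(drug_abuse = c(rep(1, 6), rep(0, n - 6)),
                   male = c(rep(1, 226), rep(0, n - 226)),
                   ga = rnorm(n) + 30)
  tb <- clinical_table(df)
  out <- filter_rare(tb, 0.10)
  expect_identical(attr(out, "dropped"), "drug_abuse")
  expect_true(all(c("male", "ga") %in% names(out$data)))
  # threshold 0 keeps everything
  out0 <- filter_rare(tb, 0)
  expect_identical(names(out0$data), names(df))
  # monotone: raising the threshold never re-admits a dropped variable
  dropped_at <- function(th) attr(filter_rare(tb, th), "dropped")
  d1 <- dropped_at(0.02); d2 <- dropped_at(0.10); d3 <- dropped_at(0.60)
  expect_true(all(d1 %in% d2) && all(d2 %in% d3))
})

test_that("cohort summary reproduces count/percentage and range formats", {
  n <- 449
  df <- data.frame(male = c(rep(1, 226), rep(0, n - 226)),
                   none = rep(0, n),
                   ga = seq(23.5, 32.9, length.out = n))
  tb <- clinical_table(df, meta = list(none = list(kind = "binary")))
  s <- cohort_summary(tb)
  expect_equal(s$percent[s$variable == "male"], 50.33)
  expect_equal(s$percent[s$variable == "none"], 0)
  expect_equal(s$central[s$variable == "ga"], median(df$ga))
  expect_equal(s$min[s$variable == "ga"], 23.5)
  # percentages recompute exactly from counts
  expect_equal(s$percent[1], round(100 * s$count[1] / s$n[1], 2))
})

test_that("subject drops propagate consistently and reject bad ids", {
  coh <- simulate_cohort(tiny_spec(n = 60, seed = 2))
  ids <- coh$dataset$subject_ids[1:5]
  out <- drop_subjects(coh, ids)
  expect_equal(out$dataset$n, 55L)
  expect_equal(nrow(out$clinical$data), 55L)
  expect_equal(nrow(out$outcomes), 55L)
  expect_equal(nrow(out$latents$values), 55L)
  expect_error(drop_subjects(coh$clinical, "sub-9999"), "unknown subject")
  expect_error(drop_subjects(coh$clinical, coh$dataset$subject_ids),
               "cannot drop all")
})
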