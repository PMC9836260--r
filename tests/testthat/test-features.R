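test_that("neutral filtering removes exact zeros and preserves order", {
  expect_equal(as.numeric(filter_neutral(c(0.5, 0, -0.2))), c(0.5, -0.2))
  expect_length(filter_neutral(c(0, 0, 0)), 0)
  x <- c(0.3, -0.1, 0.2)
  expect_equal(as.numeric(filter_neutral(x)), x)
  expect_equal(attr(filter_neutral(x), "variant"), "filtered")
})

test_that("quartile flags mark the extreme quarter of each sign", {
  expect_equal(quartile_flags(c(0.1, 0.2, 0.3, 0.4)),
               c("none", "none", "none", "happy"))
  expect_equal(quartile_flags(c(-0.4, -0.3, -0.2, -0.1)),
               c("sad", "none", "none", "none"))
  expect_false(any(quartile_flags(c(-0.5, -0.1, -0.2)) == "happy"))
  expect_equal(quartile_flags(numeric(0)), character(0))
  # a single positive score is its own top quartile
  expect_equal(quartile_flags(c(0.2, 0, -0.1)),
               c("happy", "none", "sad"))
})

test_that("islands are maximal same-flag runs with earliest-max extrema", {
  x <- c(1, 1, 0.1, 0.1, 1, 1, 1)
  isl <- find_islands(x)
  happy <- isl[isl$sign == "happy", ]
  expect_equal(happy$length, c(2, 3))
  expect_equal(happy$start, c(1, 5))
  expect_equal(happy$extremum_index, c(1, 5)) # ties -> earliest
  expect_equal(nrow(find_islands(c(0.1, 0.2))[
    find_islands(c(0.1, 0.2))$sign == "sad", , drop = FALSE]), 0)
  expect_equal(find_islands(c(5))$length, 1)
})

test_that("flip features count opposite-sign adjacencies with zeros breaking flips", {
  expect_equal(flip_features(c(0.5, -0.3, 0.2, 0.0, 0.1)),
               list(NFF = 2L, FF = 0.4))
  expect_equal(flip_features(c(0.1, 0.2, 0.3))$NFF, 0L)
  expect_equal(flip_features(c(1, -1, 1, -1)), list(NFF = 3L, FF = 0.75))
  expect_equal(flip_features(numeric(0)), list(NFF = 0L, FF = 0))
})

test_that("spacing features use the two longest islands of each sign", {
  # single happy island only -> zeros
  one <- c(0.9, 0.9, 0.1, 0.1)
  sp <- spacing_features(one)
  expect_equal(sp$HS, 0); expect_equal(sp$HMSS, 0L)
  # flagged runs [3,3] (hill 3) and [8,9] (hill 8) of n = 10
  x <- c(0.1, 0.8, 0.9, 0.1, 0.1, 0.1, 0.8, 0.9, 0.85, 0.1)
  sp <- spacing_features(x)
  expect_equal(sp$HS, 0.5)
  expect_equal(sp$HMSS, 4L) # sentences 4, 5, 6, 7 lie strictly between
})

test_that("island intensity features cover the longest island only", {
  # flagged happy run is [1,3]; the lone -0.5 is the only flagged sad score
  x <- c(1, 0.9, 0.95, rep(0.1, 9), -0.5, -0.1, -0.1, -0.1)
  ii <- island_intensity_features(x)
  expect_equal(ii$MAXHI, 1)
  expect_equal(ii$HVAR, mean((c(1, 0.9, 0.95) - mean(c(1, 0.9, 0.95)))^2))
  expect_equal(ii$MINSI, -0.5)
  expect_equal(ii$SVAR, 0)
})

test_that("moving-average RMSE truncates windows at the edges", {
  expect_equal(smoothness_rmse(rep(0.4, 6)), 0)
  expect_equal(smoothness_rmse(c(1, 0, 1, 0)), 0.5892557, tolerance = 1e-6)
  expect_equal(smoothness_rmse(c(3)), 0)
  expect_error(smoothness_rmse(c(1, 2, 3), window = 4), "odd")
})

test_that("peak features use strict interior extrema", {
  pk <- peak_features(c(0, 1, 0, -1, 0))
  expect_equal(unlist(pk),
               c(PP = 1, NP = 1, PR = 1, SPP = 1, NPP = -1, APR = 1))
  pk <- peak_features(c(0.1, 0.2, 0.3, 0.4))
  expect_equal(pk$PP + pk$NP, 0)
  expect_equal(pk$PR, 0); expect_equal(pk$APR, 0)
  pk <- peak_features(c(0, 2, 0, 3, 0))
  expect_equal(pk$PP, 2L); expect_equal(pk$NP, 1L)
})

test_that("population variance divides by the count and degenerates to zero", {
  expect_equal(series_features(c(1, 1, 1))[["VAR"]], 0)
  expect_equal(series_features(c(1, -1))[["VAR"]], 1)
  expect_equal(series_features(numeric(0))[["VAR"]], 0)
})

test_that("the 42-value vector is complete, finite and named in fixed order", {
  lex <- demo_lexicon()
  doc <- as_document("d", "Good start. We met. Bad end. Very excellent work.")
  v <- extract_eva(doc, lex)
  expect_length(v, 42)
  expect_true(all(is.finite(v)))
  expect_identical(names(v), c(paste0("FS_", eva_feature_names()),
                               paste0("UFS_", eva_feature_names())))
  # with no zero-score sentences the two blocks coincide
  doc2 <- as_document("d2", "Good start. Bad end.")
  v2 <- extract_eva(doc2, lex)
  expect_equal(unname(v2[1:21]), unname(v2[22:42]))
  # empty document -> all zeros
  expect_true(all(extract_eva(as_document("e", ""), lex) == 0))
})

test_that("every feature matches the brute-force oracle on random series", {
  set.seed(123)
  for (trial in 1:1000) {
    n <- sample(0:30, 1)
    x <- round(rnorm(n, 0, 0.4), 3)
    x[runif(n) < 0.2] <- 0
    got <- series_features(x)
    want <- oracle_features(x)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("order-dependent features react to shuffling while AVG and VAR do not", {
  set.seed(9)
  changed <- c(FF = 0, HI = 0, SI = 0, HS = 0, TS = 0, RMSE = 0)
  for (trial in 1:50) {
    x <- rnorm(40, 0, 0.5)
    f1 <- series_features(x)
    f2 <- series_features(sample(x))
    expect_equal(f2[["AVG"]], f1[["AVG"]], tolerance = 1e-12)
    expect_equal(f2[["VAR"]], f1[["VAR"]], tolerance = 1e-12)
    for (nm in names(changed)) {
      if (abs(f2[[nm]] - f1[[nm]]) > 1e-12) changed[nm] <- changed[nm] + 1
    }
  }
  # every order-dependent feature reacts in some trials; the densest ones
  # (flip rate, smoothness) react in most
  expect_true(all(changed > 0))
  expect_true(changed[["FF"]] > 25 && changed[["RMSE"]] > 25)
})

test_that("a planted happy run among sub-threshold scores is recovered exactly", {
  for (L in c(1, 3, 5, 8)) {
    x <- rep(0, 30)
    x[10:(10 + L - 1)] <- 1
    expect_equal(series_features(x)[["HI"]], L)
  }
})

test_that("normalized rates stay within their bounds", {
  set.seed(21)
  for (trial in 1:100) {
    x <- rnorm(sample(2:40, 1), 0, 0.5)
    f <- series_features(x)
    expect_true(f[["FF"]] >= 0 && f[["FF"]] <= 1)
    expect_true(f[["HS"]] >= 0 && f[["HS"]] <= 1)
    expect_true(f[["TS"]] >= 0 && f[["TS"]] <= 1)
  }
})
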