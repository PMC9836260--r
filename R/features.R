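#' Per-sentence sentiment series
#'
#' A numeric vector of sentence scores \eqn{\delta} in document order,
#' tagged with its variant: \code{"unfiltered"} keeps neutral (zero-score)
#' sentences, \code{"filtered"} has them removed.
#'
#' @param scores Numeric vector.
#' @param variant \code{"unfiltered"} or \code{"filtered"}.
#' @return Numeric vector of class \code{sentiment_series}.
#' @export
sentiment_series <- function(scores, variant = c("unfiltered", "filtered")) {
  variant <- match.arg(variant)
  scores <- as.numeric(scores)
  stopifnot(all(is.finite(scores)))
  structure(scores, variant = variant, class = "sentiment_series")
}

#' @export
print.sentiment_series <- function(x, ...) {
  cat("<sentiment_series>", attr(x, "variant"), "| n =", length(x), "\n")
  print(as.numeric(x))
  invisible(x)
}

#' Remove neutral sentences from a series
#'
#' Drops scores of exactly zero (|score| <= \code{tol}), preserving the
#' order of survivors; the result is the filtered variant on which the
#' \code{FS_} feature block is computed.
#'
#' @param series Numeric vector or [sentiment_series()].
#' @param tol Neutrality tolerance, default 1e-12.
#' @return A filtered [sentiment_series()].
#' @export
filter_neutral <- function(series, tol = 1e-12) {
  x <- as.numeric(series)
  sentiment_series(x[abs(x) > tol], variant = "filtered")
}

#' Extreme-quartile flags
#'
#' Flags each sentence \code{"happy"} when its score is strictly positive
#' and at or above the 75th percentile of all strictly positive scores in
#' the series; \code{"sad"} symmetrically at or below the 25th percentile
#' of the strictly negative scores; otherwise \code{"none"}. With no
#' positive (negative) scores there are no happy (sad) flags.
#'
#' @param series Numeric vector of scores.
#' @return Character vector of flags, aligned with the series.
#' @export
quartile_flags <- function(series) {
  x <- as.numeric(series)
  flags <- rep("none", length(x))
  pos <- x[x > 0]
  if (length(pos)) {
    thr <- quantile(pos, 0.75, names = FALSE)
    flags[x > 0 & x >= thr] <- "happy"
  }
  neg <- x[x < 0]
  if (length(neg)) {
    thr <- quantile(neg, 0.25, names = FALSE)
    flags[x < 0 & x <= thr] <- "sad"
  }
  flags
}

#' Find happy and sad islands
#'
#' An island is a maximal run of adjacent same-flag sentences; its extremal
#' point (the hill of a happy island, trough of a sad one) is the member
#' with the largest absolute score, earliest on ties.
#'
#' @param series Numeric vector of scores.
#' @param flags Flags from [quartile_flags()]; recomputed when missing.
#' @return Data frame with columns \code{sign} ("happy"/"sad"),
#'   \code{start}, \code{end} (1-based inclusive), \code{length},
#'   \code{extremum_index}.
#' @export
find_islands <- function(series, flags = quartile_flags(series)) {
  x <- as.numeric(series)
  stopifnot(length(flags) == length(x))
  empty <- data.frame(sign = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      extremum_index = integer(0), stringsAsFactors = FALSE)
  if (!length(x)) return(empty)
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "none"
  if (!any(keep)) return(empty)
  starts <- starts[keep]; ends <- ends[keep]; signs <- r$values[keep]
  ext <- mapply(function(s, e) {
    span <- s:e
    span[which.max(abs(x[span]))]
  }, starts, ends)
  data.frame(sign = signs, start = starts, end = ends,
             length = ends - starts + 1L,
             extremum_index = as.integer(ext), stringsAsFactors = FALSE)
}

longest_island <- function(islands, sign) {
  isl <- islands[islands$sign == sign, , drop = FALSE]
  if (!nrow(isl)) return(NULL)
  isl[order(-isl$length, isl$start)[1], , drop = FALSE]
}

top_two_islands <- function(islands, sign) {
  isl <- islands[islands$sign == sign, , drop = FALSE]
  if (nrow(isl) < 2) return(NULL)
  isl[order(-isl$length, isl$start)[1:2], , drop = FALSE]
}

#' Sign-flip statistics
#'
#' A flip is an adjacent sentence pair with strictly opposite nonzero score
#' signs; zero scores break a flip. \code{NFF} is the raw flip count and
#' \code{FF = NFF / n} its normalization by the series length.
#'
#' @param series Numeric vector of scores.
#' @return List with \code{NFF} (count) and \code{FF} (rate in [0, 1]).
#' @export
flip_features <- function(series) {
  x <- as.numeric(series)
  n <- length(x)
  if (n == 0) return(list(NFF = 0L, FF = 0))
  s <- sign(x)
  nff <- sum(s[-n] * s[-1] < 0)
  list(NFF = as.integer(nff), FF = nff / n)
}

pop_var <- function(x) {
  x <- as.numeric(x)
  if (length(x) <= 1) return(0)
  mean((x - mean(x))^2)
}

#' Island spacing features
#'
#' From the two longest happy islands (ties broken to the earliest):
#' \code{HS} is the hill-to-hill distance \eqn{|h_1 - h_2| / n} and
#' \code{HMSS} the number of sentences strictly between the two spans.
#' \code{TS}/\code{TMSS} are the sad-island counterparts. Fewer than two
#' islands of a sign gives 0 for that sign's pair.
#'
#' @param series Numeric vector of scores.
#' @param islands Data frame from [find_islands()]; recomputed when missing.
#' @return List \code{HS}, \code{TS}, \code{HMSS}, \code{TMSS}.
#' @export
spacing_features <- function(series, islands = find_islands(series)) {
  n <- length(as.numeric(series))
  one_sign <- function(sign) {
    top <- top_two_islands(islands, sign)
    if (is.null(top) || n == 0) return(list(spread = 0, between = 0L))
    spread <- abs(top$extremum_index[1] - top$extremum_index[2]) / n
    ord <- top[order(top$start), , drop = FALSE]
    between <- max(0L, ord$start[2] - ord$end[1] - 1L)
    list(spread = spread, between = as.integer(between))
  }
  h <- one_sign("happy"); s <- one_sign("sad")
  list(HS = h$spread, TS = s$spread, HMSS = h$between, TMSS = s$between)
}

#' Island intensity features
#'
#' Over the members of the longest happy island: \code{MAXHI} is the
#' maximum score and \code{HVAR} the population variance; \code{MINSI} and
#' \code{SVAR} are the minimum and variance over the longest sad island.
#' Absent islands give 0.
#'
#' @inheritParams spacing_features
#' @return List \code{MAXHI}, \code{MINSI}, \code{HVAR}, \code{SVAR}.
#' @export
island_intensity_features <- function(series, islands = find_islands(series)) {
  x <- as.numeric(series)
  hi <- longest_island(islands, "happy")
  si <- longest_island(islands, "sad")
  h_scores <- if (is.null(hi)) numeric(0) else x[hi$start:hi$end]
  s_scores <- if (is.null(si)) numeric(0) else x[si$start:si$end]
  list(MAXHI = if (length(h_scores)) max(h_scores) else 0,
       MINSI = if (length(s_scores)) min(s_scores) else 0,
       HVAR = pop_var(h_scores),
       SVAR = pop_var(s_scores))
}

#' Smoothness deviation (moving-average RMSE)
#'
#' Smooths the series with a centered moving average (window truncated at
#' the edges) and returns the root-mean-square error between the smoothed
#' and original series. Constant series give 0; so do series of length 0 or
#' 1.
#'
#' @param series Numeric vector of scores.
#' @param window Odd positive window size, default 3.
#' @return Non-negative numeric.
#' @export
smoothness_rmse <- function(series, window = 3L) {
  if (window < 1 || window %% 2 == 0) {
    stop("smoothing window must be a positive odd count")
  }
  x <- as.numeric(series)
  n <- length(x)
  if (n <= 1) return(0)
  h <- (window - 1L) %/% 2L
  sm <- vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
  sqrt(mean((sm - x)^2))
}

#' Peak features
#'
#' A positive peak is an interior point strictly higher than both
#' neighbours; a negative peak strictly lower. \code{PP}/\code{NP} count
#' them, \code{PR = PP / NP} (\code{PP} itself when \code{NP} is 0),
#' \code{SPP}/\code{NPP} sum the peak scores, and \code{APR = SPP / |NPP|}
#' (\code{SPP} itself when \code{NPP} is 0).
#'
#' @param series Numeric vector of scores.
#' @return List \code{PP}, \code{NP}, \code{PR}, \code{SPP}, \code{NPP},
#'   \code{APR}.
#' @export
peak_features <- function(series) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < 3) {
    return(list(PP = 0L, NP = 0L, PR = 0, SPP = 0, NPP = 0, APR = 0))
  }
  mid <- 2:(n - 1)
  is_pp <- x[mid] > x[mid - 1] & x[mid] > x[mid + 1]
  is_np <- x[mid] < x[mid - 1] & x[mid] < x[mid + 1]
  pp <- sum(is_pp); np <- sum(is_np)
  spp <- sum(x[mid][is_pp]); npp <- sum(x[mid][is_np])
  list(PP = as.integer(pp), NP = as.integer(np),
       PR = if (np == 0) pp else pp / np,
       SPP = spp, NPP = npp,
       APR = if (npp == 0) spp else spp / abs(npp))
}

#' Canonical feature-name order
#'
#' The fixed order of the 21 per-series features; the 42-value vector is
#' this list prefixed \code{FS_} (filtered block) then \code{UFS_}
#' (unfiltered block).
#'
#' @return Character vector of length 21.
#' @export
eva_feature_names <- function() {
  c("AVG", "HI", "SI", "FF", "NFF", "VAR", "HS", "TS", "HMSS", "TMSS",
    "MAXHI", "MINSI", "HVAR", "SVAR", "RMSE", "PP", "NP", "PR", "SPP",
    "NPP", "APR")
}

#' Compute the 21 emotional-variability features of one series
#'
#' \code{AVG} mean score; \code{HI}/\code{SI} longest happy/sad island
#' length; \code{FF}/\code{NFF} flip rate and count; \code{VAR} population
#' variance; \code{HS}/\code{TS}/\code{HMSS}/\code{TMSS} island spacing;
#' \code{MAXHI}/\code{MINSI}/\code{HVAR}/\code{SVAR} island intensity;
#' \code{RMSE} smoothness deviation; \code{PP}/\code{NP}/\code{PR}/
#' \code{SPP}/\code{NPP}/\code{APR} peak statistics. All degenerate cases
#' (empty series, no islands, no peaks) map to 0 so vectors stay finite and
#' comparable.
#'
#' @param series Numeric vector of scores.
#' @param smoothing_window Odd moving-average window for \code{RMSE}.
#' @return Named numeric vector of length 21 in [eva_feature_names()] order.
#' @export
series_features <- function(series, smoothing_window = 3L) {
  x <- as.numeric(series)
  n <- length(x)
  flags <- quartile_flags(x)
  islands <- find_islands(x, flags)
  hi <- longest_island(islands, "happy")
  si <- longest_island(islands, "sad")
  fl <- flip_features(x)
  sp <- spacing_features(x, islands)
  ii <- island_intensity_features(x, islands)
  pk <- peak_features(x)
  out <- c(AVG = if (n) mean(x) else 0,
           HI = if (is.null(hi)) 0 else hi$length,
           SI = if (is.null(si)) 0 else si$length,
           FF = fl$FF, NFF = fl$NFF,
           VAR = pop_var(x),
           HS = sp$HS, TS = sp$TS, HMSS = sp$HMSS, TMSS = sp$TMSS,
           MAXHI = ii$MAXHI, MINSI = ii$MINSI, HVAR = ii$HVAR,
           SVAR = ii$SVAR,
           RMSE = smoothness_rmse(x, smoothing_window),
           PP = pk$PP, NP = pk$NP, PR = pk$PR, SPP = pk$SPP,
           NPP = pk$NPP, APR = pk$APR)
  out[eva_feature_names()]
}

#' Extract the 42-value feature vector of a document
#'
#' Scores the document, computes the 21 features on the unfiltered series
#' (\code{UFS_} block) and again on the neutral-filtered series
#' (\code{FS_} block). Rates and normalizations inside each block use that
#' block's own series length.
#'
#' @param doc An \code{eva_document}.
#' @param lexicon An [lexicon()] object.
#' @param config An [eva_config()] list.
#' @return Named numeric vector of length 42 (\code{FS_*} then
#'   \code{UFS_*}).
#' @export
extract_eva <- function(doc, lexicon, config = eva_config()) {
  series <- score_document(doc, lexicon, config)
  eva_vector(series, config)
}

#' Feature vector from a precomputed series
#'
#' @param series Unfiltered [sentiment_series()] or numeric vector.
#' @param config An [eva_config()] list.
#' @return Named numeric vector of length 42.
#' @export
eva_vector <- function(series, config = eva_config()) {
  ufs <- series_features(series, config$smoothing_window)
  fs <- series_features(filter_neutral(series, config$neutral_tol),
                        config$smoothing_window)
  out <- c(stats::setNames(fs, paste0("FS_", names(fs))),
           stats::setNames(ufs, paste0("UFS_", names(ufs))))
  stopifnot(length(out) == 42L, all(is.finite(out)))
  out
}

#' Feature table for a corpus
#'
#' @param corpus List of \code{eva_document} objects.
#' @param lexicon An [lexicon()] object.
#' @param config An [eva_config()] list.
#' @return Data frame with columns \code{id}, \code{grade} (NA when
#'   absent) and the 42 feature columns in fixed order.
#' @export
extract_eva_table <- function(corpus, lexicon, config = eva_config()) {
  rows <- lapply(corpus, function(doc) {
    v <- extract_eva(doc, lexicon, config)
    cbind(data.frame(id = doc$id,
                     grade = if (is.null(doc$grade)) NA_real_ else doc$grade,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(v)))
  })
  do.call(rbind, rows)
}
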