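# Independent brute-force oracles. These re-derive every quantity with plain
# loops and literal formula transcriptions, sharing no code path with the
# package implementation.

oracle_sentence_score <- function(norms, lex, z = 0.8, z_ac = 0.25,
                                  negation_mode = "flip",
                                  denominator_mode = "linear",
                                  window_before = 5, window_after = 2,
                                  use_adversative = TRUE) {
  n <- length(norms)
  if (n == 0) return(0)
  total <- 0
  any_cluster <- FALSE
  for (i in seq_len(n)) {
    if (!norms[i] %in% names(lex$valence)) next
    any_cluster <- TRUE
    v <- unname(lex$valence[[norms[i]]])
    win <- setdiff(max(1, i - window_before):min(n, i + window_after), i)
    wn <- norms[win]
    n_neg <- sum(wn %in% lex$negators)
    n_amp <- sum(wn %in% lex$amplifiers)
    n_deamp <- sum(wn %in% lex$deamplifiers)
    n_ac <- sum(wn %in% lex$adversatives)
    w_neg <- n_neg %% 2
    w_amp <- (1 - w_neg) * z * n_amp
    w_deamp <- max(-1, -z * (w_neg * n_amp) - z * n_deamp)
    w_ac <- if (use_adversative) 1 + z_ac * n_ac else 1
    cs <- if (negation_mode == "nullify" && w_neg == 1) {
      0
    } else {
      w_ac * (1 + w_amp + w_deamp) * v * (-1)^(2 + w_neg)
    }
    total <- total + cs
  }
  if (!any_cluster) return(0)
  denom <- if (denominator_mode == "linear") n else sqrt(n)
  total / denom
}

# manual type-7 quantile so the oracle does not call quantile()
oracle_quantile <- function(v, p) {
  v <- sort(v)
  m <- length(v)
  if (m == 1) return(v)
  h <- (m - 1) * p + 1
  lo <- floor(h)
  v[lo] + (h - lo) * (v[min(lo + 1, m)] - v[lo])
}

oracle_flags <- function(x) {
  flags <- rep("none", length(x))
  pos <- x[x > 0]
  if (length(pos)) {
    thr <- oracle_quantile(pos, 0.75)
    for (i in seq_along(x)) if (x[i] > 0 && x[i] >= thr) flags[i] <- "happy"
  }
  neg <- x[x < 0]
  if (length(neg)) {
    thr <- oracle_quantile(neg, 0.25)
    for (i in seq_along(x)) if (x[i] < 0 && x[i] <= thr) flags[i] <- "sad"
  }
  flags
}

oracle_islands <- function(x, flags = oracle_flags(x)) {
  out <- list()
  i <- 1
  n <- length(x)
  while (i <= n) {
    if (flags[i] == "none") { i <- i + 1; next }
    j <- i
    while (j < n && flags[j + 1] == flags[i]) j <- j + 1
    ext <- i
    for (k in i:j) if (abs(x[k]) > abs(x[ext])) ext <- k
    out[[length(out) + 1]] <- list(sign = flags[i], start = i, end = j,
                                   length = j - i + 1, ext = ext)
    i <- j + 1
  }
  out
}

oracle_top_two <- function(isl, sgn) {
  mine <- Filter(function(a) a$sign == sgn, isl)
  if (length(mine) < 2) return(NULL)
  ord <- order(-vapply(mine, `[[`, 0, "length"),
               vapply(mine, `[[`, 0, "start"))
  mine[ord[1:2]]
}

oracle_features <- function(x, window = 3) {
  n <- length(x)
  feats <- c(AVG = if (n) sum(x) / n else 0)
  flags <- oracle_flags(x)
  isl <- oracle_islands(x, flags)
  longest <- function(sgn) {
    mine <- Filter(function(a) a$sign == sgn, isl)
    if (!length(mine)) return(NULL)
    ord <- order(-vapply(mine, `[[`, 0, "length"),
                 vapply(mine, `[[`, 0, "start"))
    mine[[ord[1]]]
  }
  hi <- longest("happy"); si <- longest("sad")
  feats["HI"] <- if (is.null(hi)) 0 else hi$length
  feats["SI"] <- if (is.null(si)) 0 else si$length
  nff <- 0
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      if ((x[i] > 0 && x[i + 1] < 0) || (x[i] < 0 && x[i + 1] > 0)) {
        nff <- nff + 1
      }
    }
  }
  feats["FF"] <- if (n) nff / n else 0
  feats["NFF"] <- nff
  feats["VAR"] <- if (n > 1) sum((x - sum(x) / n)^2) / n else 0
  pair <- function(sgn) {
    two <- oracle_top_two(isl, sgn)
    if (is.null(two)) return(c(0, 0))
    spread <- abs(two[[1]]$ext - two[[2]]$ext) / n
    a <- two[[if (two[[1]]$start < two[[2]]$start) 1 else 2]]
    b <- two[[if (two[[1]]$start < two[[2]]$start) 2 else 1]]
    between <- 0
    for (k in seq_len(n)) if (k > a$end && k < b$start) between <- between + 1
    c(spread, between)
  }
  h <- pair("happy"); s <- pair("sad")
  feats["HS"] <- h[1]; feats["TS"] <- s[1]
  feats["HMSS"] <- h[2]; feats["TMSS"] <- s[2]
  island_vals <- function(a) if (is.null(a)) numeric(0) else x[a$start:a$end]
  hv <- island_vals(hi); sv <- island_vals(si)
  feats["MAXHI"] <- if (length(hv)) max(hv) else 0
  feats["MINSI"] <- if (length(sv)) min(sv) else 0
  feats["HVAR"] <- if (length(hv) > 1) sum((hv - mean(hv))^2) / length(hv) else 0
  feats["SVAR"] <- if (length(sv) > 1) sum((sv - mean(sv))^2) / length(sv) else 0
  if (n <= 1) {
    feats["RMSE"] <- 0
  } else {
    h2 <- (window - 1) / 2
    sse <- 0
    for (i in seq_len(n)) {
      lo <- max(1, i - h2); hi2 <- min(n, i + h2)
      sm <- sum(x[lo:hi2]) / (hi2 - lo + 1)
      sse <- sse + (sm - x[i])^2
    }
    feats["RMSE"] <- sqrt(sse / n)
  }
  pp <- 0; np <- 0; spp <- 0; npp <- 0
  if (n >= 3) {
    for (i in 2:(n - 1)) {
      if (x[i] > x[i - 1] && x[i] > x[i + 1]) { pp <- pp + 1; spp <- spp + x[i] }
      if (x[i] < x[i - 1] && x[i] < x[i + 1]) { np <- np + 1; npp <- npp + x[i] }
    }
  }
  feats["PP"] <- pp; feats["NP"] <- np
  feats["PR"] <- if (np == 0) pp else pp / np
  feats["SPP"] <- spp; feats["NPP"] <- npp
  feats["APR"] <- if (npp == 0) spp else spp / abs(npp)
  feats[eva_feature_names()]
}

# random sentence builder over the demo lexicon vocabulary
random_norms <- function(n, rng_words) sample(rng_words, n, replace = TRUE)

oracle_vocab <- function(lex) {
  c(names(lex$valence), lex$negators, lex$amplifiers, lex$deamplifiers,
    lex$adversatives, c("the", "a", "we", "session", "today", "it", "was"))
}
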