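#' Specification of a synthetic sentiment series
#'
#' Describes a per-sentence score series with plantable structure: a
#' low-magnitude noise baseline, optional exact-zero (neutral) sentences,
#' injected sign flips, and happy/sad islands planted as contiguous spans
#' of extreme-magnitude scores. Planted amplitudes should sit well above
#' the baseline magnitude (the generator warns below 3 noise SDs) so the
#' extreme-quartile flags recover them.
#'
#' @param n_sentences Series length.
#' @param planted_islands List of lists with fields \code{sign}
#'   (\code{"happy"}/\code{"sad"}), \code{start} (1-based), \code{length},
#'   \code{amplitude} (> 0). Spans must be in bounds and non-overlapping.
#' @param flip_rate Probability in [0, 1] that a baseline score is forced
#'   to oppose the sign of its predecessor.
#' @param neutral_rate Fraction in [0, 1] of baseline positions set to
#'   exactly 0.
#' @param noise_sd Baseline score standard deviation (>= 0).
#' @param seed Integer seed.
#' @return List of class \code{series_spec}.
#' @export
series_spec <- function(n_sentences, planted_islands = list(),
                        flip_rate = 0, neutral_rate = 0, noise_sd = 0.05,
                        seed = 1L) {
  stopifnot(n_sentences >= 0, flip_rate >= 0, flip_rate <= 1,
            neutral_rate >= 0, neutral_rate <= 1, noise_sd >= 0)
  occupied <- rep(FALSE, n_sentences)
  for (isl in planted_islands) {
    stopifnot(isl$sign %in% c("happy", "sad"), isl$length >= 1,
              isl$amplitude > 0)
    span <- isl$start:(isl$start + isl$length - 1L)
    if (isl$start < 1 || max(span) > n_sentences) {
      stop("planted island span [", isl$start, ", ", max(span),
           "] is out of bounds")
    }
    if (any(occupied[span])) stop("planted island spans overlap")
    occupied[span] <- TRUE
  }
  structure(list(n_sentences = as.integer(n_sentences),
                 planted_islands = planted_islands,
                 flip_rate = flip_rate, neutral_rate = neutral_rate,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "series_spec")
}

#' Generate a sentiment series with planted structure
#'
#' Baseline scores are Normal(0, \code{noise_sd}) truncated to at most 1.5
#' SD in magnitude (sub-quartile relative to planted amplitudes); a
#' \code{neutral_rate} fraction of baseline positions is zeroed; sign flips
#' are injected at \code{flip_rate}; planted island spans are overwritten
#' with constant extreme-magnitude scores of the requested sign.
#' Reproducible under the spec seed.
#'
#' @param spec A [series_spec()].
#' @return List with \code{series} (unfiltered [sentiment_series()]) and
#'   \code{truth}: planted \code{hi}/\code{si} (longest planted run per
#'   sign, 0 when none), \code{nff} (sign-change count of the emitted
#'   series), \code{islands} (the planted list), \code{n}.
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "series_spec"))
  set.seed(spec$seed)
  n <- spec$n_sentences
  x <- rnorm(n, 0, spec$noise_sd)
  x <- pmin(pmax(x, -1.5 * spec$noise_sd), 1.5 * spec$noise_sd)
  planted <- rep(FALSE, n)
  for (isl in spec$planted_islands) {
    planted[isl$start:(isl$start + isl$length - 1L)] <- TRUE
  }
  # neutral sentences among the baseline
  base_idx <- which(!planted)
  n_neutral <- round(spec$neutral_rate * length(base_idx))
  if (n_neutral > 0) {
    x[sample(base_idx, n_neutral)] <- 0
  }
  # injected sign flips on the baseline
  if (spec$flip_rate > 0 && n >= 2) {
    for (i in 2:n) {
      if (planted[i] || x[i] == 0 || x[i - 1] == 0) next
      if (runif(1) < spec$flip_rate && sign(x[i]) == sign(x[i - 1])) {
        x[i] <- -x[i]
      }
    }
  }
  # planted islands overwrite their spans
  for (isl in spec$planted_islands) {
    span <- isl$start:(isl$start + isl$length - 1L)
    sgn <- if (isl$sign == "happy") 1 else -1
    if (isl$amplitude < 3 * spec$noise_sd) {
      warning("planted amplitude ", isl$amplitude,
              " is close to the noise floor; recovery is not guaranteed")
    }
    # constant amplitude across the span keeps every member at or above the
    # extreme-quartile threshold, so planted length is recovered exactly
    x[span] <- sgn * isl$amplitude
  }
  hi <- 0L; si <- 0L
  for (isl in spec$planted_islands) {
    if (isl$sign == "happy") hi <- max(hi, isl$length)
    if (isl$sign == "sad") si <- max(si, isl$length)
  }
  s <- sign(x)
  nff <- if (n >= 2) sum(s[-n] * s[-1] < 0) else 0L
  list(series = sentiment_series(x, "unfiltered"),
       truth = list(hi = as.integer(hi), si = as.integer(si),
                    nff = as.integer(nff),
                    islands = spec$planted_islands, n = n))
}

#' Sentence templates with analytically known scores
#'
#' Fixed single-sentence templates, one per class, whose sentence scores
#' under [demo_lexicon()] with default config are known exactly: strong
#' and mild positive/negative plus a neutral (zero-score) template. The
#' strong templates pair an amplifier with a maximal-valence word so their
#' scores clear the extreme-quartile threshold over the mild ones.
#'
#' @return Named list of template sentences with their class.
#' @export
journal_templates <- function() {
  list(
    strong_positive = "This was a very excellent session.",   # delta = 0.30
    mild_positive = "The session was good overall.",          # delta = 0.10
    strong_negative = "This was a very awful session.",       # delta = -0.30
    mild_negative = "The session was bad overall.",           # delta = -0.10
    neutral = "We met in the lab today."                      # delta = 0
  )
}

#' Render a sentiment series as a templated journal document
#'
#' Emits one template sentence per series element whose scored sign matches
#' the element's sign: zero scores map to the neutral template, magnitudes
#' at or above \code{strong_threshold} to the strong template of the
#' matching sign, and smaller magnitudes to the mild template. Scoring the
#' resulting document reproduces the series' sign pattern exactly.
#'
#' @param series Numeric vector or [sentiment_series()].
#' @param templates Template list as from [journal_templates()].
#' @param strong_threshold Magnitude at which the strong template is used.
#' @param id Document id.
#' @param grade Optional grade to attach.
#' @return An \code{eva_document}.
#' @export
generate_journal <- function(series, templates = journal_templates(),
                             strong_threshold = 0.5, id = "synthetic",
                             grade = NULL) {
  need <- c("strong_positive", "mild_positive", "strong_negative",
            "mild_negative", "neutral")
  missing <- setdiff(need, names(templates))
  if (length(missing)) {
    stop("missing template class(es): ", paste(missing, collapse = ", "))
  }
  x <- as.numeric(series)
  pick <- vapply(x, function(s) {
    if (s == 0) "neutral"
    else if (s > 0 && abs(s) >= strong_threshold) "strong_positive"
    else if (s > 0) "mild_positive"
    else if (abs(s) >= strong_threshold) "strong_negative"
    else "mild_negative"
  }, character(1))
  text <- paste(unlist(templates[pick]), collapse = " ")
  if (!length(x)) text <- ""
  as_document(id, text, grade = grade)
}

#' Specification of a graded synthetic cohort
#'
#' Each document gets one planted happy island whose length fraction drives
#' the grade through a linear link:
#' \code{grade = intercept + slope * (HI / n) + Normal(0, grade_noise_sd)},
#' clipped to \code{grade_range}. Defaults emulate a reflective-journal
#' cohort: 40-sentence journals, island lengths 2--32, link 60 + 40 *
#' fraction, grade noise SD 2.
#'
#' @param n_docs Number of documents (>= 1).
#' @param n_sentences Sentences per document.
#' @param grade_link Numeric \code{c(intercept, slope)} on the happy-island
#'   fraction.
#' @param grade_noise_sd Grade noise SD (>= 0).
#' @param grade_range Length-2 increasing numeric clip range.
#' @param hi_range Integer range of planted island lengths.
#' @param noise_sd Baseline score noise SD.
#' @param neutral_rate Neutral-sentence fraction of the baseline.
#' @param seed Integer seed.
#' @return List of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_docs, n_sentences = 40L,
                        grade_link = c(60, 40), grade_noise_sd = 2,
                        grade_range = c(40, 100), hi_range = c(2L, 32L),
                        noise_sd = 0.05, neutral_rate = 0.1, seed = 1L) {
  stopifnot(n_docs >= 1, n_sentences >= max(hi_range) + 2,
            length(grade_link) == 2, grade_noise_sd >= 0,
            length(grade_range) == 2, grade_range[1] < grade_range[2],
            hi_range[1] >= 1, hi_range[1] <= hi_range[2])
  structure(list(n_docs = as.integer(n_docs),
                 n_sentences = as.integer(n_sentences),
                 grade_link = as.numeric(grade_link),
                 grade_noise_sd = grade_noise_sd,
                 grade_range = as.numeric(grade_range),
                 hi_range = as.integer(hi_range),
                 noise_sd = noise_sd, neutral_rate = neutral_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a graded synthetic cohort
#'
#' Per document: draw a planted happy-island length, synthesize the score
#' series (negative/neutral baseline so the island is the only positive
#' run), render it as a templated journal, and assign the linked grade.
#' Baseline scores are drawn negative so that the planted island is exactly
#' the set of positive sentences, making the island length recoverable by
#' feature extraction.
#'
#' @param spec A [cohort_spec()].
#' @return List with \code{documents} (list of graded
#'   \code{eva_document}s) and \code{truth} data frame (\code{id},
#'   \code{hi}, \code{hi_fraction}, \code{grade}).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_sentences
  docs <- vector("list", spec$n_docs)
  truth <- data.frame(id = character(spec$n_docs), hi = integer(spec$n_docs),
                      hi_fraction = numeric(spec$n_docs),
                      grade = numeric(spec$n_docs), stringsAsFactors = FALSE)
  for (d in seq_len(spec$n_docs)) {
    len <- sample(seq(spec$hi_range[1], spec$hi_range[2]), 1L)
    start <- sample(seq_len(n - len + 1L), 1L)
    # negative baseline with neutral gaps; the island is the sole positive run
    x <- -abs(rnorm(n, 0, spec$noise_sd))
    x <- pmax(x, -1.5 * spec$noise_sd)
    neutral_idx <- which(runif(n) < spec$neutral_rate)
    x[neutral_idx] <- 0
    span <- start:(start + len - 1L)
    x[span] <- runif(len, 0.85, 0.999)
    x[span[ceiling(len / 2)]] <- 1
    frac <- len / n
    grade <- spec$grade_link[1] + spec$grade_link[2] * frac +
      rnorm(1, 0, spec$grade_noise_sd)
    grade <- min(max(grade, spec$grade_range[1]), spec$grade_range[2])
    id <- sprintf("doc%03d", d)
    docs[[d]] <- generate_journal(x, id = id, grade = grade)
    truth[d, ] <- list(id, len, frac, grade)
  }
  list(documents = docs, truth = truth)
}

#' Write a corpus to JSON-lines
#'
#' One record per document with \code{id}, \code{text} (sentence surfaces
#' re-joined) and \code{grade} when present; readable back with
#' [load_corpus()].
#'
#' @param corpus List of \code{eva_document}s.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(corpus, function(doc) {
    rec <- list(id = doc$id,
                text = paste(vapply(doc$sentences, `[[`, "", "text"),
                             collapse = " "))
    if (!is.null(doc$grade)) rec$grade <- doc$grade
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
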