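resolve_sentence <- function(sentence) {
  if (inherits(sentence, "eva_sentence")) return(sentence)
  if (is.character(sentence) && length(sentence) == 1L) {
    return(new_sentence(sentence, index = 0L))
  }
  stop("sentence must be an eva_sentence or a character scalar")
}

#' Find polar clusters in a sentence
#'
#' A polar cluster is the context window around one polarized word (the
#' pivot): by default the 5 tokens before and 2 tokens after, clipped at the
#' sentence boundaries. Within the window (pivot excluded) the four shifter
#' categories are counted. Every token whose normalized form is a valence
#' key yields one cluster; clusters from nearby pivots may overlap and each
#' contributes independently to the sentence score.
#'
#' @param sentence An \code{eva_sentence} or character scalar.
#' @param lexicon An [lexicon()] object.
#' @param config An [eva_config()] list (\code{window_before},
#'   \code{window_after}).
#' @return List of clusters; each a list with \code{pivot_index} (1-based
#'   token position), \code{valence}, \code{window} (\code{c(start, end)}),
#'   and counts \code{n_neg}, \code{n_amp}, \code{n_deamp}, \code{n_ac}.
#' @export
find_polar_clusters <- function(sentence, lexicon, config = eva_config()) {
  sentence <- resolve_sentence(sentence)
  norms <- sentence$tokens$norm
  n <- length(norms)
  pivots <- which(norms %in% names(lexicon$valence))
  lapply(pivots, function(i) {
    lo <- max(1L, i - config$window_before)
    hi <- min(n, i + config$window_after)
    win <- setdiff(seq(lo, hi), i)
    wn <- norms[win]
    list(pivot_index = i,
         valence = unname(lexicon$valence[[norms[i]]]),
         window = c(lo, hi),
         n_neg = sum(wn %in% lexicon$negators),
         n_amp = sum(wn %in% lexicon$amplifiers),
         n_deamp = sum(wn %in% lexicon$deamplifiers),
         n_ac = sum(wn %in% lexicon$adversatives))
  })
}

#' Negation parity of a polar cluster
#'
#' The count of negators inside the cluster window, modulo 2: 1 when an odd
#' number of negators leaves a net negation effect on the polarized word, 0
#' when negators cancel pairwise (or are absent).
#'
#' @param cluster A cluster from [find_polar_clusters()], or a non-negative
#'   negator count.
#' @return 0 or 1.
#' @export
negation_parity <- function(cluster) {
  n_neg <- if (is.list(cluster)) cluster$n_neg else cluster
  stopifnot(is.numeric(n_neg), n_neg >= 0)
  as.integer(n_neg %% 2)
}

#' Shifter weights for a polar cluster
#'
#' Amplification, de-amplification and adversative weights. With negation
#' parity \eqn{W_{neg}}, amplifier count \eqn{n_{amp}}, de-amplifier count
#' \eqn{n_{deamp}} and adversative count \eqn{n_{ac}}:
#' \deqn{w_{amp} = (1 - W_{neg}) \cdot z \cdot n_{amp}}
#' \deqn{w_{deamp} = \max(-1,\; -z \cdot W_{neg} \cdot n_{amp} - z \cdot n_{deamp})}
#' \deqn{w_{ac} = 1 + z_{ac} \cdot n_{ac}}
#' A negated amplifier switches role and attenuates; the total attenuation
#' is floored at \eqn{-1} so a cluster is never sign-flipped by
#' de-amplification alone.
#'
#' @param cluster A cluster from [find_polar_clusters()].
#' @param lexicon An [lexicon()] object carrying \code{z}, \code{z_ac}.
#' @param config An [eva_config()] list; \code{z}/\code{z_ac} here override
#'   the lexicon's.
#' @return Named list \code{w_amp}, \code{w_deamp}, \code{w_ac}.
#' @export
shifter_weights <- function(cluster, lexicon, config = eva_config()) {
  z <- config$z %||% lexicon$z
  z_ac <- config$z_ac %||% lexicon$z_ac
  w_neg <- negation_parity(cluster)
  list(
    w_amp = (1 - w_neg) * z * cluster$n_amp,
    w_deamp = max(-1, -z * (w_neg * cluster$n_amp) - z * cluster$n_deamp),
    w_ac = if (isTRUE(config$use_adversative)) 1 + z_ac * cluster$n_ac else 1
  )
}

#' Score one polar cluster
#'
#' \deqn{C' = w_{ac} (1 + w_{amp} + w_{deamp}) \cdot v \cdot (-1)^{2 + W_{neg}}}
#' where \eqn{v} is the pivot valence. In \code{"flip"} mode an odd number
#' of negators reverses the sign; in \code{"nullify"} mode it zeroes the
#' cluster instead.
#'
#' @param valence Pivot valence.
#' @param w_neg Negation parity, 0 or 1.
#' @param w_amp,w_deamp,w_ac Weights from [shifter_weights()].
#' @param negation_mode \code{"flip"} or \code{"nullify"}.
#' @return Numeric cluster score.
#' @export
cluster_score <- function(valence, w_neg, w_amp = 0, w_deamp = 0, w_ac = 1,
                          negation_mode = c("flip", "nullify")) {
  negation_mode <- match.arg(negation_mode)
  stopifnot(is.finite(valence), w_neg %in% c(0, 1),
            is.finite(w_amp), is.finite(w_deamp), is.finite(w_ac))
  if (negation_mode == "nullify" && w_neg == 1) return(0)
  w_ac * (1 + w_amp + w_deamp) * valence * (-1)^(2 + w_neg)
}

#' Sentence sentiment score
#'
#' Sums the scores of all polar clusters in the sentence and normalizes by
#' the sentence length: \eqn{\delta = \sum C' / \omega} (default), or by
#' \eqn{\sqrt{\omega}} when \code{denominator_mode = "sqrt"}. A sentence
#' with no tokens or no polar clusters scores 0.
#'
#' @inheritParams find_polar_clusters
#' @return List of class \code{eva_sentence_score}: \code{delta},
#'   \code{omega}, \code{cluster_scores}.
#' @export
#' @examples
#' sentence_score("this was a very good day", demo_lexicon())$delta
sentence_score <- function(sentence, lexicon, config = eva_config()) {
  sentence <- resolve_sentence(sentence)
  omega <- sentence$omega
  clusters <- find_polar_clusters(sentence, lexicon, config)
  cs <- vapply(clusters, function(cl) {
    w <- shifter_weights(cl, lexicon, config)
    cluster_score(cl$valence, negation_parity(cl), w$w_amp, w$w_deamp,
                  w$w_ac, config$negation_mode)
  }, numeric(1))
  delta <- if (omega == 0L || length(cs) == 0L) {
    0
  } else {
    denom <- switch(config$denominator_mode, linear = omega, sqrt = sqrt(omega))
    sum(cs) / denom
  }
  structure(list(delta = delta, omega = omega, cluster_scores = cs),
            class = "eva_sentence_score")
}

#' Score every sentence of a document
#'
#' Applies [sentence_score()] to each sentence in order, returning the
#' unfiltered per-sentence sentiment series.
#'
#' @param doc An \code{eva_document}.
#' @param lexicon An [lexicon()] object.
#' @param config An [eva_config()] list.
#' @return A [sentiment_series()] of variant \code{"unfiltered"}.
#' @export
score_document <- function(doc, lexicon, config = eva_config()) {
  stopifnot(inherits(doc, "eva_document"))
  scores <- vapply(doc$sentences, function(s) {
    sentence_score(s, lexicon, config)$delta
  }, numeric(1))
  sentiment_series(scores, variant = "unfiltered")
}
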