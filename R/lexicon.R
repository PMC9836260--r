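#' Construct a sentiment lexicon
#'
#' A lexicon pairs polarized words with valences in \eqn{[-1, 1]} and holds
#' the four valence-shifter categories: negators (flip or nullify polarity),
#' amplifiers (augment intensity), de-amplifiers (attenuate intensity), and
#' adversative conjunctions (contrast markers). Shifter weights \code{z}
#' (default 0.8) and \code{z_ac} (default 0.25) travel with the lexicon and
#' can be overridden per run through [eva_config()].
#'
#' All entries are matched case-insensitively against the normalized token
#' form. A word may hold only one role: valence keys and the four shifter
#' sets must be pairwise disjoint.
#'
#' @param valence Named numeric vector, word -> valence in \eqn{[-1, 1]}.
#' @param negators,amplifiers,deamplifiers,adversatives Character vectors.
#' @param z Amplification/de-amplification weight, default 0.8.
#' @param z_ac Adversative-conjunction weight, default 0.25.
#' @return Object of class \code{eva_lexicon}.
#' @export
lexicon <- function(valence, negators = character(0),
                    amplifiers = character(0), deamplifiers = character(0),
                    adversatives = character(0), z = 0.8, z_ac = 0.25) {
  stopifnot(is.numeric(valence), !is.null(names(valence)))
  names(valence) <- tolower(names(valence))
  if (any(!is.finite(valence)) || any(abs(valence) > 1)) {
    stop("valences must be finite and within [-1, 1]")
  }
  sets <- list(polar = names(valence),
               negator = tolower(negators),
               amplifier = tolower(amplifiers),
               deamplifier = tolower(deamplifiers),
               adversative = tolower(adversatives))
  all_words <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_words)) {
    dup <- unique(all_words[duplicated(all_words)])
    stop("words assigned to more than one lexicon role: ",
         paste(dup, collapse = ", "))
  }
  stopifnot(is.numeric(z), length(z) == 1L, is.finite(z),
            is.numeric(z_ac), length(z_ac) == 1L, is.finite(z_ac))
  structure(list(valence = valence,
                 negators = sets$negator,
                 amplifiers = sets$amplifier,
                 deamplifiers = sets$deamplifier,
                 adversatives = sets$adversative,
                 z = z, z_ac = z_ac),
            class = "eva_lexicon")
}

#' @export
print.eva_lexicon <- function(x, ...) {
  cat("<eva_lexicon>", length(x$valence), "polarized words |",
      length(x$negators), "negators,", length(x$amplifiers), "amplifiers,",
      length(x$deamplifiers), "de-amplifiers,", length(x$adversatives),
      "adversatives | z =", x$z, ", z_ac =", x$z_ac, "\n")
  invisible(x)
}

#' Read a lexicon from CSV
#'
#' Expected columns: \code{word}, \code{role} in \{polar, negator,
#' amplifier, deamplifier, adversative\}, and \code{valence} (used on polar
#' rows only).
#'
#' @param path CSV file path.
#' @param z,z_ac Shifter weights attached to the returned lexicon.
#' @return Object of class \code{eva_lexicon}.
#' @export
read_lexicon <- function(path, z = 0.8, z_ac = 0.25) {
  if (!file.exists(path)) stop("lexicon file does not exist: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("word", "role")
  if (!all(need %in% names(tab))) {
    stop("lexicon CSV must have columns 'word' and 'role'")
  }
  bad <- setdiff(unique(tab$role),
                 c("polar", "negator", "amplifier", "deamplifier",
                   "adversative"))
  if (length(bad)) stop("unknown lexicon role(s): ", paste(bad, collapse = ", "))
  pol <- tab[tab$role == "polar", , drop = FALSE]
  if (nrow(pol) && !"valence" %in% names(tab)) {
    stop("lexicon CSV with polar rows must have a 'valence' column")
  }
  val <- as.numeric(pol$valence)
  names(val) <- pol$word
  lexicon(valence = val,
          negators = tab$word[tab$role == "negator"],
          amplifiers = tab$word[tab$role == "amplifier"],
          deamplifiers = tab$word[tab$role == "deamplifier"],
          adversatives = tab$word[tab$role == "adversative"],
          z = z, z_ac = z_ac)
}

#' Built-in demonstration lexicon
#'
#' A compact general-purpose lexicon suitable for examples, tests and the
#' synthetic-corpus templates. Also shipped as
#' \code{inst/extdata/demo_lexicon.csv}.
#'
#' @inheritParams read_lexicon
#' @return Object of class \code{eva_lexicon}.
#' @export
demo_lexicon <- function(z = 0.8, z_ac = 0.25) {
  lexicon(
    valence = c(
      excellent = 1, wonderful = 0.9, love = 0.8, great = 0.75,
      happy = 0.75, enjoyed = 0.6, good = 0.5, fine = 0.4, useful = 0.4,
      interesting = 0.35, okay = 0.2,
      awful = -1, terrible = -0.9, hate = -0.8, horrible = -0.75,
      sad = -0.75, failed = -0.6, bad = -0.5, poor = -0.4,
      frustrating = -0.5, boring = -0.35, tired = -0.3
    ),
    negators = c("not", "never", "no", "cannot", "didnt", "wasnt"),
    amplifiers = c("very", "really", "extremely", "so", "truly"),
    deamplifiers = c("barely", "slightly", "somewhat", "rather", "hardly"),
    adversatives = c("but", "however", "although", "though"),
    z = z, z_ac = z_ac
  )
}
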