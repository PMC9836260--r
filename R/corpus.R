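# Default abbreviation guard for the rule-based sentence segmenter.
# Entries are lower-case and compared without their trailing period.
eva_abbreviations <- c(
  "dr", "mr", "mrs", "ms", "prof", "st", "etc", "vs", "fig", "eq",
  "e.g", "i.e", "no", "approx", "dept"
)

#' Split running text into sentences
#'
#' Deterministic rule-based segmentation: a run of terminal punctuation
#' (\code{.}, \code{!} or \code{?}) followed by whitespace (or end of text)
#' closes a sentence, unless the word immediately before a period is on the
#' abbreviation list. Whitespace-only segments are dropped. An external
#' segmenter can be plugged in via \code{segmenter}; it must map a character
#' scalar to a character vector of sentence texts.
#'
#' @param text Character scalar (may be empty).
#' @param abbreviations Character vector of abbreviations (without the
#'   trailing period, case-insensitive) that suppress a sentence break.
#' @param segmenter Optional function \code{text -> character vector}
#'   replacing the built-in rules.
#' @return Character vector of sentence texts, in document order.
#' @export
#' @examples
#' segment_sentences("I tried. It failed!")
#' segment_sentences("Dr. Tan helped me.")
segment_sentences <- function(text, abbreviations = eva_abbreviations,
                              segmenter = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!is.null(segmenter)) {
    out <- segmenter(text)
    return(out[nzchar(trimws(out))])
  }
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))

  abbreviations <- tolower(sub("\\.$", "", abbreviations))
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  breaks <- integer(0)
  i <- 1L
  while (i <= n) {
    if (chars[i] %in% c(".", "!", "?")) {
      j <- i
      while (j < n && chars[j + 1L] %in% c(".", "!", "?")) j <- j + 1L
      at_end <- j == n || grepl("\\s", chars[j + 1L])
      if (at_end) {
        guard <- FALSE
        if (all(chars[i:j] == ".")) {
          # word immediately preceding the period
          k <- i - 1L
          while (k >= 1L && !grepl("\\s", chars[k])) k <- k - 1L
          word <- paste(chars[seq(k + 1L, i - 1L)[seq_len(max(0L, i - 1L - k))]],
                        collapse = "")
          word <- tolower(gsub("^[[:punct:]]+", "", word))
          word <- sub("\\.$", "", word)
          if (word %in% abbreviations) guard <- TRUE
        }
        if (!guard) breaks <- c(breaks, j)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  keep <- starts <= ends
  segs <- vapply(which(keep), function(s) {
    trimws(paste(chars[starts[s]:ends[s]], collapse = ""))
  }, character(1))
  segs[nzchar(segs)]
}

#' Tokenize one sentence
#'
#' Whitespace split; each surface token is paired with a normalized form
#' (\code{norm}): lower-cased with leading and trailing punctuation stripped.
#' Lexicon lookup is performed on \code{norm}. The sentence word count
#' \eqn{\omega} is the number of tokens, including punctuation-only and
#' numeric tokens.
#'
#' @param text Character scalar.
#' @return A data frame with columns \code{surface} and \code{norm}, one row
#'   per token in order.
#' @export
#' @examples
#' tokenize("not good.")
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) {
    return(data.frame(surface = character(0), norm = character(0),
                      stringsAsFactors = FALSE))
  }
  surface <- strsplit(trimws(text), "\\s+")[[1]]
  norm <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", tolower(surface))
  data.frame(surface = surface, norm = norm, stringsAsFactors = FALSE)
}

new_sentence <- function(text, index, tokens = tokenize(text)) {
  structure(list(text = text, tokens = tokens, index = index,
                 omega = nrow(tokens)),
            class = "eva_sentence")
}

#' Build a document from raw text
#'
#' Segments and tokenizes \code{text} into an \code{eva_document}: an ordered
#' list of tokenized sentences with an id and an optional numeric grade
#' (0--100 scale). Sentences with fewer than \code{min_sentence_tokens}
#' tokens are dropped.
#'
#' @param id Character id.
#' @param text Character scalar, the document body.
#' @param grade Optional finite numeric grade.
#' @param metadata Named list of string metadata.
#' @param config An [eva_config()] list (uses \code{abbreviations},
#'   \code{min_sentence_tokens}).
#' @return An object of class \code{eva_document}.
#' @export
as_document <- function(id, text, grade = NULL, metadata = list(),
                        config = eva_config()) {
  if (!is.null(grade)) {
    grade <- as.numeric(grade)
    if (length(grade) != 1L || !is.finite(grade)) {
      stop("grade must be a single finite number, got: ", grade)
    }
  }
  texts <- segment_sentences(text, abbreviations = config$abbreviations)
  sentences <- lapply(seq_along(texts), function(i) {
    new_sentence(texts[i], index = i - 1L)
  })
  keep <- vapply(sentences, function(s) s$omega >= config$min_sentence_tokens,
                 logical(1))
  sentences <- sentences[keep]
  for (i in seq_along(sentences)) sentences[[i]]$index <- i - 1L
  structure(list(id = as.character(id), sentences = sentences,
                 grade = grade, metadata = metadata),
            class = "eva_document")
}

#' @export
print.eva_document <- function(x, ...) {
  cat("<eva_document> id:", x$id,
      "| sentences:", length(x$sentences),
      if (!is.null(x$grade)) paste("| grade:", x$grade) else "",
      "\n")
  invisible(x)
}

#' Load a corpus of documents
#'
#' Two on-disk layouts are supported: \code{"jsonl"} (one JSON record per
#' line with fields \code{id}, \code{text} and optional numeric
#' \code{grade}) and \code{"text-dir"} (a directory of UTF-8 \code{.txt}
#' files, one document each, id taken from the file name). Input order is
#' preserved; for \code{text-dir} files are taken in lexicographic order.
#'
#' @param path File (jsonl) or directory (text-dir).
#' @param format One of \code{"jsonl"}, \code{"text-dir"}.
#' @param config An [eva_config()] list.
#' @return List of \code{eva_document} objects.
#' @export
load_corpus <- function(path, format = c("jsonl", "text-dir"),
                        config = eva_config()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input path does not exist: ", path)
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    docs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) {
                        stop("malformed JSON record at line ", i, ": ",
                             conditionMessage(e), call. = FALSE)
                      })
      if (is.null(rec$id)) stop("record at line ", i, " is missing 'id'")
      if (is.null(rec$text)) stop("record at line ", i, " is missing 'text'")
      docs[[i]] <- as_document(rec$id, rec$text, grade = rec$grade,
                               config = config)
    }
    docs
  } else {
    if (!dir.exists(path)) stop("text-dir input must be a directory: ", path)
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    lapply(files, function(f) {
      as_document(sub("\\.txt$", "", basename(f)),
                  paste(readLines(f, encoding = "UTF-8", warn = FALSE),
                        collapse = "\n"),
                  config = config)
    })
  }
}
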