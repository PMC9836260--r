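resolve_lexicon <- function(path, config) {
  if (is.null(path)) demo_lexicon() else read_lexicon(path)
}

log_run <- function(subcommand, config) {
  message(sprintf("[emovar %s] %s | seed=%s | config=%s",
                  as.character(packageVersion("emovar")), subcommand,
                  config$seed, config_hash(config)))
}

#' Run a pipeline subcommand
#'
#' Ties the modules into five reproducible subcommands writing their
#' artifacts to disk:
#' \describe{
#'   \item{score}{read a corpus, write per-sentence scores
#'     (\code{output}: CSV with id, sentence index, delta).}
#'   \item{extract}{read a corpus, write the feature table
#'     (\code{output}: CSV with id, grade and the 42 feature columns).}
#'   \item{train}{read a feature CSV, run K-fold CV, write a JSON report
#'     (\code{report}) and per-document predictions (\code{predictions}).}
#'   \item{evaluate}{read a predictions CSV, write threshold-rule
#'     precision/recall/F1 JSON (\code{report}).}
#'   \item{simulate}{generate a graded synthetic cohort, write it as
#'     JSON-lines (\code{output}) plus its ground truth (\code{truth}).}
#' }
#' Every run logs the package version, seed and a hash of the fully
#' resolved config. Identical config and seed give byte-identical outputs.
#'
#' @param subcommand One of \code{"score"}, \code{"extract"},
#'   \code{"train"}, \code{"evaluate"}, \code{"simulate"}.
#' @param config An [eva_config()] list.
#' @param input Corpus path (score/extract).
#' @param format Corpus format, \code{"jsonl"} or \code{"text-dir"}.
#' @param lexicon_path Lexicon CSV; \code{NULL} uses [demo_lexicon()].
#' @param output Main output path (score/extract/simulate).
#' @param features Feature CSV path (train).
#' @param report JSON report path (train/evaluate).
#' @param predictions Predictions CSV path (train: written; evaluate:
#'   read).
#' @param truth Ground-truth CSV path (simulate).
#' @param n_docs Cohort size (simulate), default 50.
#' @return Invisible named list of the paths written.
#' @export
run_pipeline <- function(subcommand = c("score", "extract", "train",
                                        "evaluate", "simulate"),
                         config = eva_config(), input = NULL,
                         format = "jsonl", lexicon_path = NULL,
                         output = NULL, features = NULL, report = NULL,
                         predictions = NULL, truth = NULL, n_docs = 50L) {
  subcommand <- match.arg(subcommand)
  log_run(subcommand, config)
  written <- list()

  if (subcommand %in% c("score", "extract")) {
    stopifnot(!is.null(input), !is.null(output))
    lex <- resolve_lexicon(lexicon_path, config)
    corpus <- load_corpus(input, format, config)
    if (subcommand == "score") {
      rows <- do.call(rbind, lapply(corpus, function(doc) {
        s <- score_document(doc, lex, config)
        if (!length(s)) return(NULL)
        data.frame(id = doc$id, sentence = seq_along(s) - 1L,
                   delta = as.numeric(s), stringsAsFactors = FALSE)
      }))
      if (is.null(rows)) {
        rows <- data.frame(id = character(0), sentence = integer(0),
                           delta = numeric(0))
      }
      write.csv(rows, output, row.names = FALSE)
    } else {
      tab <- extract_eva_table(corpus, lex, config)
      write.csv(tab, output, row.names = FALSE)
    }
    written$output <- output
  } else if (subcommand == "train") {
    stopifnot(!is.null(features), !is.null(report))
    tab <- read.csv(features, stringsAsFactors = FALSE)
    feat_cols <- setdiff(names(tab), c("id", "grade"))
    if (anyNA(tab$grade)) stop("train requires a grade for every document")
    cv <- train_predict_cv(as.matrix(tab[, feat_cols]), tab$grade, config)
    cm <- confusion_counts(cv$predictions$predicted, cv$predictions$actual,
                           config$class_mu, config$class_sigma)
    f1 <- f1_metrics(cm[["TP"]], cm[["FP"]], cm[["FN"]])
    sel <- drop_one_selection(as.matrix(tab[, feat_cols]), tab$grade,
                              seed = config$seed)
    rep_obj <- list(K = cv$K, fold_mape = cv$fold_mape, mape = cv$mape,
                    precision = f1$precision, recall = f1$recall,
                    F1 = f1$F1, confusion = as.list(cm),
                    chosen_features = sel$ranking[seq_len(sel$k)],
                    seed = config$seed, config_hash = config_hash(config))
    jsonlite::write_json(rep_obj, report, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written$report <- report
    if (!is.null(predictions)) {
      pred <- cbind(id = tab$id, cv$predictions[c("fold", "actual",
                                                  "predicted")])
      write.csv(pred, predictions, row.names = FALSE)
      written$predictions <- predictions
    }
  } else if (subcommand == "evaluate") {
    stopifnot(!is.null(predictions), !is.null(report))
    pred <- read.csv(predictions, stringsAsFactors = FALSE)
    stopifnot(all(c("actual", "predicted") %in% names(pred)))
    cm <- confusion_counts(pred$predicted, pred$actual,
                           config$class_mu, config$class_sigma)
    f1 <- f1_metrics(cm[["TP"]], cm[["FP"]], cm[["FN"]])
    jsonlite::write_json(c(f1, list(confusion = as.list(cm))), report,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written$report <- report
  } else { # simulate
    stopifnot(!is.null(output))
    cohort <- generate_cohort(cohort_spec(n_docs, seed = config$seed))
    write_corpus_jsonl(cohort$documents, output)
    written$output <- output
    if (!is.null(truth)) {
      write.csv(cohort$truth, truth, row.names = FALSE)
      written$truth <- truth
    }
  }
  invisible(written)
}
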