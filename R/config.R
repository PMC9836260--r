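eva_config_defaults <- function() {
  list(
    # corpus handling
    abbreviations = eva_abbreviations,
    min_sentence_tokens = 1L,
    # sentence scoring
    z = NULL,                 # NULL -> use the lexicon's z
    z_ac = NULL,              # NULL -> use the lexicon's z_ac
    negation_mode = "flip",   # "flip" or "nullify"
    denominator_mode = "linear", # "linear" (omega) or "sqrt" (sqrt(omega))
    window_before = 5L,
    window_after = 2L,
    use_adversative = TRUE,
    # feature extraction
    neutral_tol = 1e-12,
    smoothing_window = 3L,
    # grade model
    depth = 25L,
    alpha = 1e-5,
    max_iter = 200L,
    tol = 1e-3,
    dropout_rate = 0.2,
    learning_rate = 0.01,
    momentum = 0.9,
    batch_size = 32L,
    k_folds = 40L,
    holdout_fraction = 0.2,
    mask_mu = 76.4,
    mask_sigma = 5.16,
    use_gaussian_mask = TRUE,
    class_mu = 76,
    class_sigma = 5,
    seed = 7L
  )
}

#' Run configuration with documented defaults
#'
#' Collects every tunable of the scoring, feature and model stages in one
#' flat list. Unknown keys are rejected. Defaults: shifter weights
#' \code{z = 0.8}, \code{z_ac = 0.25} (taken from the lexicon unless
#' overridden here); negation flips polarity (\code{negation_mode =
#' "flip"}; \code{"nullify"} zeroes negated clusters instead); sentence
#' scores divide by word count (\code{denominator_mode = "linear"},
#' \code{"sqrt"} divides by its square root); shifters act in a window of 5
#' tokens before to 2 after each polarized word. The MLP defaults are 25
#' hidden layers, ReLU, SGD with momentum, L2 penalty 1e-5, at most 200
#' epochs, loss tolerance 1e-3, dropout 0.2 on alternating layers;
#' cross-validation uses \code{k_folds = 40} and the Gaussian grade mask
#' (\code{mask_mu = 76.4}, \code{mask_sigma = 5.16}) as training sample
#' weights.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of class \code{eva_config}.
#' @export
#' @examples
#' cfg <- eva_config(negation_mode = "nullify", depth = 3)
eva_config <- function(...) {
  defaults <- eva_config_defaults()
  override <- list(...)
  if (length(override)) {
    nm <- names(override)
    if (is.null(nm) || any(!nzchar(nm))) stop("config overrides must be named")
    unknown <- setdiff(nm, names(defaults))
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
    defaults[nm] <- override
  }
  cfg <- defaults
  if (!cfg$negation_mode %in% c("flip", "nullify")) {
    stop("negation_mode must be 'flip' or 'nullify'")
  }
  if (!cfg$denominator_mode %in% c("linear", "sqrt")) {
    stop("denominator_mode must be 'linear' or 'sqrt'")
  }
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) {
    stop("dropout_rate must lie in [0, 1)")
  }
  w <- cfg$smoothing_window
  if (w < 1 || w %% 2 == 0) stop("smoothing_window must be a positive odd count")
  structure(cfg, class = "eva_config")
}

#' Read a flat key-value config file
#'
#' YAML mapping of config keys to values; keys must be known to
#' [eva_config()]. Values given in \code{...} take precedence over the file,
#' which takes precedence over the defaults.
#'
#' @param path YAML file of flat key: value pairs (optional, NULL for none).
#' @param ... Named overrides applied on top of the file.
#' @return Named list of class \code{eva_config}.
#' @export
read_config <- function(path = NULL, ...) {
  file_vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file does not exist: ", path)
    file_vals <- yaml::read_yaml(path)
    if (!is.list(file_vals)) stop("config file must be a flat key: value mapping")
  }
  merged <- modifyList(file_vals, list(...))
  do.call(eva_config, merged)
}

config_hash <- function(cfg) {
  plain <- unclass(cfg)
  plain <- plain[order(names(plain))]
  txt <- jsonlite::toJSON(plain, auto_unbox = TRUE, null = "null")
  # small stable polynomial hash; avoids a digest dependency
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
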