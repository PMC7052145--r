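#' Default analysis configuration
#'
#' Returns the full set of tunable parameters of the pipeline with their
#' defaults. A configuration is a plain named list; [read_config()] merges a
#' YAML file over these defaults so partial files are valid.
#'
#' @details
#' * `fs`, `n_target`: resampling rate (Hz) and series length. Two-minute
#'   windows at 4 Hz give a 480-point grid from which the central
#'   `n_target = 430` samples are kept.
#' * `tau`, `m`, `m_max`, `fnn_cutoff`, `r_tol`, `a_tol`: delay-embedding
#'   parameters. `m = NULL` asks the pipeline to estimate the dimension by
#'   false nearest neighbours and take the maximum over all series; a fixed
#'   integer (e.g. 11) overrides it.
#' * `normalize`: z-score each RR series per segment before embedding.
#' * `epsilon`, `epsilon_scale`, `norm`: recurrence threshold, how distances
#'   are scaled before thresholding (`"dim"` divides Euclidean distances
#'   by `sqrt(m)` so `epsilon` is a per-coordinate separation in units of
#'   the z-scored series' SD; `"max"`, `"mean"`, `"none"` are
#'   alternatives), and the point norm.
#' * `l_min`, `v_min`: minimal diagonal / vertical line lengths.
#' * `entropy_normalized`: report diagonal-line entropy divided by
#'   `log(number of distinct line lengths)` (in \[0, 1\]) instead of raw
#'   nats. Off by default: the raw entropy is the scale on which richer
#'   shared dynamics mean *higher* entropy.
#' * `threshold_mode`: statistic maximised by the per-pair threshold search;
#'   `"line_sd"` = SD of the diagonal line-length distribution,
#'   `"matrix_sd"` = SD of the binary matrix entries.
#' * `seed`: default seed for seeded operations (out-group pairing).
#'
#' @return Named list of parameters.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$epsilon
default_config <- function() {
  list(
    fs = 4,
    n_target = 430L,
    tau = 1L,
    m = NULL,
    m_max = 15L,
    fnn_cutoff = 0.1,
    r_tol = 10,
    a_tol = 2,
    normalize = TRUE,
    epsilon = 0.2,
    epsilon_scale = "dim",
    norm = "euclidean",
    l_min = 2L,
    v_min = 2L,
    entropy_normalized = FALSE,
    threshold_mode = "line_sd",
    seed = 1L
  )
}

#' Read a configuration file
#'
#' Reads a YAML configuration and merges it over [default_config()]. Unknown
#' keys are a hard error (they are almost always typos). The resolved
#' configuration is logged so every run records the parameters it used.
#'
#' @param path Path to a YAML file.
#' @return Named list as [default_config()].
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  if (length(user)) {
    bad <- setdiff(names(user), names(cfg))
    if (length(bad)) {
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    }
    cfg[names(user)] <- user
  }
  validate_config(cfg)
  crq_log("info", "resolved configuration: ", config_string(cfg))
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$fs > 0, cfg$n_target >= 2,
    cfg$tau >= 1, cfg$m_max >= 1,
    cfg$fnn_cutoff > 0, cfg$fnn_cutoff < 1,
    cfg$r_tol > 0, cfg$a_tol > 0,
    cfg$epsilon > 0,
    cfg$l_min >= 2, cfg$v_min >= 2
  )
  if (!is.null(cfg$m) && cfg$m < 1) stop("embedding dimension m must be >= 1")
  cfg$epsilon_scale <- match.arg(cfg$epsilon_scale,
                                 c("dim", "max", "mean", "none"))
  cfg$norm <- match.arg(cfg$norm, c("euclidean", "maximum"))
  cfg$threshold_mode <- match.arg(cfg$threshold_mode, c("line_sd", "matrix_sd"))
  invisible(cfg)
}

config_string <- function(cfg) {
  vals <- vapply(cfg, function(x) {
    if (is.null(x)) "auto" else paste(format(x), collapse = "-")
  }, character(1))
  paste(names(cfg), vals, sep = "=", collapse = " ")
}

#' @keywords internal
#' @noRd
crq_log <- function(level = c("info", "warn", "error"), ...) {
  level <- match.arg(level)
  threshold <- getOption("crqsync.verbosity", "info")
  ranks <- c(info = 1L, warn = 2L, error = 3L)
  if (ranks[[level]] < ranks[[threshold]]) return(invisible(NULL))
  message(sprintf("[%s] %s", toupper(level), paste0(..., collapse = "")))
  invisible(NULL)
}

## Evaluate `code` under a temporary RNG state seeded with `seed`,
## restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit({
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  code
}

## Fixed-precision number formatting used by every writer so output is
## byte-stable and round-trips to 12 significant digits.
fmt_num <- function(x) {
  out <- formatC(x, digits = 12, format = "g")
  gsub(" ", "", out, fixed = TRUE)
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}
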