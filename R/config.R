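#' Toolkit run configuration
#'
#' Collects every tunable constant in one place with documented defaults:
#' the efficacy-scoring windows and peaks (see [scoring_rules()]), the
#' protospacer length, the melting-temperature method, the qPCR
#' amplification efficiency, the Golden-Gate overhangs, the RNG seed and
#' verbosity. The object round-trips through YAML unchanged.
#'
#' @param ... Overrides of the defaults (unknown keys are an error).
#' @return A list of class `crispri_config`.
#' @export
crispri_config <- function(...) {
  defaults <- list(
    fwd_lo = 60, fwd_hi = 120,
    rev_lo = -30, rev_hi = 15,
    broad_lo = -30, broad_hi = 100,
    peak_forward = 90, peak_reverse = -5,
    base_a = 1.0, base_b = 0.5, base_c = 0.1,
    penalty = 1e-4, score_floor = 0.01,
    spacer_length = 20L,
    upstream = 200L, downstream = 300L,
    tm_method = "wallace",
    efficiency = 2,
    top_overhang = "CACC", bottom_overhang = "AAAC",
    seed = NULL,
    verbosity = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(over)] <- over
  structure(defaults, class = "crispri_config")
}

#' @rdname crispri_config
#' @param config A `crispri_config`.
#' @return For `config_scoring_rules()`, the [scoring_rules()] implied by
#'   the configuration.
#' @export
config_scoring_rules <- function(config) {
  scoring_rules(fwd_lo = config$fwd_lo, fwd_hi = config$fwd_hi,
                rev_lo = config$rev_lo, rev_hi = config$rev_hi,
                broad_lo = config$broad_lo, broad_hi = config$broad_hi,
                peak_forward = config$peak_forward,
                peak_reverse = config$peak_reverse,
                base = c(A = config$base_a, B = config$base_b,
                         C = config$base_c),
                penalty = config$penalty, floor = config$score_floor)
}

#' Read or write a configuration file
#'
#' Plain YAML key-value files; keys are the [crispri_config()] arguments.
#'
#' @param path File path.
#' @return `read_config()` returns a `crispri_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(crispri_config, vals)
}

#' @rdname read_config
#' @param config A `crispri_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.crispri_config <- function(x, ...) {
  cat("CRISPRi toolkit configuration:\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-15s %s\n", k,
                if (is.null(v)) "NULL" else paste(v, collapse = ", ")))
  }
  invisible(x)
}
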