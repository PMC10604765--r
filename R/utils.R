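`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Structured error helpers: validation errors (bad inputs / broken
# invariants) and quality errors (data too poor to analyse) get their own
# condition classes so callers and the CLI can map them to exit codes.
bsi_validation_error <- function(msg) {
  stop(errorCondition(msg, class = c("bsi_validation_error", "bsi_error")))
}

bsi_quality_error <- function(msg) {
  stop(errorCondition(msg, class = c("bsi_quality_error", "bsi_error")))
}

#' Composite trapezoidal integral on possibly non-uniform abscissae
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

# Evaluate a block with a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded rendering does not perturb outer streams.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Derive a child seed for a named pipeline stage from the global seed.
# Documented splitting rule: stage index (1-based, fixed order) times a
# large odd constant, folded into 31 bits.
stage_seed <- function(seed, stage) {
  stages <- c("simulate", "track", "quantify", "report")
  idx <- match(stage, stages)
  if (is.na(idx)) bsi_validation_error(paste0("unknown stage '", stage, "'"))
  as.integer((as.numeric(seed) + idx * 1000003) %% .Machine$integer.max)
}

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    bsi_validation_error(paste0("'", name, "' must be a single finite number"))
  }
  if ((strict && x <= lower) || (!strict && x < lower)) {
    bsi_validation_error(paste0(
      "'", name, "' must be ", if (strict) "> " else ">= ", lower,
      " (got ", format(x), ")"
    ))
  }
  invisible(x)
}

bsi_log <- function(level = c("info", "debug"), ...) {
  level <- match.arg(level)
  opt <- getOption("bsiflow.log_level", "info")
  show <- switch(opt, quiet = FALSE, info = level == "info", debug = TRUE, FALSE)
  if (isTRUE(show)) message("[bsiflow] ", ...)
  invisible(NULL)
}
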