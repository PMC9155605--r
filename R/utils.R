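`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats cor pnorm predict rnorm runif setNames
#' @importFrom utils head read.csv write.csv
NULL

## Condition helpers ---------------------------------------------------------

hs_error <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "herbsig_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

parse_error <- function(msg, position = NA_integer_) {
  hs_error(sprintf("SMILES parse error at position %s: %s", position, msg),
           "herbsig_parse_error", position = position)
}

contract_error <- function(msg) hs_error(msg, "herbsig_contract_error")
config_error <- function(msg) hs_error(msg, "herbsig_config_error")
data_error <- function(msg) hs_error(msg, "herbsig_data_error")

## Logging -------------------------------------------------------------------

.hs_log_levels <- c(debug = 10L, info = 20L, warning = 30L, quiet = 90L)

hs_log_level <- function() {
  lv <- getOption("herbsig.log_level", "info")
  .hs_log_levels[[match.arg(lv, names(.hs_log_levels))]]
}

hs_log <- function(msg, ..., level = "info") {
  if (.hs_log_levels[[level]] >= hs_log_level()) {
    message(sprintf("[herbsig] %s", sprintf(msg, ...)))
  }
  invisible(NULL)
}

## Deterministic half-up rounding (base round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  force(expr)
}
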