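#' Logit and inverse-logit
#'
#' The log-odds transform and its inverse, used throughout the logistic
#' (torpor frequency) models. `ilogit()` is the standard logistic function
#' `1 / (1 + exp(-x))`; the two are exact inverses over the range of
#' log-odds that arise in practice.
#'
#' @param p Probabilities in (0, 1).
#' @param x Log-odds values.
#' @return A numeric vector.
#' @examples
#' ilogit(logit(0.8))
#' @export
logit <- function(p) stats::qlogis(p)

#' @rdname logit
#' @export
ilogit <- function(x) stats::plogis(x)

# Recycle-safe check that a numeric scalar is a single finite value
check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < min || x > max) {
    abort(sprintf("`%s` must be in [%s, %s].", name, format(min), format(max)))
  }
  invisible(x)
}

# Derive a child RNG seed from a master seed; kept below 2^31 - 1.
child_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647)
}

# Round a timestamp down to the 10-min cadence grid
snap_to_grid <- function(time, cadence_min = 10) {
  as.POSIXct(floor(as.double(time) / (cadence_min * 60)) * (cadence_min * 60),
    origin = "1970-01-01", tz = "UTC"
  )
}

# Timestamped one-line stage log
stage_log <- function(stage, ..., quiet = FALSE) {
  if (quiet) return(invisible(NULL))
  inform(sprintf(
    "[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, sprintf(...)
  ))
}
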