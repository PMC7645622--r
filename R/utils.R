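# Shared internal helpers: error signalling, rounding, seeds.

#' Stop with a classed voxppi condition
#'
#' All user-facing errors in the package carry a condition class of the form
#' `voxppi_error_<what>` so callers (and tests) can branch on the failure
#' mode rather than on message text.
#'
#' @param what short snake_case identifier of the failure mode
#' @param message human-readable message
#' @param ... additional condition fields
#' @noRd
vox_abort <- function(what, message, ...) {
  abort(message, class = paste0("voxppi_error_", what), ...)
}

vox_warn <- function(what, message, ...) {
  warn(message, class = paste0("voxppi_warning_", what), ...)
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; voxel index assignment uses the
#' nearest-integer convention with ties moving away from zero, so that the
#' mapping is symmetric about the grid centre.
#'
#' @param x numeric vector
#' @return integer-valued numeric vector
#' @export
#' @examples
#' round_half_away(c(-1.5, -0.5, 0.5, 1.5))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a stream-specific child seed from a run seed, kept below 2^31.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 1009) %% 2147483647
}

stopifnot_scalar_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != floor(x)) {
    vox_abort("config", sprintf("`%s` must be a single integer", name))
  }
  as.integer(x)
}
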