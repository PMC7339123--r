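# Physical constants (SI, CODATA 2018 exact values)
.kB <- 1.380649e-23      # Boltzmann constant, J/K
.eC <- 1.602176634e-19   # elementary charge, C
.Rgas <- 8.314462618     # molar gas constant, J/(mol K)
.T0C <- 273.15           # 0 degC in kelvin

#' Thermal voltage kT/e in millivolts
#'
#' The voltage scale of the Boltzmann relation between carrier-mediated
#' membrane conductance and interfacial potential. At 298.15 K (25 degC)
#' it equals 25.69 mV.
#'
#' @param temperature Absolute temperature in kelvin (default 298.15,
#'   room temperature).
#' @return Thermal voltage in mV.
#' @examples
#' thermal_voltage()          # 25.69 mV
#' thermal_voltage(310.15)    # body temperature
#' @export
thermal_voltage <- function(temperature = 298.15) {
  stopifnot(is.numeric(temperature), all(temperature > 0))
  .kB * temperature / .eC * 1000
}

celsius_to_kelvin <- function(x) x + .T0C
kelvin_to_celsius <- function(x) x - .T0C

# internal: fail with a message naming the offending field
.check_field <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    stop(sprintf("invalid configuration: field '%s' %s", field, msg),
         call. = FALSE)
  }
  invisible(TRUE)
}

# internal: run expr with a locally seeded RNG, restoring global state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a per-stage random seed from a global study seed
#'
#' Deterministic counter scheme: each (compound, stage) pair maps to its own
#' 31-bit seed so no stage shares random state with another. Used by
#' [run_study()] and available for user pipelines.
#'
#' @param seed Global integer seed.
#' @param counter Non-negative integer stage counter.
#' @return An integer seed below 2^31.
#' @export
derive_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), is.numeric(counter), counter >= 0)
  as.integer((as.numeric(seed) + 7919 * (as.numeric(counter) + 1)) %% 2147483629)
}
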