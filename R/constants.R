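#' Gas constant in kcal/(mol K)
#'
#' Single authoritative value of the gas constant used by every fitting and
#' simulation routine in the package, in the calorie-based units conventional
#' in protein thermodynamics.
#'
#' @format A length-one numeric, 1.987e-3 kcal/(mol K).
#' @export
Rgas_kcal <- 1.987e-3

# Water reference state for sedimentation standardization (20 C).
.water20 <- list(density_g_mL = 0.99823, viscosity_cP = 1.002)

.C_to_K <- function(temp_C) temp_C + 273.15

# Run code under a temporary RNG state so generators never disturb the
# caller's stream.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
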