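.kB <- 0.0019872041        # kcal mol^-1 K^-1
.coulomb_k <- 332.0637     # kcal A mol^-1 e^-2
.akma <- 418.4             # amu A^2 ps^-2 per kcal/mol

#' Physical constants used by the engine
#'
#' @return Named list with `kB` (kcal/mol/K), `coulomb` (kcal A/mol/e^2) and
#'   `kcal_per_akma` (amu A^2/ps^2 in one kcal/mol).
#' @export
#' @examples
#' unit_constants()$kB
unit_constants <- function() {
  list(kB = .kB, coulomb = .coulomb_k, kcal_per_akma = .akma)
}
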