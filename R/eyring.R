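#' Eyring transition-state-theory rate constant
#'
#' `k = (k_B T / h) exp(-dG / (R T))`. Bimolecular constants are referenced
#' to the 1 M standard state, i.e. the same numerical value is returned in
#' M^-1 s^-1 when `molecularity = 2` (the activation energy must then itself
#' be a 1 M standard-state quantity, as produced by [gibbs_energy()]).
#'
#' @param dG_activation activation free energy in kcal/mol, non-negative.
#' @param T temperature in K.
#' @param molecularity 1 (s^-1) or 2 (M^-1 s^-1); affects only the unit
#'   interpretation, not the value.
#' @return Rate constant (s^-1 or M^-1 s^-1).
#' @export
#' @examples
#' eyring_rate(29, T = 393.15)
eyring_rate <- function(dG_activation, T, molecularity = 1) {
  if (!is.numeric(T) || any(T <= 0)) stop("`T` must be positive", call. = FALSE)
  if (!is.numeric(dG_activation) || any(!is.finite(dG_activation)) ||
      any(dG_activation < 0))
    stop("activation energy must be finite and non-negative", call. = FALSE)
  if (!all(molecularity %in% c(1, 2)))
    stop("`molecularity` must be 1 or 2", call. = FALSE)
  .eyring_prefactor(T) * exp(-dG_activation / (phys_const$R_kcal * T))
}
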