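#' Solution standard state
#'
#' Defines the thermodynamic reference state used to correct gas-phase (1 atm)
#' Gibbs energies to the 1 M solution standard state customary for reactions
#' in solvent.
#'
#' @param T temperature in K.
#' @param C0 reference concentration in mol/L (default 1 M).
#' @param P pressure in atm (default 1).
#' @return An object of class `standard_state`.
#' @export
#' @examples
#' standard_state(T = 393.15)
standard_state <- function(T, C0 = 1, P = 1) {
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0)
    stop("`T` must be a single positive temperature in K", call. = FALSE)
  if (!is.numeric(C0) || C0 <= 0) stop("`C0` must be positive", call. = FALSE)
  if (!is.numeric(P) || P <= 0) stop("`P` must be positive", call. = FALSE)
  structure(list(T = T, C0 = C0, P = P, R = phys_const$R_kcal),
            class = "standard_state")
}

#' @export
print.standard_state <- function(x, ...) {
  cat(sprintf("<standard_state> T = %.2f K, C0 = %g M, P = %g atm\n",
              x$T, x$C0, x$P))
  invisible(x)
}

#' Concentration of an ideal gas at standard pressure
#'
#' Evaluates `P / (R T)` with R in L atm mol^-1 K^-1, i.e. the molarity of an
#' ideal gas at the state's pressure and temperature. At 120 degC and 1 atm
#' this is 0.031 M.
#'
#' @param state a [standard_state()].
#' @return Concentration in mol/L.
#' @export
#' @examples
#' gas_standard_concentration(standard_state(T = 393.15))
gas_standard_concentration <- function(state) {
  stopifnot(inherits(state, "standard_state"))
  state$P / (phys_const$R_Latm * state$T)
}

#' Standard-state concentration correction to the Gibbs energy
#'
#' The term `R T ln(C0 / C_1atm)` added per molecule when converting from the
#' 1 atm ideal-gas reference to a `C0` (by default 1 M) solution reference.
#' Positive whenever `C0` exceeds the ideal-gas molarity; at 120 degC it
#' amounts to 2.71 kcal/mol per molecule.
#'
#' @inheritParams gas_standard_concentration
#' @return Energy in kcal/mol.
#' @export
#' @examples
#' standard_state_correction(standard_state(T = 393.15))
standard_state_correction <- function(state) {
  stopifnot(inherits(state, "standard_state"))
  c1atm <- gas_standard_concentration(state)
  phys_const$R_kcal * state$T * log(state$C0 / c1atm)
}

#' Raw thermochemistry for one stationary point
#'
#' Bundles the terms of the composite Gibbs energy expression
#' `G = E_el + H_corr - T S + R T ln(C0/C_1atm)`: the electronic energy
#' (solvent and dispersion included, large basis), the thermal enthalpy
#' correction and the entropy from the frequency calculation.
#'
#' @param label species identifier.
#' @param E_BS2 electronic energy, in `unit`.
#' @param H_corr_BS1 thermal correction to enthalpy, in `unit`.
#' @param S_BS1 entropy in kcal mol^-1 K^-1 (always; not affected by `unit`).
#' @param role one of `"intermediate"`, `"transition_state"`, `"reactant"`,
#'   `"product"`.
#' @param unit unit of `E_BS2` and `H_corr_BS1`: `"kcal/mol"` or `"hartree"`.
#' @return An object of class `thermo_record`.
#' @export
thermo_record <- function(label, E_BS2, H_corr_BS1, S_BS1,
                          role = c("intermediate", "transition_state",
                                   "reactant", "product"),
                          unit = c("kcal/mol", "hartree")) {
  role <- match.arg(role)
  unit <- match.arg(unit)
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stop("`label` must be a non-empty string", call. = FALSE)
  if (!is.finite(S_BS1) || S_BS1 < 0)
    stop("entropy `S_BS1` must be non-negative", call. = FALSE)
  structure(list(label = label, E_BS2 = E_BS2, H_corr_BS1 = H_corr_BS1,
                 S_BS1 = S_BS1, role = role, unit = unit),
            class = "thermo_record")
}

#' Standard-state Gibbs energy of one stationary point
#'
#' Evaluates `G_T^0 = E_BS2 + H_corr - T S + R T ln(C0 / C_1atm)` in kcal/mol.
#' Hartree-tagged electronic/enthalpy terms are converted with the fixed
#' factor 627.5095 kcal/mol per hartree; the entropy is always kcal/(mol K).
#'
#' @param rec a [thermo_record()].
#' @param state a [standard_state()].
#' @return Gibbs energy in kcal/mol.
#' @export
gibbs_energy <- function(rec, state) {
  stopifnot(inherits(rec, "thermo_record"), inherits(state, "standard_state"))
  f <- if (rec$unit == "hartree") phys_const$hartree_kcal else 1
  f * rec$E_BS2 + f * rec$H_corr_BS1 - state$T * rec$S_BS1 +
    standard_state_correction(state)
}
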