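#' Frontier-orbital energies of a substrate
#'
#' @param eps_homo HOMO energy in eV.
#' @param eps_lumo LUMO energy in eV; must lie above the HOMO.
#' @param level level-of-theory tag (free text, used only for consistency
#'   checks when tabulating).
#' @return An object of class `frontier_energies`.
#' @export
frontier_energies <- function(eps_homo, eps_lumo, level = "") {
  if (!is.finite(eps_homo) || !is.finite(eps_lumo))
    stop("orbital energies must be finite", call. = FALSE)
  if (eps_lumo <= eps_homo)
    stop("`eps_lumo` must lie above `eps_homo` (degenerate gap)", call. = FALSE)
  structure(list(eps_homo = eps_homo, eps_lumo = eps_lumo, level = level),
            class = "frontier_energies")
}

#' Global conceptual-DFT reactivity descriptors
#'
#' Computes, from frontier-orbital energies in the Koopmans-type
#' approximation (`I = -eps_HOMO`, `A = -eps_LUMO`), the electronic chemical
#' potential `mu = (eps_H + eps_L)/2`, Mulliken electronegativity
#' `chi = -mu`, hardness `eta = eps_L - eps_H` (gap convention), softness
#' `S = 1/(2 eta)`, electrophilicity `omega = mu^2/(2 eta)` and the
#' electrodonating / electroaccepting powers
#' `omega^- = (3I + A)^2 / (16 (I - A))`,
#' `omega^+ = (I + 3A)^2 / (16 (I - A))`.
#'
#' `omega^- - omega^+ = chi` holds identically.
#'
#' @param fe a [frontier_energies()].
#' @return Named list with `mu`, `chi`, `eta`, `softness` (eV^-1), `omega`,
#'   `omega_minus`, `omega_plus` (all eV unless noted).
#' @export
#' @examples
#' global_descriptors(frontier_energies(-7, -1))
global_descriptors <- function(fe) {
  stopifnot(inherits(fe, "frontier_energies"))
  eH <- fe$eps_homo; eL <- fe$eps_lumo
  eta <- eL - eH
  mu <- (eH + eL) / 2
  I <- -eH; A <- -eL
  list(mu = mu,
       chi = -mu,
       eta = eta,
       softness = 1 / (2 * eta),
       omega = mu^2 / (2 * eta),
       omega_minus = (3 * I + A)^2 / (16 * (I - A)),
       omega_plus = (I + 3 * A)^2 / (16 * (I - A)))
}

#' Nucleophilicity index
#'
#' `N = eps_HOMO - eps_HOMO(reference)`, the HOMO energy measured against a
#' reference electrophile computed at the same level of theory
#' (conventionally tetracyanoethylene). The reference must be supplied
#' explicitly; there is no default.
#'
#' @param fe a [frontier_energies()].
#' @param reference_homo HOMO energy of the reference species in eV.
#' @return Nucleophilicity in eV.
#' @export
nucleophilicity <- function(fe, reference_homo) {
  stopifnot(inherits(fe, "frontier_energies"))
  if (missing(reference_homo) || is.null(reference_homo) ||
      !is.finite(reference_homo))
    stop("`reference_homo` must be supplied explicitly", call. = FALSE)
  fe$eps_homo - reference_homo
}

#' Tabulate substrate descriptors
#'
#' Expands a table of substrates (one row each, with frontier-orbital
#' energies and optional pass-through columns such as population-analysis
#' charges or inductive parameters) into the full descriptor table: all
#' [global_descriptors()] fields plus, when references are supplied, the
#' `N` and `N_prime` nucleophilicity indexes.
#'
#' @param substrates data.frame with at least `substrate_id`, `role`
#'   (`"alkylborane"` or `"ketone"`), `eps_homo_eV`, `eps_lumo_eV`; any other
#'   column is passed through unchanged.
#' @param reference_homo,reference_homo_prime reference HOMO energies (eV)
#'   for the `N` and `N_prime` indexes; either may be `NULL` to skip that
#'   column.
#' @return data.frame keyed by `substrate_id` with descriptor columns added.
#' @export
descriptor_table <- function(substrates, reference_homo = NULL,
                             reference_homo_prime = NULL) {
  stopifnot(is.data.frame(substrates))
  if (nrow(substrates) == 0L) return(substrates)
  need <- c("substrate_id", "role", "eps_homo_eV", "eps_lumo_eV")
  if (!all(need %in% names(substrates)))
    stop("substrate table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(substrates$substrate_id))
    stop("duplicated substrate id(s): ",
         paste(unique(substrates$substrate_id[
           duplicated(substrates$substrate_id)]), collapse = ", "),
         call. = FALSE)
  if (!all(substrates$role %in% c("alkylborane", "ketone")))
    stop("role must be 'alkylborane' or 'ketone'", call. = FALSE)
  derived <- lapply(seq_len(nrow(substrates)), function(i) {
    fe <- frontier_energies(substrates$eps_homo_eV[i],
                            substrates$eps_lumo_eV[i])
    d <- global_descriptors(fe)
    if (!is.null(reference_homo)) d$N <- nucleophilicity(fe, reference_homo)
    if (!is.null(reference_homo_prime))
      d$N_prime <- nucleophilicity(fe, reference_homo_prime)
    as.data.frame(d)
  })
  cbind(substrates, do.call(rbind, derived))
}
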