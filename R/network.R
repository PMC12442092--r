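#' Elementary-step mechanism template for the Cu(I) cycle
#'
#' The canonical five-step mechanism for the copper-catalysed addition of an
#' alkylborane to a ketone, expressed against the stationary-point labels of
#' a [gibbs_profile()]:
#'
#' 1. `activation` (off-cycle, irreversible): `I1 + CsF -> I2 + CsI`,
#'    halide replacement on the catalyst precursor; barrierless.
#' 2. `borane_uptake`: `I2 + RB -> I3`, adduct formation driven by B-F
#'    affinity; barrierless.
#' 3. `transmetalation`: `I3 -> I4 + BF`, alkyl transfer from boron to
#'    copper through `TS1`; releases the fluoroborane byproduct.
#' 4. `cc_addition`: `I4 + ketone -> I5`, nucleophilic attack of the
#'    copper-bound alkyl on the carbonyl through `TS2`.
#' 5. `product_release`: `I5 + CsF -> I2 + product`, alkoxide/fluoride
#'    exchange closing the cycle; barrierless.
#'
#' Steps without a located transition state carry `ts = NA` and get their
#' forward barrier from `max(dG_rxn, 0)` plus an optional intrinsic barrier.
#' Profile stationary points are composite states (catalyst complex plus the
#' free substrates and byproducts present at that stage), so the species a
#' step produces can differ from the profile label its energy is read from:
#' `to_energy` names the profile point, `to_species` the copper complex it
#' corresponds to. The final exchange regenerates `I2` while its reaction
#' energy is the profile endpoint `P`.
#'
#' @return A data.frame describing the template (one row per step).
#' @export
cu_mechanism <- function() {
  data.frame(
    step       = c("activation", "borane_uptake", "transmetalation",
                   "cc_addition", "product_release"),
    from       = c("I1", "I2", "I3", "I4", "I5"),
    to_species = c("I2", "I3", "I4", "I5", "I2"),
    to_energy  = c("I2", "I3", "I4", "I5", "P"),
    ts         = c(NA, NA, "TS1", "TS2", NA),
    co_react   = c("CsF", "RB", NA, "ketone", "CsF"),
    co_prod    = c("CsI", NA, "BF", NA, "product"),
    reversible = c(FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Build a mass-action reaction network from a free-energy profile
#'
#' Maps the stationary points of a [gibbs_profile()] onto a mechanism
#' template and derives, for every elementary step, the forward activation
#' energy (TS energy minus its preceding on-profile state, or
#' `max(dG_rxn, 0) + delta_intrinsic` for barrierless steps), the step
#' reaction energy, and forward/backward Eyring rate constants obeying
#' detailed balance (`dG_back = dG_forward - dG_rxn` exactly).
#'
#' Barrierless association steps can reach unphysically large Eyring
#' constants; when a step's faster direction exceeds `diffusion_cap`, both
#' directions are scaled down by the same factor, which caps the kinetics at
#' the diffusion limit while preserving the step's equilibrium constant.
#'
#' @param profile a [gibbs_profile()] whose labels include the template's
#'   cycle positions.
#' @param template mechanism template, by default [cu_mechanism()].
#' @param delta_intrinsic intrinsic barrier (kcal/mol) added to steps with no
#'   located transition state; default 0.
#' @param diffusion_cap rate-constant cap in M^-1 s^-1 (or s^-1); `Inf`
#'   disables it. Default 1e9.
#' @return An object of class `reaction_network`.
#' @export
#' @examples
#' build_network(cu_acetone_profile())
build_network <- function(profile, template = cu_mechanism(),
                          delta_intrinsic = 0, diffusion_cap = 1e9) {
  stopifnot(inherits(profile, "gibbs_profile"))
  pts <- profile$points
  G <- stats::setNames(pts$G_rel, pts$label)
  T <- profile$temperature
  RT <- phys_const$R_kcal * T

  need <- stats::na.omit(unique(c(template$from, template$to_energy,
                                  template$ts)))
  missing <- setdiff(need, names(G))
  if (length(missing))
    stop("profile is missing template position(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  steps <- vector("list", nrow(template))
  for (i in seq_len(nrow(template))) {
    tp <- template[i, ]
    dG_rxn <- G[[tp$to_energy]] - G[[tp$from]]
    if (is.na(tp$ts)) {
      dG_f <- max(dG_rxn, 0) + delta_intrinsic
    } else {
      dG_f <- G[[tp$ts]] - G[[tp$from]]
      if (dG_f < 0)
        stop(sprintf("transition state %s lies below its preceding state %s",
                     tp$ts, tp$from), call. = FALSE)
    }
    dG_b <- dG_f - dG_rxn
    if (dG_b < 0)
      stop(sprintf("step %s has a negative backward barrier", tp$step),
           call. = FALSE)
    reac <- c(tp$from, if (!is.na(tp$co_react)) tp$co_react)
    prod <- c(tp$to_species, if (!is.na(tp$co_prod)) tp$co_prod)
    k_f <- eyring_rate(dG_f, T, molecularity = min(length(reac), 2))
    k_b <- if (tp$reversible) eyring_rate(dG_b, T, min(length(prod), 2)) else 0
    s <- max(k_f, k_b) / diffusion_cap
    if (is.finite(s) && s > 1) {
      k_f <- k_f / s
      k_b <- k_b / s
    }
    steps[[i]] <- list(step = tp$step, reactants = reac, products = prod,
                       dG_forward = dG_f, dG_rxn = dG_rxn, k_f = k_f,
                       k_b = k_b, reversible = tp$reversible)
  }

  species <- unique(unlist(lapply(steps, function(s) c(s$reactants, s$products))))
  structure(list(species = species, steps = steps, temperature = T,
                 system_id = profile$system_id),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d species, %d steps, T = %.2f K\n",
              length(x$species), length(x$steps), x$temperature))
  for (s in x$steps)
    cat(sprintf("  %-16s %s %s %s  dG^f = %5.1f  k_f = %.3g  k_b = %.3g\n",
                s$step, paste(s$reactants, collapse = " + "),
                if (s$reversible) "<->" else " ->",
                paste(s$products, collapse = " + "),
                s$dG_forward, s$k_f, s$k_b))
  invisible(x)
}
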