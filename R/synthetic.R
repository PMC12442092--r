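#' Specification of the synthetic substrate-library generator
#'
#' Fixes, in one object, the statistical design that the synthetic systems
#' emulate: a library of `n_boranes` alkylboranes crossed with `n_ketones`
#' symmetric ketones; activation barriers generated from a two-descriptor
#' plane in the autoscaled borane nucleophilicity `N'` and ketone LUMO
#' energy, with Gaussian noise, floored at the barrier of the
#' transmetalation step (which does not depend on the ketone); and a
#' free-energy-profile template whose C-C addition transition state sits
#' `ts2_i5_drop` kcal/mol above the alkoxide intermediate it collapses to.
#'
#' The default `beta` places the standardized ketone coefficient about 13
#' times the borane one, the default ketone LUMO levels mirror four degrees
#' of methyl fluorination of acetone, and the default floor (17.4 kcal/mol)
#' is the transmetalation span of an electron-rich butyl borane, so the
#' generated libraries span roughly 17-46 kcal/mol.
#'
#' @param n_boranes,n_ketones library size (defaults 7 and 4).
#' @param beta generating coefficients `(b0, b_Nprime, b_lumo)` on the
#'   autoscaled scale, kcal/mol.
#' @param sigma Gaussian noise on the barriers, kcal/mol.
#' @param Nprime_range range of the borane nucleophilicity index, eV.
#' @param lumo_values ketone LUMO levels in eV, used when `n_ketones` equals
#'   their number; otherwise draws are uniform over `lumo_range`.
#' @param lumo_range fallback uniform range for ketone LUMO energies, eV.
#' @param tm_floor transmetalation barrier floor, kcal/mol.
#' @param ts2_i5_drop energy drop from the C-C addition TS to the alkoxide
#'   intermediate, kcal/mol.
#' @param template base levels (kcal/mol) of the profile template: `I2`,
#'   `I3`, `I4` and the reaction energy `release_dG` of the final
#'   alkoxide/fluoride exchange.
#' @param seed integer seed fixing all randomness of the generator.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_boranes = 7, n_ketones = 4,
                           beta = c(30.84, -0.85, 10.69),
                           sigma = 1,
                           Nprime_range = c(2, 5),
                           lumo_values = c(-0.655, -1.238, -1.906, -2.204),
                           lumo_range = c(-3.5, -0.5),
                           tm_floor = 17.4,
                           ts2_i5_drop = 50,
                           template = list(I2 = -0.3, I3 = -3.0, I4 = -1.6,
                                           release_dG = -2.0),
                           seed = 1L) {
  stopifnot(n_boranes >= 0, n_ketones >= 0, length(beta) == 3, sigma >= 0,
            diff(Nprime_range) > 0, diff(lumo_range) > 0, tm_floor > 0,
            ts2_i5_drop > 0)
  structure(list(n_boranes = n_boranes, n_ketones = n_ketones, beta = beta,
                 sigma = sigma, Nprime_range = Nprime_range,
                 lumo_values = lumo_values, lumo_range = lumo_range,
                 tm_floor = tm_floor, ts2_i5_drop = ts2_i5_drop,
                 template = template, seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a synthetic substrate library
#'
#' Draws descriptor tables for the alkylboranes (donor side: frontier
#' orbitals, `N_prime`, pass-through charge and inductive decoys) and the
#' ketones (acceptor side: frontier orbitals and charge decoys), emulating
#' the structure of a computed substrate-descriptor table. Fully reproducible
#' from `spec$seed`.
#'
#' @param spec a [generator_spec()].
#' @return List with data.frames `boranes` and `ketones` (full descriptor
#'   tables, via [descriptor_table()]).
#' @export
generate_substrates <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  ref <- -9.2   # reference HOMO (eV) anchoring N' = eps_HOMO - ref
  nb <- spec$n_boranes; nk <- spec$n_ketones
  boranes <- data.frame(
    substrate_id = character(0), role = character(0),
    eps_homo_eV = numeric(0), eps_lumo_eV = numeric(0))
  if (nb > 0) {
    Np <- stats::runif(nb, spec$Nprime_range[1], spec$Nprime_range[2])
    boranes <- data.frame(
      substrate_id = sprintf("B%d", seq_len(nb)),
      role = "alkylborane",
      eps_homo_eV = ref + Np,
      eps_lumo_eV = ref + Np + stats::runif(nb, 5, 8),
      q_boron_nbo = stats::rnorm(nb, 0.8, 0.1),
      q_calpha_cm5 = stats::rnorm(nb, -0.35, 0.05),
      sigma_i = stats::runif(nb, -0.05, 0.6))
    boranes <- descriptor_table(boranes, reference_homo = ref - 0.4,
                                reference_homo_prime = ref)
  }
  ketones <- data.frame(
    substrate_id = character(0), role = character(0),
    eps_homo_eV = numeric(0), eps_lumo_eV = numeric(0))
  if (nk > 0) {
    lumo <- if (nk == length(spec$lumo_values)) spec$lumo_values
            else stats::runif(nk, spec$lumo_range[1], spec$lumo_range[2])
    ketones <- data.frame(
      substrate_id = sprintf("K%d", seq_len(nk)),
      role = "ketone",
      eps_homo_eV = lumo - stats::runif(nk, 5.5, 7.5),
      eps_lumo_eV = lumo,
      q_carbonyl_nbo = stats::rnorm(nk, 0.55, 0.08))
    ketones <- descriptor_table(ketones)
  }
  list(boranes = boranes, ketones = ketones)
}

#' Generate activation barriers for every substrate pairing
#'
#' Crosses the borane and ketone tables and draws each pairing's overall
#' activation barrier from the generating plane
#' `dG^ = b0 + b_Nprime z(N') + b_lumo z(eps_LUMO) + N(0, sigma^2)`, where
#' `z()` autoscales over the pairing table. Barriers falling below the
#' transmetalation floor are replaced by it, and the pairing's kinetic
#' regime switches to `"transmetalation"` -- the ketone has become so
#' electrophilic that the boron-to-copper transfer is rate-limiting.
#'
#' @param substrates a [generate_substrates()] result.
#' @param spec a [generator_spec()].
#' @return data.frame with one row per (borane, ketone) pairing: descriptor
#'   values, `delta_G` (kcal/mol) and `regime`.
#' @export
generate_barriers <- function(substrates, spec) {
  stopifnot(inherits(spec, "generator_spec"))
  b <- substrates$boranes; k <- substrates$ketones
  if (nrow(b) == 0L || nrow(k) == 0L)
    return(data.frame(borane_id = character(0), ketone_id = character(0),
                      N_prime = numeric(0), eps_lumo_eV = numeric(0),
                      delta_G = numeric(0), regime = character(0)))
  pairs <- expand.grid(bi = seq_len(nrow(b)), ki = seq_len(nrow(k)))
  d <- data.frame(borane_id = b$substrate_id[pairs$bi],
                  ketone_id = k$substrate_id[pairs$ki],
                  N_prime = b$N_prime[pairs$bi],
                  eps_lumo_eV = k$eps_lumo_eV[pairs$ki])
  Z <- autoscale(d[c("N_prime", "eps_lumo_eV")])
  set.seed(spec$seed + 1L)
  plane <- spec$beta[1] + spec$beta[2] * Z[, 1] + spec$beta[3] * Z[, 2]
  d$delta_G <- plane + stats::rnorm(nrow(d), 0, spec$sigma)
  d$regime <- ifelse(d$delta_G <= spec$tm_floor, "transmetalation",
                     "cc_addition")
  d$delta_G <- pmax(d$delta_G, spec$tm_floor)
  d
}

#' Generate a free-energy profile realising a given overall barrier
#'
#' Inverse of [overall_barrier()] on the generator's profile template: the
#' returned profile's overall activation barrier equals `barrier` exactly.
#' For barriers above the transmetalation floor the C-C addition transition
#' state is placed at `I3 + barrier`; at the floor the profile is
#' transmetalation-controlled and TS2 is parked 1 kcal/mol below TS1. The
#' alkoxide intermediate always sits `spec$ts2_i5_drop` below TS2 (plus an
#' optional jitter), and the final exchange step adds
#' `spec$template$release_dG`.
#'
#' @param barrier target overall activation barrier, kcal/mol; must not lie
#'   below `spec$tm_floor`.
#' @param spec a [generator_spec()].
#' @param system_id identifier for the generated system.
#' @param jitter half-width (kcal/mol) of a uniform jitter on the TS2-I5
#'   drop; default 0 (deterministic).
#' @return A [gibbs_profile()].
#' @export
#' @examples
#' overall_barrier(generate_profile(23.6, generator_spec()))
generate_profile <- function(barrier, spec = generator_spec(),
                             system_id = "synthetic", jitter = 0) {
  stopifnot(inherits(spec, "generator_spec"), is.numeric(barrier),
            length(barrier) == 1L)
  tpl <- spec$template
  if (barrier < spec$tm_floor - 1e-9)
    stop(sprintf("barrier %.2f below the transmetalation floor %.2f is infeasible",
                 barrier, spec$tm_floor), call. = FALSE)
  I3 <- tpl$I3
  TS1 <- I3 + spec$tm_floor
  TS2 <- if (barrier > spec$tm_floor + 1e-9) I3 + barrier else TS1 - 1.0
  drop <- spec$ts2_i5_drop +
    if (jitter > 0) stats::runif(1, -jitter, jitter) else 0
  I5 <- TS2 - drop
  gibbs_profile(data.frame(
    label = c("I1", "I2", "I3", "TS1", "I4", "TS2", "I5", "P"),
    role  = c("intermediate", "intermediate", "intermediate",
              "transition_state", "intermediate", "transition_state",
              "intermediate", "product"),
    G_rel = c(0, tpl$I2, I3, TS1, tpl$I4, TS2, I5, I5 + tpl$release_dG)),
    system_id = system_id)
}
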