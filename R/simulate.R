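#' Microkinetic simulation conditions
#'
#' Defaults emulate typical Cu(I)/NHC batch conditions for this chemistry:
#' 120 degC, equimolar substrates at 1 M, two equivalents of the cesium
#' fluoride activator and 5 mol% catalyst precursor, run for 16 hours.
#'
#' @param T temperature in K.
#' @param conc named vector of initial concentrations (M); species absent
#'   from the network are ignored, network species absent here start at 0.
#' @param t_end simulation horizon in seconds.
#' @param rtol,atol solver tolerances.
#' @param n_times number of output time points (log-spaced plus t = 0).
#' @return An object of class `sim_conditions`.
#' @export
sim_conditions <- function(T = 393.15,
                           conc = c(I1 = 0.05, RB = 1, ketone = 1, CsF = 2),
                           t_end = 16 * 3600,
                           rtol = 1e-8, atol = 1e-12, n_times = 400) {
  if (any(conc < 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (t_end <= 0) stop("`t_end` must be positive", call. = FALSE)
  structure(list(T = T, conc = conc, t_end = t_end, rtol = rtol, atol = atol,
                 n_times = n_times),
            class = "sim_conditions")
}

#' Integrate the mass-action kinetics of a reaction network
#'
#' Builds the mass-action ODE system of the network's elementary steps and
#' integrates it with a stiff solver (`deSolve::lsoda`, which switches to BDF
#' on the stiff transients produced by the barrierless association steps).
#' Output times are log-spaced so both the fast pre-equilibria and the
#' 16-hour horizon are resolved.
#'
#' @param network a [build_network()] result.
#' @param conditions a [sim_conditions()]; its temperature must match the
#'   network's (rate constants are temperature-specific).
#' @return A `kinetic_trace`: data.frame with a `time` column (s) and one
#'   concentration column (M) per species, with the conditions attached as
#'   attributes.
#' @export
#' @examples
#' tr <- simulate_network(build_network(cu_acetone_profile()))
#' product_yield(tr, 16 * 3600)
simulate_network <- function(network, conditions = sim_conditions()) {
  stopifnot(inherits(network, "reaction_network"),
            inherits(conditions, "sim_conditions"))
  if (abs(network$temperature - conditions$T) > 1e-6)
    stop("network was built at a different temperature than the conditions",
         call. = FALSE)
  sp <- network$species
  y0 <- stats::setNames(numeric(length(sp)), sp)
  known <- intersect(names(conditions$conc), sp)
  y0[known] <- conditions$conc[known]

  # stoichiometry matrix and rate-law index lists, built once
  ns <- length(network$steps)
  N <- matrix(0, nrow = length(sp), ncol = ns, dimnames = list(sp, NULL))
  ridx <- pidx <- vector("list", ns)
  kf <- kb <- numeric(ns)
  for (j in seq_len(ns)) {
    st <- network$steps[[j]]
    for (s in st$reactants) N[s, j] <- N[s, j] - 1
    for (s in st$products) N[s, j] <- N[s, j] + 1
    ridx[[j]] <- match(st$reactants, sp)
    pidx[[j]] <- match(st$products, sp)
    kf[j] <- st$k_f
    kb[j] <- st$k_b
  }

  rhs <- function(t, y, parms) {
    y <- pmax(y, 0)
    v <- numeric(ns)
    for (j in seq_len(ns))
      v[j] <- kf[j] * prod(y[ridx[[j]]]) - kb[j] * prod(y[pidx[[j]]])
    list(as.vector(N %*% v))
  }

  times <- c(0, 10^seq(log10(conditions$t_end) - 9, log10(conditions$t_end),
                       length.out = conditions$n_times - 1))
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = conditions$rtol, atol = conditions$atol,
                        maxsteps = 50000)
  if (attr(sol, "istate")[1L] < 0)
    stop("stiff solver failed: ", paste(attr(sol, "istate"), collapse = " "),
         call. = FALSE)
  out <- as.data.frame(sol)
  names(out)[1L] <- "time"
  attr(out, "conditions") <- conditions
  attr(out, "species") <- sp
  class(out) <- c("kinetic_trace", "data.frame")
  out
}

#' Product yield at a given time
#'
#' Fraction of the limiting substrate (the smaller of the initial alkylborane
#' and ketone concentrations) converted to product by time `t`, interpolated
#' linearly on the trace.
#'
#' @param trace a [simulate_network()] result.
#' @param t time in seconds, within the trace span.
#' @param product name of the product species.
#' @return Yield in `[0, 1]`.
#' @export
product_yield <- function(trace, t, product = "product") {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (t < min(trace$time) || t > max(trace$time) * (1 + 1e-9))
    stop("`t` outside the simulated time span", call. = FALSE)
  cond <- attr(trace, "conditions")
  subs <- cond$conc[intersect(c("RB", "ketone"), names(cond$conc))]
  subs <- subs[subs > 0]
  if (!length(subs)) stop("no limiting substrate in the conditions", call. = FALSE)
  limiting <- min(subs)
  if (!product %in% names(trace))
    stop("species `", product, "` not in trace", call. = FALSE)
  p <- stats::approx(trace$time, trace[[product]], xout = min(t, max(trace$time)),
                     rule = 2)$y
  max(min(p / limiting, 1), 0)
}

#' Time to reach a target yield
#'
#' First time at which the product yield reaches `threshold`, interpolated on
#' the trace; `NA` if the threshold is never reached within the horizon.
#'
#' @inheritParams product_yield
#' @param threshold target yield fraction (default 0.99, "complete").
#' @return Time in seconds, or `NA`.
#' @export
time_to_completion <- function(trace, threshold = 0.99, product = "product") {
  stopifnot(inherits(trace, "kinetic_trace"))
  cond <- attr(trace, "conditions")
  subs <- cond$conc[intersect(c("RB", "ketone"), names(cond$conc))]
  limiting <- min(subs[subs > 0])
  y <- trace[[product]] / limiting
  i <- which(y >= threshold)
  if (!length(i)) return(NA_real_)
  i <- i[1L]
  if (i == 1L) return(trace$time[1L])
  stats::approx(y[(i - 1L):i], trace$time[(i - 1L):i], xout = threshold)$y
}
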