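#' Barrier sweep: simulate the cycle over imposed overall barriers
#'
#' For each target barrier, the designated C-C addition transition state is
#' displaced on its own (every other stationary point kept at its original
#' value, via [shift_ts()]) so the overall activation barrier equals the
#' target, the mass-action kinetics are re-simulated, and the yield at the
#' horizon plus the time to 99% conversion are recorded.
#'
#' Targets below the floor imposed by the transmetalation step cannot be
#' realised by moving the C-C transition state alone; those runs carry a
#' regime warning from [shift_ts()].
#'
#' @param profile a [gibbs_profile()] containing the C-C addition TS.
#' @param barriers numeric vector of target overall barriers (kcal/mol),
#'   conventionally the integers 23 to 35.
#' @param conditions a [sim_conditions()].
#' @param ts label of the C-C addition transition state (default `"TS2"`).
#' @param ... passed to [build_network()].
#' @return A data.frame of class `barrier_sweep` with columns `barrier_kcal`,
#'   `yield_16h` (yield at the conditions' horizon) and `t99_s`.
#' @export
#' @examples
#' \donttest{
#' prof <- generate_profile(23.6, generator_spec())
#' sw <- barrier_sweep(prof, 26:32)
#' feasibility_limit(sw)
#' }
barrier_sweep <- function(profile, barriers, conditions = sim_conditions(),
                          ts = "TS2", ...) {
  stopifnot(inherits(profile, "gibbs_profile"), is.numeric(barriers),
            length(barriers) >= 1)
  if (any(barriers <= 0)) stop("barriers must be positive", call. = FALSE)
  res <- lapply(barriers, function(b) {
    shifted <- shift_ts(profile, ts, b)
    tr <- simulate_network(build_network(shifted, ...), conditions)
    data.frame(barrier_kcal = b,
               yield_16h = product_yield(tr, conditions$t_end),
               t99_s = time_to_completion(tr))
  })
  out <- do.call(rbind, res)
  attr(out, "t_end") <- conditions$t_end
  class(out) <- c("barrier_sweep", "data.frame")
  out
}

#' Feasibility limit of the overall activation barrier
#'
#' Largest swept barrier whose yield at the horizon is at least `threshold`
#' (by default 99% in a 16-hour run) -- the practical upper bound on the
#' activation barrier of a "working" reaction under the given conditions.
#'
#' @param sweep a [barrier_sweep()] result.
#' @param threshold yield threshold (default 0.99).
#' @return Barrier in kcal/mol. If every swept barrier passes (the crossing
#'   lies above the sweep) the maximum is returned with a warning; if none
#'   passes the minimum is returned with a warning.
#' @export
feasibility_limit <- function(sweep, threshold = 0.99) {
  stopifnot(inherits(sweep, "barrier_sweep"))
  ok <- sweep$yield_16h >= threshold
  if (all(ok)) {
    warning("all swept barriers meet the threshold; the limit lies above the sweep range",
            call. = FALSE)
    return(max(sweep$barrier_kcal))
  }
  if (!any(ok)) {
    warning("no swept barrier meets the threshold; the limit lies below the sweep range",
            call. = FALSE)
    return(min(sweep$barrier_kcal))
  }
  max(sweep$barrier_kcal[ok])
}
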