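# Rejection-free kinetic Monte Carlo: one event per step, selected with
# probability proportional to its rate via the cumulative distribution, and
# stochastic time advancement dt = -ln(u2) / R.

#' Construct an event list
#'
#' @param recipes List of [recipe()] objects (may be empty).
#' @param rates Numeric vector of rates, 1/s, `>= 0`, same length.
#' @return An object of class `event_list` with fields `recipes`, `rates`,
#'   `total_rate` and the cumulative selection function `cumulative`.
#' @export
event_list <- function(recipes = list(), rates = numeric()) {
  stopifnot(length(recipes) == length(rates), all(rates >= 0),
            all(is.finite(rates)))
  R <- total_rate_kahan(rates)
  structure(list(recipes = recipes, rates = rates, total_rate = R,
                 cumulative = if (R > 0) cumsum(rates / R) else numeric()),
            class = "event_list")
}

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("event_list: %d event(s), total rate %g /s\n",
              length(x$rates), x$total_rate))
  invisible(x)
}

total_rate_kahan <- function(rates) {
  # compensated (Kahan) summation: exact-sum contract for long event lists
  s <- 0; comp <- 0
  for (r in rates) {
    y <- r - comp
    t <- s + y
    comp <- (t - s) - y
    s <- t
  }
  s
}

#' Total rate of an event list
#'
#' Sum of all event rates, accumulated with compensated summation.
#'
#' @param el An [event_list()].
#' @return Total rate `R`, 1/s (0 for an empty list).
#' @export
total_rate <- function(el) el$total_rate

#' Cumulative event selection
#'
#' Returns the index `i` satisfying `F(p_[i-1]) < u1 <= F(p_i)`, where `F`
#' is the cumulative function of the selection probabilities
#' `p_i = rate_i / R`. The boundary belongs to the lower index (the `<=`
#' rule), and events with zero rate can never be selected. Implemented as
#' a binary search (`findInterval` with left-open intervals) over the
#' prefix sums.
#'
#' @param el An [event_list()] with positive total rate.
#' @param u1 Uniform draw(s) in (0, 1] (vectorized).
#' @return Integer index (or vector of indices) into the event list.
#' @export
kmc_select <- function(el, u1) {
  stopifnot(el$total_rate > 0, all(u1 > 0), all(u1 <= 1))
  chosen <- findInterval(u1, el$cumulative, left.open = TRUE) + 1L
  pmin(chosen, length(el$rates))  # guard u1 == 1 against cumsum rounding
}

#' One rejection-free kinetic Monte Carlo step
#'
#' Draws `u1, u2` uniform on (0, 1]; selects the event `i` satisfying
#' `F(p_[i-1]) < u1 <= F(p_i)` (the boundary belongs to the lower index)
#' where `F` is the cumulative function of the selection probabilities
#' `p_i = rate_i / R`; advances time by `dt = -ln(u2) / R`. Zero-rate
#' events are never chosen. Exactly two random numbers are consumed.
#'
#' @param el An [event_list()] with positive total rate. A zero total rate
#'   returns `NULL` (no-event signal; the caller decides whether to
#'   resample or halt).
#' @param rng An RNG stream from the orchestrator (or `rng_new(seed)`).
#' @return List with `chosen_index`, `delta_t`, `u1`, `u2`, or `NULL`.
#' @export
rf_kmc_step <- function(el, rng) {
  if (el$total_rate <= 0) return(NULL)
  u <- rng_unif_open0(rng, 2)
  u1 <- u[1]; u2 <- u[2]
  list(chosen_index = kmc_select(el, u1), delta_t = -log(u2) / el$total_rate,
       u1 = u1, u2 = u2)
}

#' Look up a kMC stepping algorithm by name
#'
#' `"rf"` (rejection-free, the default used throughout) returns
#' [rf_kmc_step()]. `"first-reaction"` is reserved as an interface slot
#' for the first-reaction method but is not implemented.
#'
#' @param name Algorithm name.
#' @return A function with the [rf_kmc_step()] signature.
#' @export
get_kmc_algorithm <- function(name = "rf") {
  switch(name,
         "rf" = rf_kmc_step,
         "first-reaction" = stop("first-reaction kMC is an interface slot; ",
                                 "only the rejection-free algorithm is implemented"),
         stop("unknown kMC algorithm '", name, "'"))
}

#' Draw many kMC selections and waiting times at once
#'
#' Batch version of [rf_kmc_step()] for convergence diagnostics: `n`
#' independent (selection, waiting time) draws from a fixed event list.
#' Consumes `2 n` random numbers in (u1, u2) pairs, in the same order as
#' `n` successive calls to `rf_kmc_step`.
#'
#' @param el An [event_list()] with positive total rate.
#' @param n Number of draws.
#' @param rng An RNG stream.
#' @return List with integer vector `chosen_index` and numeric vector
#'   `delta_t`.
#' @export
rf_kmc_sample <- function(el, n, rng) {
  if (el$total_rate <= 0) stop("rf_kmc_sample: zero total rate")
  u <- matrix(rng_unif_open0(rng, 2 * n), ncol = 2, byrow = TRUE)
  list(chosen_index = kmc_select(el, u[, 1]),
       delta_t = -log(u[, 2]) / el$total_rate)
}
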