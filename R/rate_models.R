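# Pluggable reaction-rate emulators. The transition-state Eyring equation
# converts free-energy barriers to rates; a Bell model gives force-dependent
# homolysis; a force/pH/surface-accessibility heuristic gives hydrolysis; a
# distance-and-angle heuristic gives photodimerization rates and quantum
# yields; and a table-driven surrogate stands in for a learned barrier
# predictor behind the same interface.

#' Eyring transition-state rate
#'
#' `k = (kB T / h) exp(-barrier / (kB T))`. At 300 K the attempt frequency
#' `kB T / h` is about 6.25e12 / s.
#'
#' @param barrier Free-energy barrier, kcal/mol (vectorized, must be >= 0).
#' @param c A [constants()] object.
#' @return Rate(s), 1/s.
#' @export
eyring_rate <- function(barrier, c = constants()) {
  if (any(barrier < 0)) stop("eyring_rate: negative barrier")
  (c$kB * c$T / c$h) * exp(-barrier / (c$kB * c$T))
}

#' Ensemble-averaged rate from per-frame barriers
#'
#' The arithmetic mean of the per-frame Eyring rates -- an average of
#' rates, not of barriers. The two differ by Jensen's gap: rare low-barrier
#' conformations dominate, which is how ensemble averaging captures
#' entropic accessibility of reactive geometries.
#'
#' @param barriers Numeric vector of per-frame barriers, kcal/mol.
#' @param c A [constants()] object.
#' @return A single rate, 1/s.
#' @export
ensemble_average_rate <- function(barriers, c = constants()) {
  if (!length(barriers)) stop("ensemble_average_rate: empty ensemble")
  mean(eyring_rate(barriers, c))
}

#' Bell model parameters
#'
#' @param k0 Zero-force rate, 1/s.
#' @param delta_x Activation length, A.
#' @return An object of class `bell_params`.
#' @export
bell_params <- function(k0 = 1e-15, delta_x = 0.3) {
  stopifnot(k0 >= 0, delta_x >= 0)
  structure(list(k0 = k0, delta_x = delta_x), class = "bell_params")
}

#' Bell force-accelerated bond rupture rate
#'
#' `k(F) = k0 exp(F delta_x / kB T)` with `kB T` converted to pN A
#' (1 kcal/mol = 69.48 pN A; at 300 K, kB T is about 41.69 pN A). Log-rate
#' is affine in force, so homolysis keeps accelerating at forces where
#' saturating models level off.
#'
#' @param force Applied force, pN (vectorized, >= 0).
#' @param p A [bell_params()] object.
#' @param c A [constants()] object.
#' @return Rate(s), 1/s.
#' @export
bell_rate <- function(force, p = bell_params(), c = constants()) {
  if (any(force < 0)) stop("bell_rate: negative force")
  kBT_pNA <- c$kB * c$T * KCAL_PER_MOL_IN_PN_A
  p$k0 * exp(force * p$delta_x / kBT_pNA)
}

#' Hydrolysis heuristic parameters
#'
#' Reference rate at a reference force, pH and solvent-accessible surface
#' area, a force sensitivity that saturates at `F_sat`, and linear SASA
#' scaling. Defaults are chosen so that, against the default
#' [bell_params()], hydrolysis dominates around 1 nN while homolysis
#' overtakes it at several nN (the saturating-vs-exponential crossover).
#'
#' @param k_ref Reference rate, 1/s.
#' @param F_ref Reference force, pN.
#' @param alpha Force sensitivity, 1/pN.
#' @param F_sat Saturation force, pN.
#' @param pH_ref Reference pH.
#' @param sasa_ref Reference solvent-accessible surface area, A^2.
#' @return An object of class `hydrolysis_params`.
#' @export
hydrolysis_params <- function(k_ref = 1e-9, F_ref = 0, alpha = 0.01,
                              F_sat = 2000, pH_ref = 7, sasa_ref = 100) {
  stopifnot(k_ref > 0, F_ref >= 0, alpha > 0, F_sat > 0, sasa_ref > 0)
  structure(list(k_ref = k_ref, F_ref = F_ref, alpha = alpha, F_sat = F_sat,
                 pH_ref = pH_ref, sasa_ref = sasa_ref),
            class = "hydrolysis_params")
}

#' Heuristic hydrolysis rate
#'
#' `k = k_ref exp(alpha (F - F_ref) / (1 + F / F_sat)) * 10^(pH - pH_ref)
#' * sasa / sasa_ref`: a saturating force response (hydrolysis tapers off
#' at high force), one rate decade per pH unit (base catalysis), and linear
#' scaling with solvent accessibility (a buried peptide bond cannot be
#' attacked by water).
#'
#' @param force Applied force, pN (vectorized).
#' @param pH Solution pH.
#' @param sasa Solvent-accessible surface area of the site, A^2 (>= 0).
#' @param p A [hydrolysis_params()] object.
#' @param c A [constants()] object (unused by the formula; kept so all rate
#'   models share one signature shape).
#' @return Rate(s), 1/s.
#' @export
hydrolysis_rate <- function(force, pH, sasa, p = hydrolysis_params(),
                            c = constants()) {
  if (any(sasa < 0)) stop("hydrolysis_rate: negative SASA")
  p$k_ref * exp(p$alpha * (force - p$F_ref) / (1 + force / p$F_sat)) *
    10^(pH - p$pH_ref) * (sasa / p$sasa_ref)
}

#' Dimerization heuristic parameters
#'
#' @param A Prefactor rate, 1/s.
#' @param d0 Distance decay constant, A.
#' @param theta_max Dihedral acceptance half-width, degrees (<= 90).
#' @param rate_threshold Rates above this count as dimerisable, 1/s.
#' @return An object of class `dimer_params`.
#' @export
dimer_params <- function(A = 1e9, d0 = 1.0, theta_max = 60,
                         rate_threshold = 1e9 * exp(-4)) {
  stopifnot(A > 0, d0 > 0, theta_max > 0, theta_max <= 90, rate_threshold > 0)
  structure(list(A = A, d0 = d0, theta_max = theta_max,
                 rate_threshold = rate_threshold), class = "dimer_params")
}

#' Distance-and-angle dimerization rate
#'
#' `rate = A exp(-d / d0) max(0, cos(theta))` inside the dihedral window
#' `|theta| <= theta_max`, zero outside: closer, better-aligned double
#' bonds react faster; antiparallel or twisted stacks do not react.
#'
#' @param d Distance between the reactive double bonds, A (vectorized).
#' @param theta Dihedral angle between them, degrees in (-180, 180].
#' @param p A [dimer_params()] object.
#' @return Rate(s), 1/s.
#' @export
dimerization_rate <- function(d, theta, p = dimer_params()) {
  if (any(d < 0)) stop("dimerization_rate: negative distance")
  th <- wrap_angle(theta)
  p$A * exp(-d / p$d0) * pmax(0, cos(th * pi / 180)) * (abs(th) <= p$theta_max)
}

#' @rdname dimerization_rate
#' @param rate Rate(s) as returned by `dimerization_rate`.
#' @return `is_dimerisable`: logical vector, `rate > rate_threshold`.
#' @export
is_dimerisable <- function(rate, p = dimer_params()) {
  rate > p$rate_threshold
}

#' Quantum yield of dimerization over a geometry ensemble
#'
#' The fraction of sampled conformations whose dimerization rate exceeds
#' the threshold -- frames above the threshold are counted as dimerisable
#' configurations contributing to the quantum yield.
#'
#' @param samples Data frame with columns `distance` (A) and `dihedral`
#'   (deg), e.g. from [synth_dimer_geometry_ensemble()].
#' @param p A [dimer_params()] object.
#' @return Quantum yield in `[0, 1]`.
#' @export
quantum_yield <- function(samples, p = dimer_params()) {
  if (!nrow(samples)) stop("quantum_yield: empty ensemble")
  mean(is_dimerisable(dimerization_rate(samples$distance, samples$dihedral, p), p))
}

# ---- surrogate HAT barrier predictor ----

#' Surrogate barrier table for hydrogen atom transfer
#'
#' A table-driven stand-in for a learned barrier predictor, keyed by the
#' hydrogen shift class (`"1-2"` ... `"1-7"`, `"long-range"`,
#' `"intermolecular"`). The shipped default encodes the ring-strain
#' ordering of intramolecular shifts: 1-2 and 1-3 highest (strained three-
#' and four-membered transition rings), 1-5 lowest (six-membered transition
#' ring), with a linear penalty for hydrogen-acceptor distances beyond the
#' 1.1 A product bond length.
#'
#' @param barriers Named numeric vector, kcal/mol (all >= 0).
#' @param slope Distance-penalty slope, kcal/mol/A.
#' @param default Fallback barrier for missing keys, kcal/mol, or `NA` to
#'   make missing keys an error.
#' @return An object of class `barrier_table`.
#' @export
barrier_table <- function(barriers = c("1-2" = 38, "1-3" = 34, "1-4" = 24,
                                       "1-5" = 19.5, "1-6" = 21.5,
                                       "1-7" = 23.5, "long-range" = 25,
                                       "intermolecular" = 22),
                          slope = 2.0, default = 25) {
  stopifnot(all(barriers >= 0), slope >= 0)
  structure(list(barriers = barriers, slope = slope, default = default),
            class = "barrier_table")
}

#' Surrogate HAT barrier from a table plus frame geometry
#'
#' `barrier = table[shift class] + slope * max(0, d_HA - 1.1)`, where the
#' shift class comes from [classify_shift()] on the current topology and
#' `d_HA` is the hydrogen-acceptor distance in the frame. A pure function
#' of (topology, atoms, frame, table); any object implementing this
#' signature can serve as the barrier predictor of the HAT plugin.
#'
#' @param t A [topology()].
#' @param h Hydrogen index.
#' @param acceptor Radical acceptor index.
#' @param f A [frame()].
#' @param table A [barrier_table()].
#' @return Barrier, kcal/mol.
#' @export
surrogate_hat_barrier <- function(t, h, acceptor, f, table = barrier_table()) {
  nb <- c(t$bonds$aj[t$bonds$ai == h], t$bonds$ai[t$bonds$aj == h])
  if (length(nb) != 1 || t$atoms$element[h] != "H") {
    stop("surrogate_hat_barrier: h must be a singly-bonded hydrogen")
  }
  label <- classify_shift(t, acceptor, nb[1])
  base <- table$barriers[label]
  if (is.na(base)) {
    if (is.na(table$default)) {
      stop("surrogate_hat_barrier: no table entry for '", label,
           "' and no default")
    }
    base <- table$default
  }
  d_ha <- sqrt(sum((f$positions[h, ] - f$positions[acceptor, ])^2))
  unname(base + table$slope * max(0, d_ha - 1.1))
}
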