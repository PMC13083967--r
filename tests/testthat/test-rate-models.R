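test_that("transition-state rates follow the Eyring form", {
  co <- constants()
  # kB*T/h at 300 K, evaluated from the constants themselves
  expect_equal(eyring_rate(0, co), 0.0019872 * 300 / 9.5306e-14,
               tolerance = 1e-12)
  expect_equal(eyring_rate(0, co), 6.2552e12, tolerance = 1e-4)
  expect_lt(eyring_rate(200, co), 1e-130)
  b <- seq(0, 40, by = 5)
  expect_true(all(diff(eyring_rate(b, co)) < 0))
  expect_error(eyring_rate(-1, co), "negative")
  # temperature is a parameter, not a constant
  expect_gt(eyring_rate(20, constants(T = 500)), eyring_rate(20, co))
})

test_that("ensemble averaging is over rates, not barriers", {
  co <- constants()
  expect_equal(ensemble_average_rate(17.3, co), eyring_rate(17.3, co))
  expect_equal(ensemble_average_rate(rep(12, 3), co), eyring_rate(12, co))
  # Jensen: the low-barrier frame dominates
  expect_gt(ensemble_average_rate(c(10, 20), co), eyring_rate(15, co))
  expect_equal(ensemble_average_rate(c(10, 20), co),
               mean(eyring_rate(c(10, 20), co)))
  expect_error(ensemble_average_rate(numeric(), co), "empty")
})

test_that("Bell rupture rates are exponential in force", {
  co <- constants()
  p <- bell_params(k0 = 1e-12, delta_x = 0.5)
  expect_equal(bell_rate(0, p, co), 1e-12)
  expect_equal(bell_rate(1000, p, co),
               1e-12 * exp(500 / (0.0019872 * 300 * 69.48)), tolerance = 1e-12)
  # affine log-rate: k(2F)/k(F) == k(F)/k(0)
  expect_equal(bell_rate(2000, p, co) / bell_rate(1000, p, co),
               bell_rate(1000, p, co) / bell_rate(0, p, co), tolerance = 1e-9)
  expect_true(all(diff(bell_rate(c(0, 500, 1500, 4000), p, co)) > 0))
})

test_that("hydrolysis responds to reference point, pH decade and SASA", {
  co <- constants()
  p <- hydrolysis_params()
  expect_equal(hydrolysis_rate(p$F_ref, p$pH_ref, p$sasa_ref, p, co), p$k_ref)
  expect_equal(hydrolysis_rate(500, 7, 0, p, co), 0)
  expect_equal(hydrolysis_rate(0, 9, p$sasa_ref, p, co), 100 * p$k_ref)
  expect_equal(hydrolysis_rate(0, 7, 2 * p$sasa_ref, p, co), 2 * p$k_ref)
})

test_that("saturating hydrolysis is overtaken by Bell homolysis at high force", {
  co <- constants()
  hp <- hydrolysis_params()
  bp <- bell_params()
  hyd <- function(F) hydrolysis_rate(F, 7, hp$sasa_ref, hp, co)
  hom <- function(F) bell_rate(F, bp, co)
  # hydrolysis wins around 1 nN, homolysis at high force; a crossover exists
  expect_gt(hyd(1000), hom(1000))
  expect_lt(hyd(8000), hom(8000))
  fx <- stats::uniroot(function(F) log(hom(F)) - log(hyd(F)),
                       c(1000, 8000))$root
  expect_gt(fx, 1000)
  expect_lt(fx, 8000)
  # hydrolysis is bounded in force, Bell is not
  expect_lt(hyd(1e7), hyd(8000) * exp(hp$alpha * hp$F_sat))
})

test_that("dimerization rates honor the distance decay and angular window", {
  p <- dimer_params()
  expect_equal(dimerization_rate(50, 0, p), 0, tolerance = 1e-12)
  expect_equal(dimerization_rate(3.5, 90, p), 0)
  expect_equal(dimerization_rate(3.5, p$theta_max + 1, p), 0)
  expect_gt(dimerization_rate(3.0, 0, p), dimerization_rate(3.5, 0, p))
  expect_gt(dimerization_rate(3.5, 0, p), dimerization_rate(3.5, 40, p))
  expect_error(dimerization_rate(-1, 0, p), "negative")
})

test_that("quantum yield counts the dimerisable fraction", {
  p <- dimer_params()
  inside <- data.frame(distance = rep(1, 300), dihedral = 0)
  outside <- data.frame(distance = rep(20, 700), dihedral = 0)
  s <- rbind(inside, outside)
  expect_equal(quantum_yield(s, p), 0.300)
  # monotone non-increasing in the threshold
  th <- c(1e5, 1e7, 1e9, 1e11)
  phis <- vapply(th, function(x) {
    quantum_yield(s, dimer_params(rate_threshold = x))
  }, numeric(1))
  expect_true(all(diff(phis) <= 0))
  expect_error(quantum_yield(s[0, ], p), "empty")
})

test_that("the surrogate barrier is a pure table-plus-distance function", {
  fx <- build_alkyl_radical(8, 1)
  t <- fx$topology
  h <- hydrogens_on(t, 5)[1]
  tab <- barrier_table()
  b1 <- surrogate_hat_barrier(t, h, 1, fx$frame, tab)
  b2 <- surrogate_hat_barrier(t, h, 1, fx$frame, tab)
  expect_identical(b1, b2)

  # at the product bond length the bare table value is returned
  f <- fx$frame
  f$positions[h, ] <- f$positions[1, ] + c(1.1, 0, 0)
  expect_equal(surrogate_hat_barrier(t, h, 1, f, tab),
               unname(tab$barriers["1-5"]))
  # ring-strain ordering of the shipped table: 1-2, 1-3 highest, 1-5 lowest
  shifts <- c("1-2", "1-3", "1-4", "1-5", "1-6")
  bars <- tab$barriers[shifts]
  expect_equal(names(which.min(bars)), "1-5")
  expect_true(all(bars[c("1-2", "1-3")] > max(bars[c("1-4", "1-5", "1-6")])))
  expect_gt(bars["1-3"], bars["1-4"])

  # missing entries fall back to the default, or error without one
  tab2 <- barrier_table(barriers = c("1-2" = 30), default = 25)
  expect_equal(surrogate_hat_barrier(t, h, 1, f, tab2), 25)
  tab3 <- barrier_table(barriers = c("1-2" = 30), default = NA)
  expect_error(surrogate_hat_barrier(t, h, 1, f, tab3), "no table entry")
})
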