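small_hat_config <- function(seed, max_steps, n_carbons = 6) {
  fx <- build_alkyl_radical(n_carbons, 1)
  run_config(topology = fx$topology, coordinates = fx$frame,
             plugins = list(list(name = "hat")),
             sampler = list(n_steps = 200, stride = 100),
             equilibration = list(n_steps = 100),
             max_steps = max_steps, seed = seed)
}

test_that("a zero-step budget returns the input unchanged", {
  fx <- build_alkyl_radical(4, 1)
  cfg <- run_config(topology = fx$topology, coordinates = fx$frame,
                    plugins = list("hat"), max_steps = 0, seed = 1)
  res <- run_emulation(cfg)
  expect_length(res$records, 0)
  expect_equal(res$topology$bonds, fx$topology$bonds)
  expect_equal(res$frame$positions, fx$frame$positions)
  expect_equal(res$sim_time, 0)
})

test_that("each cycle logs provenance and advances simulated time", {
  res <- run_emulation(small_hat_config(23, 5))
  expect_length(res$records, 5)
  for (r in res$records) {
    expect_true(r$u1 > 0 && r$u1 <= 1 && r$u2 > 0 && r$u2 <= 1)
    expect_gt(r$delta_t, 0)
    expect_true(is.data.frame(r$events) && nrow(r$events) >= 1)
    expect_equal(r$rng_algorithm, "Mersenne-Twister")
    expect_match(r$topology_digest, "^19a:18b:")
  }
  expect_equal(res$sim_time,
               sum(vapply(res$records, `[[`, numeric(1), "delta_t")))
  expect_true(all(diff(vapply(res$records, `[[`, numeric(1), "sim_time")) > 0))
  # HAT keeps exactly one radical alive
  expect_length(res$records[[5]]$radicals, 1)
})

test_that("identical seeds reproduce runs bitwise; different seeds do not", {
  a <- run_emulation(small_hat_config(9, 6))
  b <- run_emulation(small_hat_config(9, 6))
  expect_identical(a$records, b$records)
  expect_identical(a$frame$positions, b$frame$positions)
  c <- run_emulation(small_hat_config(10, 6))
  expect_false(identical(a$records, c$records))
})

test_that("checkpointed runs continue identically to uninterrupted ones", {
  full <- run_emulation(small_hat_config(9, 10))
  head5 <- run_emulation(small_hat_config(9, 5))
  ck <- withr::local_tempfile(fileext = ".json")
  checkpoint_state(head5, ck)
  cont <- run_emulation(small_hat_config(9, 10), resume = restore_state(ck))
  expect_length(cont$records, 5)
  expect_identical(cont$records, full$records[6:10])
  expect_identical(cont$frame$positions, full$frame$positions)
})

test_that("checkpoints validate their format and plugin set", {
  res <- run_emulation(small_hat_config(4, 2))
  ck <- withr::local_tempfile(fileext = ".json")
  checkpoint_state(res, ck)
  st <- restore_state(ck)
  expect_equal(st$step, 2)
  expect_identical(st$rng$state, res$rng$state)

  fx <- build_alkyl_radical(6, 1)
  other <- run_config(topology = fx$topology, coordinates = fx$frame,
                      plugins = list(list(name = "homolysis",
                                          params = list(bonds = data.frame(ai = 1, aj = 2)))),
                      max_steps = 4, seed = 4)
  expect_error(run_emulation(other, resume = st), "plugin set")

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{\"format\": \"something-else\"}", bad)
  expect_error(restore_state(bad), "not a checkpoint")
  bad2 <- withr::local_tempfile(fileext = ".json")
  writeLines("not json at all {", bad2)
  expect_error(restore_state(bad2), "cannot read")
})

test_that("an empty event list halts gracefully after retries", {
  fx <- build_alkane(3)  # saturated: no radicals, no HAT candidates
  cfg <- run_config(topology = fx$topology, coordinates = fx$frame,
                    plugins = list("hat"),
                    sampler = list(n_steps = 50, stride = 50),
                    max_steps = 5, seed = 2, retries = 1)
  res <- run_emulation(cfg)
  expect_true(res$halted)
  expect_length(res$records, 0)
})

test_that("configs round trip through YAML with relative paths", {
  dir <- withr::local_tempdir()
  fx <- build_alkyl_radical(5, 1)
  write_topology(fx$topology, file.path(dir, "mol.top"))
  write_frames(ensemble(list(fx$frame)), file.path(dir, "mol.xyz"), fx$topology)
  writeLines(c("topology: mol.top",
               "coordinates: mol.xyz",
               "seed: 6",
               "max_steps: 2",
               "sampler: {n_steps: 100, stride: 100}",
               "equilibration: {n_steps: 50}",
               "plugins:",
               "  - name: hat",
               "    params: {cutoff: 7.0}"),
             file.path(dir, "run.yaml"))
  cfg <- run_config_from_yaml(file.path(dir, "run.yaml"))
  expect_equal(cfg$seed, 6)
  res <- run_emulation(cfg)
  expect_length(res$records, 2)
  expect_equal(res$records[[1]]$chosen_type, "hat")
})

test_that("competing plugins contribute to one event list", {
  w <- build_dipeptide_water()
  cfg <- run_config(
    topology = w$topology, coordinates = w$frame,
    plugins = list(
      list(name = "homolysis",
           params = list(bonds = data.frame(ai = w$peptide_c, aj = w$peptide_n),
                         force = 4000)),
      list(name = "hydrolysis",
           params = list(sites = data.frame(c = w$peptide_c, n = w$peptide_n,
                                            water_o = w$water_o,
                                            water_h = w$water_h),
                         force = 4000, pH = 7))),
    sampler = list(n_steps = 0),
    equilibration = list(n_steps = 0),
    max_steps = 1, seed = 3)
  res <- run_emulation(cfg)
  expect_length(res$records, 1)
  ev <- res$records[[1]]$events
  expect_setequal(ev$type, c("homolysis", "hydrolysis"))
  expect_true(res$records[[1]]$chosen_type %in% c("homolysis", "hydrolysis"))
  # at 4 nN the Bell channel dominates the saturating hydrolysis heuristic
  expect_gt(ev$rate[ev$type == "homolysis"], ev$rate[ev$type == "hydrolysis"])
})

test_that("run logs are written as TSV tables", {
  dir <- withr::local_tempdir()
  fx <- build_alkyl_radical(5, 1)
  cfg <- run_config(topology = fx$topology, coordinates = fx$frame,
                    plugins = list("hat"),
                    sampler = list(n_steps = 100, stride = 100),
                    equilibration = list(n_steps = 50),
                    max_steps = 3, seed = 11, output_dir = dir)
  res <- run_emulation(cfg)
  steps <- utils::read.delim(file.path(dir, "steps.tsv"))
  expect_equal(nrow(steps), 3)
  expect_true(all(c("chosen_label", "delta_t", "u1", "u2") %in% names(steps)))
  rates <- utils::read.delim(file.path(dir, "rates.tsv"))
  expect_equal(sum(rates$chosen), 3)
})

test_that("the dimerization plugin rates frames by stack geometry", {
  y <- build_pyrimidine_pair(separation = 3.2)
  ens <- ensemble(list(y$frame))
  ev <- dimerization_plugin(y$topology, ens,
                            params = list(sites = data.frame(c5a = y$c5a, c6a = y$c6a,
                                                             c5b = y$c5b, c6b = y$c6b)))
  expect_length(ev, 1)
  expect_gt(ev[[1]]$rate, 0)
  far <- build_pyrimidine_pair(separation = 9)
  ev2 <- dimerization_plugin(far$topology, ensemble(list(far$frame)),
                             params = list(sites = data.frame(c5a = 1, c6a = 2,
                                                              c5b = 7, c6b = 8)))
  expect_lt(ev2[[1]]$rate, ev[[1]]$rate)
})
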