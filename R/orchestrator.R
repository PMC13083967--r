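# The emulation cycle: sample an ensemble of the current state, query every
# enabled reaction plugin for candidate events, select one event by
# rejection-free kMC, effect its recipe on the topology and coordinates,
# equilibrate the product, and repeat. State transitions are Markov: each
# cycle depends only on the current (topology, frame) and the RNG stream.

#' Build and validate a run configuration
#'
#' @param topology A [topology()] object or path to a topology file.
#' @param coordinates A [frame()] object or path to an XYZ/PDB file (first
#'   frame used).
#' @param plugins List of enabled reaction plugins, each a list with
#'   `name` (registry key) and optional `params`.
#' @param sampler Named list of [sampler_config()] overrides for the
#'   per-cycle reaction-sampling ensemble.
#' @param equilibration Named list of overrides for the post-reaction
#'   equilibration run (default 200 steps).
#' @param max_steps Total kMC step budget (0 allowed).
#' @param max_time Simulated-time stopping criterion, s.
#' @param seed Integer master seed; every random draw in the run flows
#'   from it.
#' @param retries How many fresh ensembles to try when no candidate
#'   reaction is found before halting gracefully.
#' @param output_dir Optional directory for TSV step/rate logs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(topology, coordinates, plugins,
                       sampler = list(), equilibration = list(),
                       max_steps = 10, max_time = Inf, seed = 1,
                       retries = 3, output_dir = NULL) {
  stopifnot(length(plugins) >= 1)
  stopifnot(is.finite(max_steps) || is.finite(max_time))
  plugins <- lapply(plugins, function(p) {
    if (is.character(p)) p <- list(name = p)
    stopifnot(!is.null(p$name))
    get_reaction_plugin(p$name)  # fail early on unknown names
    p$params <- p$params %||% list()
    p
  })
  structure(list(topology = topology, coordinates = coordinates,
                 plugins = plugins, sampler = sampler,
                 equilibration = equilibration,
                 max_steps = as.integer(max_steps), max_time = max_time,
                 seed = as.integer(seed), retries = as.integer(retries),
                 output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Schema (version 1): top-level keys `topology`, `coordinates`, `seed`,
#' `max_steps`, `max_time`, `retries`, `output_dir`, `sampler` (mapping),
#' `equilibration` (mapping) and `plugins` (sequence of mappings with
#' `name` and `params`). Paths are resolved relative to the config file.
#'
#' @param path Path to the YAML file.
#' @return A [run_config()].
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) {
    if (is.character(p) && !file.exists(p) && file.exists(file.path(base, p))) {
      file.path(base, p)
    } else p
  }
  run_config(topology = resolve(y$topology),
             coordinates = resolve(y$coordinates),
             plugins = y$plugins,
             sampler = y$sampler %||% list(),
             equilibration = y$equilibration %||% list(),
             max_steps = y$max_steps %||% 10,
             max_time = y$max_time %||% Inf,
             seed = y$seed %||% 1,
             retries = y$retries %||% 3,
             output_dir = y$output_dir)
}

resolve_topology <- function(x) {
  if (inherits(x, "topology")) x else read_topology(x)
}

resolve_frame <- function(x, t) {
  if (inherits(x, "frame")) x else read_frames(x, t)$frames[[1]]
}

make_sampler_cfg <- function(overrides, seed) {
  args <- overrides
  args$seed <- seed
  do.call(sampler_config, args)
}

#' Run the reaction emulation cycle
#'
#' Per cycle: (1) sample a conformational ensemble of the current state
#' with the toy stochastic-dynamics sampler; (2) collect candidate events
#' from every enabled plugin, with rates computed fresh from this
#' ensemble (the event list of a state is built only when the state is
#' visited); (3) select one event and a waiting time by rejection-free
#' kMC; (4) apply the chosen recipe and equilibrate the product. Halts
#' when the step or simulated-time budget is reached, or -- after
#' `retries` fresh ensembles with an empty event list -- gracefully with
#' the records so far.
#'
#' @param config A [run_config()].
#' @param resume Optional state from [restore_state()] to continue a
#'   checkpointed run; `config$max_steps` is the total budget including
#'   the completed steps.
#' @return An object of class `kmc_run`: `records` (one per step, with the
#'   event-list digest, chosen event, `u1`, `u2`, `delta_t`, cumulative
#'   simulated time, product digest and radical set), `frames` (per-step
#'   product frames), final `topology` and `frame`, and `rng` state.
#' @export
run_emulation <- function(config, resume = NULL) {
  stopifnot(inherits(config, "run_config"))
  consts <- constants(T = config$sampler$temperature %||% 300)
  rng <- rng_new(config$seed)
  if (is.null(resume)) {
    t <- resolve_topology(config$topology)
    problems <- validate_topology(t)
    if (length(problems)) stop("run_emulation: ", problems[1])
    f <- resolve_frame(config$coordinates, t)
    step0 <- 0L
    sim_time <- 0
  } else {
    plugin_names <- vapply(config$plugins, `[[`, character(1), "name")
    if (!identical(sort(plugin_names), sort(resume$plugins))) {
      stop("run_emulation: plugin set does not match checkpoint")
    }
    t <- resume$topology
    f <- resume$frame
    step0 <- resume$step
    sim_time <- resume$sim_time
    rng_set_state(rng, resume$rng)
  }

  records <- list()
  frames <- list()
  step <- step0
  halted <- FALSE

  while (step < config$max_steps && sim_time < config$max_time) {
    # (1) sample: fresh ensemble of the current state, retrying if no
    # plugin proposes any reaction
    ens <- NULL; el <- NULL; ev <- list(); sampler_seed <- NA_integer_
    for (try in seq_len(config$retries + 1L)) {
      sampler_seed <- rng_spawn_seed(rng)
      ens <- toy_sd_sample(t, f, make_sampler_cfg(config$sampler, sampler_seed))
      ev <- list()
      for (p in config$plugins) {
        fn <- get_reaction_plugin(p$name)
        got <- tryCatch(fn(t, ens, p$params, consts), error = function(e) {
          stop("run_emulation: plugin '", p$name, "' failed at step ",
               step + 1L, ": ", conditionMessage(e))
        })
        ev <- c(ev, got)
      }
      el <- event_list(lapply(ev, `[[`, "recipe"),
                       vapply(ev, `[[`, numeric(1), "rate"))
      if (total_rate(el) > 0) break
    }
    if (is.null(el) || total_rate(el) <= 0) { halted <- TRUE; break }

    # (2)+(3) choose reaction and waiting time
    sel <- rf_kmc_step(el, rng)
    chosen <- ev[[sel$chosen_index]]

    # (4) effect reaction on the provenance frame, then equilibrate
    apply_frame <- ens$frames[[chosen$recipe$provenance$frame_index %||%
                                length(ens$frames)]]
    product <- tryCatch(apply_recipe(t, apply_frame, chosen$recipe),
                        error = function(e) {
                          stop("run_emulation: recipe failed at step ",
                               step + 1L, ": ", conditionMessage(e))
                        })
    equil_seed <- rng_spawn_seed(rng)
    eq_over <- config$equilibration
    if (is.null(eq_over$n_steps)) eq_over$n_steps <- 200L
    if (is.null(eq_over$stride)) eq_over$stride <- eq_over$n_steps
    t <- product$topology
    f <- if (eq_over$n_steps > 0) {
      eq <- toy_sd_sample(t, product$frame, make_sampler_cfg(eq_over, equil_seed))
      eq$frames[[length(eq$frames)]]
    } else product$frame

    step <- step + 1L
    sim_time <- sim_time + sel$delta_t
    rad <- find_radicals(t)
    records[[length(records) + 1L]] <- list(
      step = step,
      events = data.frame(
        type = vapply(ev, `[[`, character(1), "type"),
        atoms = vapply(ev, function(e) paste(e$atoms, collapse = "-"), character(1)),
        label = vapply(ev, `[[`, character(1), "label"),
        rate = el$rates),
      chosen_index = sel$chosen_index,
      chosen_type = chosen$type,
      chosen_label = chosen$label,
      chosen_atoms = chosen$atoms,
      u1 = sel$u1, u2 = sel$u2, delta_t = sel$delta_t,
      sim_time = sim_time,
      sampler_seed = sampler_seed, equil_seed = equil_seed,
      rng_algorithm = rng$algorithm,
      topology_digest = topology_digest(t),
      radicals = rad$atom)
    frames[[length(frames) + 1L]] <- f
  }

  result <- structure(list(records = records, frames = frames,
                           topology = t, frame = f,
                           sim_time = sim_time, halted = halted,
                           config = config, rng = rng_get_state(rng)),
                      class = "kmc_run")
  if (!is.null(config$output_dir)) write_run_logs(result, config$output_dir)
  result
}

#' @export
print.kmc_run <- function(x, ...) {
  cat(sprintf("kmc_run: %d step(s), simulated time %.3g s%s\n",
              length(x$records), x$sim_time,
              if (x$halted) " (halted: no reactions found)" else ""))
  invisible(x)
}

write_run_logs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  steps <- do.call(rbind, lapply(result$records, function(r) {
    data.frame(step = r$step, chosen_type = r$chosen_type,
               chosen_label = r$chosen_label,
               chosen_atoms = paste(r$chosen_atoms, collapse = "-"),
               u1 = r$u1, u2 = r$u2, delta_t = r$delta_t,
               sim_time = r$sim_time, topology_digest = r$topology_digest)
  }))
  rates <- do.call(rbind, lapply(result$records, function(r) {
    cbind(step = r$step, r$events,
          chosen = seq_len(nrow(r$events)) == r$chosen_index)
  }))
  if (!is.null(steps)) {
    utils::write.table(steps, file.path(dir, "steps.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(rates)) {
    utils::write.table(rates, file.path(dir, "rates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Checkpoint and restore emulation state
#'
#' The checkpoint is a JSON file carrying the step index, simulated time,
#' topology (in its text dialect), coordinates, enabled plugin names and
#' the exact RNG state, so a restored run continues bitwise identically to
#' an uninterrupted one.
#'
#' @param result A [run_emulation()] result.
#' @param path Checkpoint file path.
#' @return `checkpoint_state`: `path` invisibly. `restore_state`: a state
#'   list accepted by `run_emulation(config, resume = )`.
#' @export
checkpoint_state <- function(result, path) {
  stopifnot(inherits(result, "kmc_run"))
  last_step <- if (length(result$records)) {
    result$records[[length(result$records)]]$step
  } else 0L
  # floats go through "%.17g" strings: JSON number printing is lossy, and
  # the restore contract is bitwise continuation
  payload <- list(
    format = "kmcreact-checkpoint",
    version = 1L,
    step = last_step,
    sim_time = sprintf("%.17g", result$sim_time),
    plugins = vapply(result$config$plugins, `[[`, character(1), "name"),
    topology = write_topology(result$topology),
    positions = sprintf("%.17g", as.vector(result$frame$positions)),
    frame_time = sprintf("%.17g", result$frame$time),
    rng = result$rng)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname checkpoint_state
#' @export
restore_state <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        stop("restore_state: cannot read checkpoint: ",
                             conditionMessage(e))
                      })
  if (!identical(payload$format, "kmcreact-checkpoint")) {
    stop("restore_state: not a checkpoint file")
  }
  t <- parse_topology(payload$topology)
  x <- matrix(as.numeric(payload$positions), ncol = 3)
  list(step = as.integer(payload$step),
       sim_time = as.numeric(payload$sim_time),
       plugins = as.character(payload$plugins),
       topology = t,
       frame = frame(x, time = as.numeric(payload$frame_time)),
       rng = list(algorithm = payload$rng$algorithm,
                  seed = as.integer(payload$rng$seed),
                  state = as.integer(payload$rng$state)))
}
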