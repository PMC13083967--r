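# Reaction plugins: each plugin inspects the current topology and
# conformational ensemble and proposes candidate reactions as
# (recipe, rate) events. Plugins are discovered by name through a registry,
# so new reaction types can be added without touching the cycle.
#
# Plugin contract:
#   function(t, ens, params, consts) -> list of
#     list(recipe, rate, type, atoms, label)

.plugin_registry <- new.env(parent = emptyenv())

#' Register / look up reaction plugins by name
#'
#' @param name Plugin name used in run configurations.
#' @param fn Function `(topology, ensemble, params, constants)` returning a
#'   list of candidate events, each a list with at least `recipe` and
#'   `rate` (and optionally `type`, `atoms`, `label`).
#' @return `register_reaction_plugin` returns `name` invisibly;
#'   `get_reaction_plugin` returns the plugin function;
#'   `list_reaction_plugins` the registered names.
#' @export
register_reaction_plugin <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  assign(name, fn, envir = .plugin_registry)
  invisible(name)
}

#' @rdname register_reaction_plugin
#' @export
get_reaction_plugin <- function(name) {
  if (!exists(name, envir = .plugin_registry, inherits = FALSE)) {
    stop("unknown reaction plugin '", name, "' (see list_reaction_plugins())")
  }
  get(name, envir = .plugin_registry, inherits = FALSE)
}

#' @rdname register_reaction_plugin
#' @export
list_reaction_plugins <- function() sort(ls(.plugin_registry))

#' Hydrogen atom transfer plugin
#'
#' Candidate reactions are (hydrogen, radical acceptor) pairs that come
#' within `params$cutoff` A in at least one ensemble frame. Each
#' candidate's barrier is evaluated per frame by the configured predictor
#' (default [surrogate_hat_barrier()] with the shipped [barrier_table()]),
#' and the event rate is the ensemble average of the per-frame Eyring
#' rates. The recipe's placement frame is the frame of closest approach.
#'
#' `params`: `cutoff` (A, default 7), `table` (a [barrier_table()]),
#' `max_shift` (default 6), `predictor` (function with the
#' [surrogate_hat_barrier()] signature).
#'
#' @param t A [topology()].
#' @param ens An [ensemble()].
#' @param params Named list, see above.
#' @param consts A [constants()] object.
#' @return List of candidate events.
#' @export
hat_plugin <- function(t, ens, params = list(), consts = constants()) {
  cutoff <- params$cutoff %||% 7.0
  table <- params$table %||% barrier_table()
  max_shift <- params$max_shift %||% 6
  predictor <- params$predictor %||% surrogate_hat_barrier

  rad <- find_radicals(t)
  if (!nrow(rad)) return(list())
  deg <- tabulate(c(t$bonds$ai, t$bonds$aj), nbins = n_atoms(t))
  hydrogens <- t$atoms$index[t$atoms$element == "H" & deg == 1]
  if (!length(hydrogens)) return(list())

  donor_of <- function(h) {
    c(t$bonds$aj[t$bonds$ai == h], t$bonds$ai[t$bonds$aj == h])[1]
  }

  events <- list()
  for (h in hydrogens) {
    donor <- donor_of(h)
    for (a in rad$atom) {
      if (donor == a) next
      d <- vapply(ens$frames, function(f) {
        sqrt(sum((f$positions[h, ] - f$positions[a, ])^2))
      }, numeric(1))
      if (min(d) > cutoff) next
      barriers <- vapply(seq_along(ens$frames), function(k) {
        predictor(t, h, a, ens$frames[[k]], table)
      }, numeric(1))
      rate <- ensemble_average_rate(barriers, consts)
      k_best <- which.min(d)
      rec <- make_hat_recipe(t, h, a, ens$frames[[k_best]],
                             frame_index = k_best)
      label <- classify_shift(t, a, donor, max_shift = max_shift)
      rec$provenance$shift <- label
      rec$provenance$d_min <- min(d)
      events[[length(events) + 1L]] <-
        list(recipe = rec, rate = rate, type = "hat",
             atoms = c(h, donor, a), label = label)
    }
  }
  events
}

#' Homolysis plugin (Bell model)
#'
#' Candidate bonds and their per-bond forces come from the configuration;
#' rates follow the force-accelerated [bell_rate()].
#'
#' `params`: `bonds` (data frame with columns `ai`, `aj` and optionally
#' `force` in pN), `force` (scalar fallback, pN, default 0), `bell`
#' (a [bell_params()]).
#'
#' @inheritParams hat_plugin
#' @return List of candidate events.
#' @export
homolysis_plugin <- function(t, ens, params = list(), consts = constants()) {
  sites <- params$bonds
  if (is.null(sites) || !nrow(sites)) return(list())
  bp <- params$bell %||% bell_params()
  force <- sites$force %||% rep(params$force %||% 0, nrow(sites))
  lapply(seq_len(nrow(sites)), function(r) {
    i <- sites$ai[r]; j <- sites$aj[r]
    list(recipe = make_homolysis_recipe(t, i, j),
         rate = bell_rate(force[r], bp, consts),
         type = "homolysis", atoms = c(i, j), label = "homolysis")
  })
}

#' Hydrolysis plugin (force/pH/SASA heuristic)
#'
#' `params`: `sites` (data frame with columns `c`, `n`, `water_o`,
#' `water_h` and optionally `sasa`, `force`), `force` and `sasa` scalar
#' fallbacks, `pH` (default 7), `hydrolysis` (a [hydrolysis_params()]).
#'
#' @inheritParams hat_plugin
#' @return List of candidate events.
#' @export
hydrolysis_plugin <- function(t, ens, params = list(), consts = constants()) {
  sites <- params$sites
  if (is.null(sites) || !nrow(sites)) return(list())
  hp <- params$hydrolysis %||% hydrolysis_params()
  pH <- params$pH %||% 7
  force <- sites$force %||% rep(params$force %||% 0, nrow(sites))
  sasa <- sites$sasa %||% rep(params$sasa %||% hp$sasa_ref, nrow(sites))
  lapply(seq_len(nrow(sites)), function(r) {
    list(recipe = make_hydrolysis_recipe(t, sites$c[r], sites$n[r],
                                         sites$water_o[r], sites$water_h[r]),
         rate = hydrolysis_rate(force[r], pH, sasa[r], hp, consts),
         type = "hydrolysis",
         atoms = c(sites$c[r], sites$n[r]), label = "hydrolysis")
  })
}

#' Photodimerization plugin (distance-and-angle heuristic)
#'
#' For each configured pair of stacked double bonds, the per-frame
#' (distance, dihedral) geometry is converted to a rate by
#' [dimerization_rate()] and averaged over the ensemble.
#'
#' `params`: `sites` (data frame with columns `c5a`, `c6a`, `c5b`, `c6b`),
#' `dimer` (a [dimer_params()]).
#'
#' @inheritParams hat_plugin
#' @return List of candidate events.
#' @export
dimerization_plugin <- function(t, ens, params = list(), consts = constants()) {
  sites <- params$sites
  if (is.null(sites) || !nrow(sites)) return(list())
  dp <- params$dimer %||% dimer_params()
  lapply(seq_len(nrow(sites)), function(r) {
    geo <- lapply(ens$frames, dimer_geometry, c5a = sites$c5a[r],
                  c6a = sites$c6a[r], c5b = sites$c5b[r], c6b = sites$c6b[r])
    rates <- vapply(geo, function(g) {
      dimerization_rate(g$distance, g$dihedral, dp)
    }, numeric(1))
    list(recipe = make_dimerization_recipe(t, sites$c5a[r], sites$c6a[r],
                                           sites$c5b[r], sites$c6b[r]),
         rate = mean(rates), type = "dimerization",
         atoms = unlist(sites[r, c("c5a", "c6a", "c5b", "c6b")]),
         label = "dimerization")
  })
}

register_reaction_plugin("hat", hat_plugin)
register_reaction_plugin("homolysis", homolysis_plugin)
register_reaction_plugin("hydrolysis", hydrolysis_plugin)
register_reaction_plugin("dimerization", dimerization_plugin)
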