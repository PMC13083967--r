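# Post-hoc analysis: hydrogen shift classification, selection
# probabilities across runs, rate convergence, radical migration distances
# and quantum-yield summaries.

#' Classify a hydrogen shift by donor-acceptor separation
#'
#' A shift between atoms `k` bonds apart in the same molecule is labelled
#' `"1-(k+1)"` -- both endpoint heavy atoms are counted, so the 1-5 shift
#' (4 bonds apart) passes through a six-membered transition ring. Shifts
#' beyond `max_shift` bonds are `"long-range"`; shifts between molecules
#' are `"intermolecular"`.
#'
#' @param t A [topology()].
#' @param acceptor Radical acceptor atom index.
#' @param donor_heavy Donor heavy atom index.
#' @param max_shift Largest bond separation still labelled `1-n`
#'   (default 6 bonds, i.e. up to `"1-7"`).
#' @return A single label string.
#' @export
classify_shift <- function(t, acceptor, donor_heavy, max_shift = 6) {
  if (!all(c(acceptor, donor_heavy) %in% t$atoms$index)) {
    stop("classify_shift: atom index out of range")
  }
  d <- graph_distance(t, acceptor, donor_heavy)
  if (is.infinite(d)) return("intermolecular")
  if (d > max_shift) return("long-range")
  sprintf("1-%d", as.integer(d) + 1L)
}

#' Selection probabilities per shift label across runs
#'
#' Counts how often events with each label were chosen, restricted to the
#' `considered` labels, and normalizes to sum 1. Labels outside
#' `considered` are excluded before normalizing (mirroring comparisons
#' where experimentally unobservable shifts are set to probability 0).
#'
#' @param labels Character vector of chosen-event labels, pooled over runs
#'   (e.g. `chosen_label` column of [run_emulation()] records).
#' @param considered Character vector of labels to keep.
#' @return Named numeric vector of probabilities over `considered`,
#'   summing to 1.
#' @export
selection_probabilities <- function(labels,
                                    considered = sort(unique(labels))) {
  if (!length(labels)) stop("selection_probabilities: no events")
  kept <- labels[labels %in% considered]
  if (!length(kept)) stop("selection_probabilities: no events in considered set")
  counts <- table(factor(kept, levels = considered))
  p <- as.numeric(counts) / length(kept)
  stats::setNames(p, considered)
}

#' Running mean rate versus number of barrier predictions
#'
#' For each requested block size `k`, the mean over the first `k`
#' per-prediction rates -- the convergence diagnostic for how many barrier
#' evaluations per reaction are needed for a stable mean rate.
#'
#' @param rates Numeric vector of per-prediction rates, 1/s.
#' @param block_sizes Integer vector of prefix lengths (default: all).
#' @return Data frame with columns `k` and `mean_rate`.
#' @export
rate_convergence <- function(rates, block_sizes = seq_along(rates)) {
  stopifnot(length(rates) >= 1, all(block_sizes >= 1),
            all(block_sizes <= length(rates)))
  cm <- cumsum(rates) / seq_along(rates)
  data.frame(k = as.integer(block_sizes), mean_rate = cm[block_sizes])
}

#' Radical migration distance from the cleavage origin
#'
#' For each kMC step, the Euclidean distance between every current radical
#' atom and its nearest origin atom (for example the two atoms of a
#' homolytically cleaved bond), measured in that step's product frame.
#'
#' @param result A [run_emulation()] result (uses `records[[i]]$radicals`
#'   and the per-step product frames).
#' @param origin_atoms Integer vector of origin atom indices.
#' @return Data frame with columns `step`, `atom`, `distance` (A).
#' @export
migration_distance <- function(result, origin_atoms) {
  stopifnot(length(origin_atoms) >= 1)
  rows <- list()
  for (i in seq_along(result$records)) {
    rec <- result$records[[i]]
    x <- result$frames[[i]]$positions
    for (a in rec$radicals) {
      d <- sqrt(colSums((t(x[origin_atoms, , drop = FALSE]) - x[a, ])^2))
      rows[[length(rows) + 1L]] <- data.frame(step = rec$step, atom = a,
                                              distance = min(d))
    }
  }
  if (!length(rows)) {
    return(data.frame(step = integer(), atom = integer(), distance = numeric()))
  }
  do.call(rbind, rows)
}

#' Mean and standard deviation of per-ensemble quantum yields
#'
#' @param yields Numeric vector of per-simulation yields.
#' @return List with `mean`, `sd` (n-1 denominator; 0 with a `degenerate`
#'   flag when only one yield is supplied) and `n`.
#' @export
yield_summary <- function(yields) {
  stopifnot(length(yields) >= 1)
  list(mean = mean(yields),
       sd = if (length(yields) == 1) 0 else stats::sd(yields),
       n = length(yields),
       degenerate = length(yields) == 1)
}
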