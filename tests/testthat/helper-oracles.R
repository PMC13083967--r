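# Independent oracles, deliberately written without the package's graph
# machinery: plain breadth-first search and exhaustive path enumeration.

# all-pairs bond-graph distances by hand-rolled BFS
oracle_distances <- function(n, bonds) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds$ai[r]; j <- bonds$aj[r]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (is.infinite(d[s, nb])) {
          d[s, nb] <- d[s, cur] + 1
          queue <- c(queue, nb)
        }
      }
    }
  }
  d
}

# exhaustive enumeration of length-2 paths (angles), length-3 paths
# (proper dihedrals) and distance-3 pairs from a bond list
oracle_term_counts <- function(n, bonds) {
  has <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(bonds))) {
    has[bonds$ai[r], bonds$aj[r]] <- TRUE
    has[bonds$aj[r], bonds$ai[r]] <- TRUE
  }
  angles <- 0L
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    if (i < k && i != j && j != k && has[i, j] && has[j, k]) angles <- angles + 1L
  }
  dihedrals <- 0L
  for (i in 1:n) for (j in 1:n) for (k in 1:n) for (l in 1:n) {
    if (length(unique(c(i, j, k, l))) == 4 &&
        has[i, j] && has[j, k] && has[k, l]) {
      dihedrals <- dihedrals + 1L
    }
  }
  d <- oracle_distances(n, bonds)
  pairs <- sum(d[upper.tri(d)] == 3)
  list(angles = angles, dihedrals = dihedrals %/% 2L, pairs = pairs)
}

# random connected molecule: a random spanning tree plus a few extra edges
random_molecule <- function(n, extra = 2, seed = 1) {
  set.seed(seed)
  ai <- integer(); aj <- integer()
  for (v in 2:n) {
    p <- sample.int(v - 1, 1)
    ai <- c(ai, p); aj <- c(aj, v)
  }
  for (k in seq_len(extra)) {
    cand <- sample.int(n, 2)
    i <- min(cand); j <- max(cand)
    if (i != j && !any(ai == i & aj == j)) {
      ai <- c(ai, i); aj <- c(aj, j)
    }
  }
  at <- kmcreact:::atoms_frame(index = seq_len(n),
                               element = sample(c("C", "N", "O"), n, TRUE))
  topology(at, kmcreact:::bonds_frame(ai, aj, r0 = 1.5, kb = 300))
}

# small topology text fixtures
methane_text <- function() {
  c("[atoms]",
    "1 C CT 1 MET 0 12.011",
    "2 H HC 1 MET 0 1.008",
    "3 H HC 1 MET 0 1.008",
    "4 H HC 1 MET 0 1.008",
    "5 H HC 1 MET 0 1.008",
    "[bonds]",
    "1 2 1.09 340 1", "1 3 1.09 340 1", "1 4 1.09 340 1", "1 5 1.09 340 1")
}

ethane_text <- function() {
  c("[atoms]",
    "1 C CT 1 ETH 0 12.011", "2 C CT 1 ETH 0 12.011",
    "3 H HC 1 ETH 0 1.008", "4 H HC 1 ETH 0 1.008",
    "5 H HC 1 ETH 0 1.008", "6 H HC 1 ETH 0 1.008",
    "7 H HC 1 ETH 0 1.008", "8 H HC 1 ETH 0 1.008",
    "[bonds]",
    "1 2 1.526 310 1",
    "1 3 1.09 340 1", "1 4 1.09 340 1", "1 5 1.09 340 1",
    "2 6 1.09 340 1", "2 7 1.09 340 1", "2 8 1.09 340 1")
}

# hydrogen atoms of t bonded to the given heavy atom
hydrogens_on <- function(t, heavy) {
  hs <- t$atoms$index[t$atoms$element == "H"]
  hs[vapply(hs, function(h) {
    nb <- c(t$bonds$aj[t$bonds$ai == h], t$bonds$ai[t$bonds$aj == h])
    length(nb) == 1 && nb == heavy
  }, logical(1))]
}

# octyl-radical HAT run used by orchestrator-level checks
octyl_hat_config <- function(seed, max_steps = 30, n_steps = 400,
                             equil = 200) {
  fx <- build_alkyl_radical(8, 1)
  run_config(topology = fx$topology, coordinates = fx$frame,
             plugins = list(list(name = "hat")),
             sampler = list(n_steps = n_steps, stride = 100),
             equilibration = list(n_steps = equil),
             max_steps = max_steps, seed = seed)
}
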