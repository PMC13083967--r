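# Built-in fixture generators: alkane-derived radicals, a small peptide
# with one explicit water, a stacked pair of reactive double bonds standing
# in for two pyrimidine C5=C6 bonds, and a synthetic (distance, dihedral)
# geometry ensemble. All are generated in code from a seed; nothing is read
# from disk.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) return(c(1, 0, 0))
  v / n
}

CC_BOND <- 1.526; CH_BOND <- 1.09
CC_KB <- 310; CH_KB <- 340

#' Build an all-trans n-alkane
#'
#' Zig-zag backbone (C-C 1.526 A, C-C-C 111 deg) with tetrahedral
#' hydrogens. Carbons get indices 1..n; hydrogens follow. A small seeded
#' Gaussian jitter (sd 0.01 A) breaks exact planarity.
#'
#' @param n_carbons Number of carbons (>= 1).
#' @param seed Integer seed for the jitter.
#' @return List with elements `topology` and `frame`.
#' @export
build_alkane <- function(n_carbons, seed = 1) {
  build_chain(n_carbons, radical_carbon = NA, seed = seed)
}

#' Build an n-alkyl radical
#'
#' The all-trans alkane of [build_alkane()] with one hydrogen removed at
#' `radical_carbon`, leaving a single valence-deficit radical site.
#'
#' @param n_carbons Number of carbons, 3 to 8.
#' @param radical_carbon Carbon index carrying the radical (1 = chain end).
#' @param seed Integer seed for the geometry jitter.
#' @return List with elements `topology` and `frame`;
#'   `find_radicals(topology)` contains exactly `radical_carbon`.
#' @export
build_alkyl_radical <- function(n_carbons, radical_carbon = 1, seed = 1) {
  if (n_carbons < 3 || n_carbons > 8) {
    stop("build_alkyl_radical: n_carbons must be in 3..8")
  }
  if (radical_carbon < 1 || radical_carbon > n_carbons) {
    stop("build_alkyl_radical: radical_carbon out of range")
  }
  build_chain(n_carbons, radical_carbon = radical_carbon, seed = seed)
}

build_chain <- function(n_carbons, radical_carbon, seed) {
  stopifnot(n_carbons >= 1)
  half <- 111 / 2 * pi / 180
  dx <- CC_BOND * sin(half); dy <- CC_BOND * cos(half)
  cpos <- cbind((seq_len(n_carbons) - 1) * dx,
                ifelse(seq_len(n_carbons) %% 2 == 0, dy, 0), 0)

  pos <- list(); elem <- character()
  for (i in seq_len(n_carbons)) {
    pos[[i]] <- cpos[i, ]
    elem[i] <- "C"
  }
  tet <- 109.5 * pi / 180
  tau <- sqrt((1 + abs(cos(tet))) / (1 - abs(cos(tet))))  # H-C-H spread
  add_h <- function(at) {
    pos[[length(pos) + 1L]] <<- at
    elem[length(elem) + 1L] <<- "H"
    length(pos)
  }
  bonds_i <- integer(); bonds_j <- integer()
  r0 <- numeric(); kb <- numeric()
  add_bond <- function(i, j, r, k) {
    bonds_i <<- c(bonds_i, i); bonds_j <<- c(bonds_j, j)
    r0 <<- c(r0, r); kb <<- c(kb, k)
  }
  for (i in seq_len(max(0, n_carbons - 1))) add_bond(i, i + 1, CC_BOND, CC_KB)

  for (i in seq_len(n_carbons)) {
    nb <- c(if (i > 1) i - 1, if (i < n_carbons) i + 1)
    n_h <- 4L - length(nb) - (if (!is.na(radical_carbon) && i == radical_carbon) 1L else 0L)
    dirs <- if (length(nb) == 2) {
      u <- unit3(cpos[nb[1], ] - cpos[i, ]); v <- unit3(cpos[nb[2], ] - cpos[i, ])
      b <- unit3(-(u + v)); w <- unit3(cross3(u, v))
      list(unit3(b + tau * w), unit3(b - tau * w))
    } else {
      u <- if (length(nb) == 1) unit3(cpos[nb[1], ] - cpos[i, ]) else c(1, 0, 0)
      p <- unit3(cross3(u, c(0, 0, 1)))
      if (sqrt(sum(cross3(u, c(0, 0, 1))^2)) < 1e-6) p <- unit3(cross3(u, c(0, 1, 0)))
      q <- cross3(u, p)
      lapply(0:2 * (2 * pi / 3), function(th) {
        unit3(cos(tet) * u + sin(tet) * (cos(th) * p + sin(th) * q))
      })
    }
    for (k in seq_len(n_h)) {
      h <- add_h(cpos[i, ] + CH_BOND * dirs[[k]])
      add_bond(i, h, CH_BOND, CH_KB)
    }
  }

  x <- do.call(rbind, pos)
  rng <- rng_new(seed)
  x <- x + matrix(rng_norm(rng, 3 * nrow(x)), ncol = 3) * 0.01

  resnm <- paste0("AL", n_carbons)
  at <- atoms_frame(index = seq_along(elem), element = elem,
                    type_label = ifelse(elem == "C", "CT", "HC"),
                    residue_index = 1L, residue_name = resnm)
  t <- topology(at, bonds_frame(bonds_i, bonds_j, r0, kb))
  t <- regenerate_bonded_terms(t)
  list(topology = t, frame = frame(x))
}

# crude deterministic embedding for fixtures specified only as a graph:
# BFS placement at bond length from the parent, then steepest descent
embed_coordinates <- function(t, seed = 1, relax_steps = 300) {
  rng <- rng_new(seed)
  n <- n_atoms(t)
  adj <- adjacency_list(t)
  mem <- molecule_membership(t)
  x <- matrix(NA_real_, n, 3)
  b <- t$bonds
  bond_r0 <- function(i, j) {
    row <- which((b$ai == min(i, j)) & (b$aj == max(i, j)))
    r <- b$r0[row]
    if (is.na(r)) 1.4 else r
  }
  for (m in unique(mem)) {
    root <- which(mem == m)[1]
    x[root, ] <- c(6 * (m - 1), 0, 0)
    queue <- root
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in adj[[cur]]) {
        if (is.na(x[nb, 1])) {
          dir <- unit3(rng_norm(rng, 3))
          x[nb, ] <- x[cur, ] + dir * bond_r0(cur, nb)
          queue <- c(queue, nb)
        }
      }
    }
  }
  f <- frame(x)
  minimize_frame(assign_generic_parameters(t), f, n_steps = relax_steps)
}

#' Build a two-residue peptide plus one explicit water
#'
#' A glycylglycine-like fixture (all hydrogens explicit, carbonyls as
#' order-2 bonds) with a single water molecule, used by the hydrolysis and
#' homolysis recipes. Coordinates come from a seeded graph embedding
#' followed by relaxation; the fixture is about connectivity, not
#' conformation.
#'
#' @param seed Integer seed for the embedding.
#' @return List with `topology`, `frame`, and the role indices
#'   `peptide_c`, `peptide_n`, `water_o`, `water_h`.
#' @export
build_dipeptide_water <- function(seed = 1) {
  elem <- c("N", "H", "H", "C", "H", "H", "C", "O",
            "N", "H", "C", "H", "H", "C", "O", "O", "H",
            "O", "H", "H")
  type <- c("N", "H", "H", "CT", "H1", "H1", "C", "O",
            "N", "H", "CT", "H1", "H1", "C", "O", "OH", "HO",
            "OW", "HW", "HW")
  resi <- c(rep(1L, 8), rep(2L, 9), rep(3L, 3))
  resn <- c(rep("GLY", 17), rep("HOH", 3))
  at <- atoms_frame(index = 1:20, element = elem, type_label = type,
                    residue_index = resi, residue_name = resn)
  bi <- c(1, 1, 1, 4, 4, 4, 7, 7, 9, 9, 11, 11, 11, 14, 14, 16, 18, 18)
  bj <- c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 19, 20)
  ord <- rep(1, 18); ord[7] <- 2; ord[14] <- 2  # C=O carbonyls
  t <- topology(at, bonds_frame(bi, bj, order = ord))
  t <- regenerate_bonded_terms(t)
  f <- embed_coordinates(t, seed = seed)
  list(topology = t, frame = f,
       peptide_c = 7L, peptide_n = 9L, water_o = 18L, water_h = 19L)
}

#' Build a stacked pair of reactive double bonds
#'
#' A minimal synthetic stand-in for the C5=C6 bonds of two stacked
#' pyrimidine bases: two ethylene-like units (order-2 C=C, four hydrogens
#' each) stacked a configurable distance apart. Used by the dimerization
#' recipe, which closes the cyclobutane ring across the stack.
#'
#' @param separation Stacking distance between the two double bonds, A.
#' @param seed Integer seed for a small geometry jitter.
#' @return List with `topology`, `frame` and the ring-atom indices
#'   `c5a`, `c6a`, `c5b`, `c6b`.
#' @export
build_pyrimidine_pair <- function(separation = 3.5, seed = 1) {
  elem <- rep(c("C", "C", "H", "H", "H", "H"), 2)
  at <- atoms_frame(index = 1:12, element = elem,
                    type_label = ifelse(elem == "C", "CM", "HA"),
                    residue_index = rep(c(1L, 2L), each = 6),
                    residue_name = "THY")
  unit_bonds <- function(off) {
    data.frame(ai = off + c(1, 1, 1, 2, 2), aj = off + c(2, 3, 4, 5, 6),
               ord = c(2, 1, 1, 1, 1))
  }
  bb <- rbind(unit_bonds(0L), unit_bonds(6L))
  t <- topology(at, bonds_frame(bb$ai, bb$aj, order = bb$ord))
  t <- regenerate_bonded_terms(t)
  unit_xyz <- function(z) {
    rbind(c(0, 0, z), c(1.34, 0, z),
          c(-0.56, 0.92, z), c(-0.56, -0.92, z),
          c(1.90, 0.92, z), c(1.90, -0.92, z))
  }
  x <- rbind(unit_xyz(0), unit_xyz(separation))
  rng <- rng_new(seed)
  x <- x + matrix(rng_norm(rng, 36), ncol = 3) * 0.01
  list(topology = t, frame = frame(x),
       c5a = 1L, c6a = 2L, c5b = 7L, c6b = 8L)
}

wrap_angle <- function(x) {
  y <- ((x + 180) %% 360) - 180
  y[y == -180] <- 180
  y
}

#' Synthesize a (distance, dihedral) geometry feature ensemble
#'
#' Emulates the joint distance/dihedral distribution of stacked reactive
#' double bonds: distances from a normal truncated at zero, dihedrals from
#' a wrapped normal on (-180, 180] degrees.
#'
#' @param d_mean,d_sd Distance mean and sd, A (`d_sd >= 0`).
#' @param theta_mean,theta_sd Dihedral mean and sd, degrees.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Data frame with columns `distance` (A) and `dihedral` (deg).
#' @export
synth_dimer_geometry_ensemble <- function(d_mean, d_sd, theta_mean, theta_sd,
                                          n, seed = 1) {
  stopifnot(n >= 1, d_sd >= 0, theta_sd >= 0)
  rng <- rng_new(seed)
  u <- rng_unif(rng, n)
  d <- if (d_sd == 0) rep(d_mean, n) else {
    p0 <- stats::pnorm(0, mean = d_mean, sd = d_sd)
    stats::qnorm(p0 + u * (1 - p0), mean = d_mean, sd = d_sd)
  }
  z <- rng_norm(rng, n)
  th <- wrap_angle(theta_mean + theta_sd * z)
  data.frame(distance = d, dihedral = th)
}

# torsion angle (deg) of four points, standard sign convention
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit3(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# (distance, dihedral) features of a stacked double-bond pair in a frame:
# distance between bond midpoints, torsion over (c5a, c6a, c6b, c5b)
dimer_geometry <- function(f, c5a, c6a, c5b, c6b) {
  x <- f$positions
  mid_a <- (x[c5a, ] + x[c6a, ]) / 2
  mid_b <- (x[c5b, ] + x[c6b, ]) / 2
  list(distance = sqrt(sum((mid_a - mid_b)^2)),
       dihedral = torsion_angle(x[c5a, ], x[c6a, ], x[c6b, ], x[c5b, ]))
}
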