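# Toy force field: harmonic bonds V = kb (r - r0)^2, harmonic angles
# V = ktheta (theta - theta0)^2 and a soft purely repulsive penalty
# V = krep (r - rc)^2 for r < rc between atoms at bond-graph distance >= 4
# or in different molecules. No electrostatics, no torsional energies, no
# periodic boundaries: the contract is correct Boltzmann sampling of a
# well-defined toy energy, not force-field realism.

REPULSION_CUTOFF <- 2.5  # A
REPULSION_K <- 10        # kcal mol^-1 A^-2

ff_compile <- function(t) {
  b <- t$bonds; a <- t$angles
  if (nrow(b) && any(is.na(b$r0) | is.na(b$kb))) {
    stop("ff_compile: unparameterized bond (run assign_generic_parameters)")
  }
  if (nrow(a) && any(is.na(a$theta0) | is.na(a$ktheta))) {
    stop("ff_compile: unparameterized angle (run assign_generic_parameters)")
  }
  rep_i <- integer(); rep_j <- integer()
  if (nrow(b)) {
    dm <- igraph::distances(bond_graph(t))
    ord <- match(as.character(t$atoms$index), rownames(dm))
    dm <- dm[ord, ord]
    idx <- which((dm >= 4 | is.infinite(dm)) & upper.tri(dm), arr.ind = TRUE)
    rep_i <- idx[, 1]; rep_j <- idx[, 2]
  }
  list(n = n_atoms(t),
       b_i = b$ai, b_j = b$aj, b_r0 = b$r0, b_k = b$kb,
       a_i = a$ai, a_j = a$aj, a_k = a$ak,
       a_t0 = a$theta0 * pi / 180, a_kt = a$ktheta,
       rep_i = rep_i, rep_j = rep_j,
       mass = t$atoms$mass)
}

row_norms <- function(m) sqrt(rowSums(m * m))

scatter_add <- function(F, idx, contrib) {
  s <- rowsum(contrib, idx)
  tgt <- as.integer(rownames(s))
  F[tgt, ] <- F[tgt, ] + s
  F
}

# per-bond harmonic energies, used by equipartition checks
ff_bond_energies <- function(ff, x) {
  if (!length(ff$b_i)) return(numeric())
  d <- x[ff$b_i, , drop = FALSE] - x[ff$b_j, , drop = FALSE]
  r <- row_norms(d)
  ff$b_k * (r - ff$b_r0)^2
}

ff_energy <- function(ff, x) {
  e_bond <- sum(ff_bond_energies(ff, x))
  e_angle <- 0
  if (length(ff$a_i)) {
    rij <- x[ff$a_i, , drop = FALSE] - x[ff$a_j, , drop = FALSE]
    rkj <- x[ff$a_k, , drop = FALSE] - x[ff$a_j, , drop = FALSE]
    nij <- row_norms(rij); nkj <- row_norms(rkj)
    ct <- pmin(1, pmax(-1, rowSums(rij * rkj) / (nij * nkj)))
    e_angle <- sum(ff$a_kt * (acos(ct) - ff$a_t0)^2)
  }
  e_rep <- 0
  if (length(ff$rep_i)) {
    d <- x[ff$rep_i, , drop = FALSE] - x[ff$rep_j, , drop = FALSE]
    r <- row_norms(d)
    close <- r < REPULSION_CUTOFF
    e_rep <- sum(REPULSION_K * (r[close] - REPULSION_CUTOFF)^2)
  }
  list(bond = e_bond, angle = e_angle, repulsion = e_rep,
       total = e_bond + e_angle + e_rep)
}

ff_forces <- function(ff, x) {
  F <- matrix(0, ff$n, 3)
  if (length(ff$b_i)) {
    d <- x[ff$b_i, , drop = FALSE] - x[ff$b_j, , drop = FALSE]
    r <- row_norms(d)
    coef <- -2 * ff$b_k * (r - ff$b_r0) / pmax(r, 1e-10)
    fb <- d * coef
    F <- scatter_add(F, ff$b_i, fb)
    F <- scatter_add(F, ff$b_j, -fb)
  }
  if (length(ff$a_i)) {
    rij <- x[ff$a_i, , drop = FALSE] - x[ff$a_j, , drop = FALSE]
    rkj <- x[ff$a_k, , drop = FALSE] - x[ff$a_j, , drop = FALSE]
    nij <- pmax(row_norms(rij), 1e-10); nkj <- pmax(row_norms(rkj), 1e-10)
    uij <- rij / nij; ukj <- rkj / nkj
    ct <- pmin(1, pmax(-1, rowSums(uij * ukj)))
    st <- pmax(sqrt(1 - ct * ct), 1e-8)
    dVdt <- 2 * ff$a_kt * (acos(ct) - ff$a_t0)
    fi <- (dVdt / (nij * st)) * (ukj - ct * uij)
    fk <- (dVdt / (nkj * st)) * (uij - ct * ukj)
    F <- scatter_add(F, ff$a_i, fi)
    F <- scatter_add(F, ff$a_k, fk)
    F <- scatter_add(F, ff$a_j, -(fi + fk))
  }
  if (length(ff$rep_i)) {
    d <- x[ff$rep_i, , drop = FALSE] - x[ff$rep_j, , drop = FALSE]
    r <- row_norms(d)
    close <- which(r < REPULSION_CUTOFF)
    if (length(close)) {
      dc <- d[close, , drop = FALSE]
      rc <- pmax(r[close], 1e-10)
      coef <- -2 * REPULSION_K * (rc - REPULSION_CUTOFF) / rc
      fr <- dc * coef
      F <- scatter_add(F, ff$rep_i[close], fr)
      F <- scatter_add(F, ff$rep_j[close], -fr)
    }
  }
  F
}

#' Steepest-descent relaxation of a coordinate frame
#'
#' The default `Relax` hook for recipes: a fixed number of steepest-descent
#' steps on the toy force field, with the per-atom displacement capped so
#' badly strained product geometries relax stably.
#'
#' @param t A [topology()] with all bonded terms parameterized.
#' @param f A [frame()].
#' @param n_steps Number of descent steps (default 200).
#' @param max_disp Per-atom displacement cap per step, A (default 0.02).
#' @return The relaxed [frame()].
#' @export
minimize_frame <- function(t, f, n_steps = 200, max_disp = 0.02) {
  ff <- ff_compile(t)
  x <- f$positions
  lr <- 1e-4
  for (s in seq_len(n_steps)) {
    F <- ff_forces(ff, x)
    if (!all(is.finite(F))) stop("minimize_frame: non-finite force at step ", s)
    disp <- F * lr
    nrm <- row_norms(disp)
    scale <- pmin(1, max_disp / pmax(nrm, 1e-12))
    x <- x + disp * scale
  }
  frame(x, time = f$time, box = f$box)
}
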