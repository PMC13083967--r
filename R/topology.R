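# Molecular topology: atoms plus bonded terms (bonds, angles, dihedrals,
# 1-4 pairs). The bond graph is the single source of truth; angles, proper
# dihedrals and pairs are derivable from it with regenerate_bonded_terms().
# Atom indices are 1-based everywhere (files and in memory).

DEFAULT_VALENCE <- c(H = 1L, C = 4L, N = 3L, O = 2L, S = 2L, P = 3L)

# covalent radii (A) used by the generic parameter assigner
COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07)

atoms_frame <- function(index = integer(), element = character(),
                        type_label = element, residue_index = 1L,
                        residue_name = "MOL", charge = 0, mass = NA_real_) {
  default_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974)
  if (all(is.na(mass)) && length(element)) {
    mass <- unname(default_mass[element])
  }
  data.frame(index = as.integer(index), element = as.character(element),
             type_label = as.character(type_label),
             residue_index = as.integer(residue_index),
             residue_name = as.character(residue_name),
             charge = as.numeric(charge), mass = as.numeric(mass),
             stringsAsFactors = FALSE)
}

bonds_frame <- function(ai = integer(), aj = integer(), r0 = NA_real_,
                        kb = NA_real_, order = 1) {
  n <- length(ai)
  d <- data.frame(ai = as.integer(ai), aj = as.integer(aj),
                  r0 = rep_len(as.numeric(r0), n),
                  kb = rep_len(as.numeric(kb), n),
                  order = rep_len(as.numeric(order), n))
  if (nrow(d)) {
    swap <- d$ai > d$aj
    tmp <- d$ai[swap]; d$ai[swap] <- d$aj[swap]; d$aj[swap] <- tmp
    d <- d[order(d$ai, d$aj), , drop = FALSE]
    rownames(d) <- NULL
  }
  d
}

angles_frame <- function(ai = integer(), aj = integer(), ak = integer(),
                         theta0 = NA_real_, ktheta = NA_real_) {
  n <- length(ai)
  d <- data.frame(ai = as.integer(ai), aj = as.integer(aj),
                  ak = as.integer(ak),
                  theta0 = rep_len(as.numeric(theta0), n),
                  ktheta = rep_len(as.numeric(ktheta), n))
  if (nrow(d)) {
    swap <- d$ai > d$ak
    tmp <- d$ai[swap]; d$ai[swap] <- d$ak[swap]; d$ak[swap] <- tmp
    d <- d[order(d$aj, d$ai, d$ak), , drop = FALSE]
    rownames(d) <- NULL
  }
  d
}

dihedrals_frame <- function(ai = integer(), aj = integer(), ak = integer(),
                            al = integer(), improper = FALSE,
                            phi0 = 0, kphi = 0, mult = 3) {
  n <- length(ai)
  d <- data.frame(ai = as.integer(ai), aj = as.integer(aj),
                  ak = as.integer(ak), al = as.integer(al),
                  improper = rep_len(as.logical(improper), n),
                  phi0 = rep_len(as.numeric(phi0), n),
                  kphi = rep_len(as.numeric(kphi), n),
                  mult = rep_len(as.integer(mult), n))
  if (nrow(d)) {
    # canonical orientation for propers: central bond with smaller index first
    swap <- !d$improper & d$aj > d$ak
    d[swap, c("ai", "aj", "ak", "al")] <- d[swap, c("al", "ak", "aj", "ai")]
    d <- d[order(d$improper, d$aj, d$ak, d$ai, d$al), , drop = FALSE]
    rownames(d) <- NULL
  }
  d
}

pairs_frame <- function(ai = integer(), aj = integer()) {
  d <- data.frame(ai = as.integer(ai), aj = as.integer(aj))
  if (nrow(d)) {
    swap <- d$ai > d$aj
    tmp <- d$ai[swap]; d$ai[swap] <- d$aj[swap]; d$aj[swap] <- tmp
    d <- d[order(d$ai, d$aj), , drop = FALSE]
    rownames(d) <- NULL
  }
  d
}

#' Construct a molecular topology
#'
#' A topology is the molecular graph a reaction emulator edits: atoms and
#' harmonic bonds, plus angles, dihedrals and 1-4 pairs consistent with the
#' bond graph. Bonds carry a formal `order` column (default 1) so that
#' radical detection by valence deficit treats, for example, carbonyl
#' carbons as saturated.
#'
#' @param atoms Data frame with columns `index`, `element`, `type_label`,
#'   `residue_index`, `residue_name`, `charge`, `mass`.
#' @param bonds Data frame with columns `ai`, `aj`, `r0` (A), `kb`
#'   (kcal mol^-1 A^-2), `order`.
#' @param angles,dihedrals,pairs Optional bonded-term tables; empty tables
#'   are valid and can be regenerated from the bonds.
#' @return An object of class `topology`.
#' @seealso [regenerate_bonded_terms()], [parse_topology()], [find_radicals()]
#' @export
topology <- function(atoms, bonds, angles = angles_frame(),
                     dihedrals = dihedrals_frame(), pairs = pairs_frame()) {
  t <- structure(list(atoms = atoms, bonds = bonds, angles = angles,
                      dihedrals = dihedrals, pairs = pairs),
                 class = "topology")
  problems <- validate_topology(t)
  if (length(problems)) {
    stop("invalid topology: ", paste(problems, collapse = "; "))
  }
  t
}

n_atoms <- function(t) nrow(t$atoms)

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d bonds, %d angles, %d dihedrals, %d pairs, %d molecule(s)\n",
              nrow(x$atoms), nrow(x$bonds), nrow(x$angles), nrow(x$dihedrals),
              nrow(x$pairs), length(unique(molecule_membership(x)))))
  invisible(x)
}

bond_graph <- function(t) {
  igraph::graph_from_data_frame(
    d = if (nrow(t$bonds)) t$bonds[, c("ai", "aj")] else data.frame(ai = integer(), aj = integer()),
    directed = FALSE,
    vertices = data.frame(name = t$atoms$index))
}

adjacency_list <- function(t) {
  n <- n_atoms(t)
  adj <- vector("list", n)
  for (r in seq_len(nrow(t$bonds))) {
    i <- t$bonds$ai[r]; j <- t$bonds$aj[r]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, function(v) sort(unique(v)))
}

#' Validate topology invariants
#'
#' Checks the structural invariants: unique contiguous atom indices,
#' supported elements, no self or duplicate bonds, every angle backed by its
#' two bonds, every proper dihedral backed by its three bonds, and every 1-4
#' pair at bond-graph distance exactly 3.
#'
#' @param t A [topology()].
#' @return Character vector of problems; empty when the topology is valid.
#' @export
validate_topology <- function(t) {
  p <- character()
  a <- t$atoms
  if (!nrow(a)) return("no atoms")
  if (anyDuplicated(a$index)) p <- c(p, "duplicate atom indices")
  if (!setequal(a$index, seq_len(nrow(a)))) {
    p <- c(p, "atom indices not contiguous 1..n")
  }
  unknown <- setdiff(unique(a$element), names(DEFAULT_VALENCE))
  if (length(unknown)) {
    p <- c(p, paste("unsupported element(s):", paste(unknown, collapse = ", ")))
  }
  b <- t$bonds
  if (nrow(b)) {
    if (any(b$ai == b$aj)) p <- c(p, "self-bond")
    if (anyDuplicated(b[, c("ai", "aj")])) p <- c(p, "duplicate bond")
    if (any(!(c(b$ai, b$aj) %in% a$index))) p <- c(p, "bond references unknown atom")
  }
  has_bond <- function(i, j) {
    key <- paste(pmin(i, j), pmax(i, j))
    key %in% paste(b$ai, b$aj)
  }
  if (nrow(t$angles)) {
    ok <- has_bond(t$angles$ai, t$angles$aj) & has_bond(t$angles$aj, t$angles$ak)
    if (!all(ok)) p <- c(p, "angle not backed by bonds")
  }
  dpr <- t$dihedrals[!t$dihedrals$improper, , drop = FALSE]
  if (nrow(dpr)) {
    ok <- has_bond(dpr$ai, dpr$aj) & has_bond(dpr$aj, dpr$ak) & has_bond(dpr$ak, dpr$al)
    if (!all(ok)) p <- c(p, "proper dihedral not backed by bonds")
  }
  if (nrow(t$pairs)) {
    dm <- igraph::distances(bond_graph(t))
    ord <- match(as.character(a$index), rownames(dm))
    dm <- dm[ord, ord]
    dd <- dm[cbind(t$pairs$ai, t$pairs$aj)]
    if (any(dd != 3)) p <- c(p, "1-4 pair not at graph distance 3")
  }
  p
}

#' Bond-graph distance between two atoms
#'
#' @param t A [topology()].
#' @param a,b Atom indices.
#' @return Minimal number of bonds on a path from `a` to `b`; `Inf` when the
#'   atoms are in different molecules; 0 when `a == b`.
#' @export
graph_distance <- function(t, a, b) {
  if (!all(c(a, b) %in% t$atoms$index)) {
    stop("graph_distance: atom index out of range")
  }
  if (a == b) return(0)
  d <- igraph::distances(bond_graph(t), v = as.character(a), to = as.character(b))
  as.numeric(d[1, 1])
}

#' Partition atoms into molecules
#'
#' @param t A [topology()].
#' @return Integer vector, one molecule id per atom, equal to the connected
#'   components of the bond graph.
#' @export
molecule_membership <- function(t) {
  comp <- igraph::components(bond_graph(t))
  m <- comp$membership
  as.integer(m[as.character(t$atoms$index)])
}

#' Detect radical atoms by valence deficit
#'
#' An atom is a radical iff the sum of its bond orders falls short of the
#' nominal valence of its element (H 1, C 4, N 3, O 2, S 2, P 3 by default).
#' The unpaired-electron count is the deficit. Deliberately recomputable
#' from the topology alone, so it stays consistent under arbitrary recipe
#' edits.
#'
#' @param t A [topology()].
#' @param valence Named integer vector mapping element symbols to valences.
#' @return Data frame with columns `atom` and `unpaired` (both integer);
#'   zero rows when the molecule is fully saturated.
#' @export
find_radicals <- function(t, valence = DEFAULT_VALENCE) {
  unknown <- setdiff(unique(t$atoms$element), names(valence))
  if (length(unknown)) {
    stop("find_radicals: element(s) not in valence table: ",
         paste(unknown, collapse = ", "))
  }
  deg <- numeric(n_atoms(t))
  if (nrow(t$bonds)) {
    for (col in c("ai", "aj")) {
      tab <- tapply(t$bonds$order, t$bonds[[col]], sum)
      deg[as.integer(names(tab))] <- deg[as.integer(names(tab))] + tab
    }
  }
  deficit <- as.integer(round(valence[t$atoms$element] - deg))
  keep <- deficit >= 1L
  data.frame(atom = t$atoms$index[keep], unpaired = deficit[keep])
}

term_key <- function(...) do.call(paste, c(list(...), sep = "_"))

#' Regenerate angles, proper dihedrals and 1-4 pairs from the bond graph
#'
#' After a reaction edits the bonds, the dependent bonded terms are rebuilt:
#' angles are all length-2 simple bond paths, proper dihedrals all length-3
#' simple bond paths, and 1-4 pairs all atom pairs at bond-graph distance
#' exactly 3. Parameters of terms that survive the edit are preserved; new
#' terms receive generic parameters from [assign_generic_parameters()].
#' Improper dihedrals are carried through (when their atoms survive) but
#' never auto-generated. The operation is idempotent.
#'
#' @param t A [topology()].
#' @return A new `topology` with consistent bonded terms.
#' @export
regenerate_bonded_terms <- function(t) {
  adj <- adjacency_list(t)
  n <- n_atoms(t)

  # angles: center j, neighbors i < k
  ai <- integer(); aj <- integer(); ak <- integer()
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(nb, 2)
      ai <- c(ai, cmb[1, ]); aj <- c(aj, rep(j, ncol(cmb))); ak <- c(ak, cmb[2, ])
    }
  }
  new_angles <- angles_frame(ai, aj, ak)
  if (nrow(t$angles)) {
    old_key <- term_key(t$angles$ai, t$angles$aj, t$angles$ak)
    new_key <- term_key(new_angles$ai, new_angles$aj, new_angles$ak)
    m <- match(new_key, old_key)
    hit <- !is.na(m)
    new_angles$theta0[hit] <- t$angles$theta0[m[hit]]
    new_angles$ktheta[hit] <- t$angles$ktheta[m[hit]]
  }

  # proper dihedrals: one per (i, j, k, l) with central bond (j, k)
  di <- integer(); dj <- integer(); dk <- integer(); dl <- integer()
  for (r in seq_len(nrow(t$bonds))) {
    j <- t$bonds$ai[r]; k <- t$bonds$aj[r]
    for (i in setdiff(adj[[j]], k)) {
      for (l in setdiff(adj[[k]], j)) {
        if (i != l) {
          di <- c(di, i); dj <- c(dj, j); dk <- c(dk, k); dl <- c(dl, l)
        }
      }
    }
  }
  new_prop <- dihedrals_frame(di, dj, dk, dl, improper = FALSE,
                              phi0 = NA_real_, kphi = NA_real_, mult = NA_integer_)
  old_prop <- t$dihedrals[!t$dihedrals$improper, , drop = FALSE]
  if (nrow(old_prop) && nrow(new_prop)) {
    okey1 <- term_key(old_prop$ai, old_prop$aj, old_prop$ak, old_prop$al)
    okey2 <- term_key(old_prop$al, old_prop$ak, old_prop$aj, old_prop$ai)
    nkey <- term_key(new_prop$ai, new_prop$aj, new_prop$ak, new_prop$al)
    m <- match(nkey, okey1)
    m2 <- match(nkey, okey2)
    m[is.na(m)] <- m2[is.na(m)]
    hit <- !is.na(m)
    new_prop$phi0[hit] <- old_prop$phi0[m[hit]]
    new_prop$kphi[hit] <- old_prop$kphi[m[hit]]
    new_prop$mult[hit] <- old_prop$mult[m[hit]]
  }
  old_impr <- t$dihedrals[t$dihedrals$improper, , drop = FALSE]
  if (nrow(old_impr)) {
    keep <- old_impr$ai <= n & old_impr$aj <= n & old_impr$ak <= n & old_impr$al <= n
    old_impr <- old_impr[keep, , drop = FALSE]
  }
  new_dih <- rbind(new_prop, old_impr)
  rownames(new_dih) <- NULL

  # 1-4 pairs: graph distance exactly 3
  pi_ <- integer(); pj_ <- integer()
  if (nrow(t$bonds)) {
    g <- bond_graph(t)
    dm <- igraph::distances(g)
    ord <- match(as.character(t$atoms$index), rownames(dm))
    dm <- dm[ord, ord]
    idx <- which(dm == 3 & upper.tri(dm), arr.ind = TRUE)
    pi_ <- t$atoms$index[idx[, 1]]
    pj_ <- t$atoms$index[idx[, 2]]
  }
  new_pairs <- pairs_frame(pi_, pj_)

  out <- structure(list(atoms = t$atoms, bonds = t$bonds, angles = new_angles,
                        dihedrals = new_dih, pairs = new_pairs),
                   class = "topology")
  assign_generic_parameters(out)
}

#' Fill in missing force-field parameters with generic defaults
#'
#' A deliberately simple parameter assigner: bond reference lengths from
#' covalent-radius sums, bond stiffness 340 kcal mol^-1 A^-2 when hydrogen
#' is involved and 300 otherwise, tetrahedral reference angles (109.5 deg,
#' 40 kcal mol^-1 rad^-2) and zero-height torsions. Existing (non-missing)
#' parameters are never overwritten.
#'
#' @param t A [topology()].
#' @return The topology with all `NA` bonded parameters replaced.
#' @export
assign_generic_parameters <- function(t) {
  b <- t$bonds
  if (nrow(b)) {
    el_i <- t$atoms$element[b$ai]; el_j <- t$atoms$element[b$aj]
    miss <- is.na(b$r0)
    b$r0[miss] <- COVALENT_RADII[el_i[miss]] + COVALENT_RADII[el_j[miss]]
    miss <- is.na(b$kb)
    b$kb[miss] <- ifelse(el_i[miss] == "H" | el_j[miss] == "H", 340, 300)
    b$order[is.na(b$order)] <- 1
  }
  a <- t$angles
  if (nrow(a)) {
    a$theta0[is.na(a$theta0)] <- 109.5
    a$ktheta[is.na(a$ktheta)] <- 40
  }
  d <- t$dihedrals
  if (nrow(d)) {
    d$phi0[is.na(d$phi0)] <- 0
    d$kphi[is.na(d$kphi)] <- 0
    d$mult[is.na(d$mult)] <- 3L
  }
  t$bonds <- b; t$angles <- a; t$dihedrals <- d
  t
}

#' Short deterministic digest of a topology
#'
#' Used in run records to fingerprint the product state of each cycle.
#' A simple polynomial hash over the canonical bond list and element string;
#' stable across sessions and platforms.
#'
#' @param t A [topology()].
#' @return A character scalar like `"25a:24b:c3f2a1"`.
#' @export
topology_digest <- function(t) {
  s <- paste(c(t$atoms$element, t$bonds$ai, t$bonds$aj, round(t$bonds$order, 3)),
             collapse = ",")
  codes <- utf8ToInt(s)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  sprintf("%da:%db:%x", nrow(t$atoms), nrow(t$bonds), as.integer(h))
}
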