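test_that("parsing reads atoms and bonds and leaves missing sections empty", {
  t <- parse_topology(methane_text())
  expect_equal(nrow(t$atoms), 5)
  expect_equal(nrow(t$bonds), 4)
  expect_equal(nrow(t$angles), 0)
  expect_equal(nrow(t$pairs), 0)

  t2 <- regenerate_bonded_terms(t)
  expect_equal(nrow(t2$angles), 6)
  expect_equal(nrow(t2$dihedrals), 0)
  expect_equal(nrow(t2$pairs), 0)
})

test_that("parse errors carry line numbers and reference checks", {
  bad <- methane_text()
  bad[3] <- "2 H HC 1 MET zero 1.008"
  expect_error(parse_topology(bad), "line 3")
  bad2 <- c(methane_text(), "1 9 1.09 340 1")
  expect_error(parse_topology(bad2), "unknown atom")
  expect_error(parse_topology(c("[atoms]", "1 C CT 1 M 0 12", "[bonds]", "1 1")),
               "self-bond")
})

test_that("write/parse round trip is lossless", {
  fx <- build_alkyl_radical(5, 2)
  t <- fx$topology
  t2 <- parse_topology(write_topology(t))
  expect_equal(t2$atoms, t$atoms)
  expect_equal(t2$bonds, t$bonds, tolerance = 1e-6)
  expect_equal(t2$angles, t$angles, tolerance = 1e-6)
  expect_equal(t2$dihedrals, t$dihedrals, tolerance = 1e-6)
  expect_equal(t2$pairs, t$pairs)

  path <- withr::local_tempfile(fileext = ".top")
  write_topology(t, path)
  expect_equal(write_topology(read_topology(path)), write_topology(t))
})

test_that("ethane regeneration gives the exhaustive path counts", {
  t <- regenerate_bonded_terms(parse_topology(ethane_text()))
  expect_equal(nrow(t$angles), 12)
  expect_equal(nrow(t$dihedrals), 9)
  expect_equal(nrow(t$pairs), 9)
  expect_length(validate_topology(t), 0)
})

test_that("regeneration is idempotent and preserves surviving parameters", {
  t <- regenerate_bonded_terms(parse_topology(ethane_text()))
  t$angles$theta0[1] <- 112.3  # user-set parameter must survive
  t2 <- regenerate_bonded_terms(t)
  expect_equal(t2$angles, regenerate_bonded_terms(t2)$angles)
  expect_equal(t2$angles$theta0[1], 112.3)
  expect_equal(nrow(t2$angles), nrow(t$angles))

  empty <- topology(kmcreact:::atoms_frame(1:2, c("C", "C")),
                    kmcreact:::bonds_frame())
  r <- regenerate_bonded_terms(empty)
  expect_equal(nrow(r$angles) + nrow(r$dihedrals) + nrow(r$pairs), 0)
})

test_that("regenerated term counts match exhaustive enumeration on random molecules", {
  for (seed in 1:5) {
    n <- 5 + (seed %% 5)
    t <- random_molecule(n, extra = 2, seed = seed)
    t2 <- regenerate_bonded_terms(t)
    o <- oracle_term_counts(n, t$bonds)
    expect_equal(nrow(t2$angles), o$angles, info = paste("seed", seed))
    expect_equal(nrow(t2$dihedrals[!t2$dihedrals$improper, ]), o$dihedrals,
                 info = paste("seed", seed))
    expect_equal(nrow(t2$pairs), o$pairs, info = paste("seed", seed))
  }
})

test_that("graph distance matches BFS and flags other molecules", {
  fx <- build_alkyl_radical(8, 1)
  expect_equal(graph_distance(fx$topology, 3, 3), 0)
  expect_equal(graph_distance(fx$topology, 1, 5), 4)
  d <- oracle_distances(25, fx$topology$bonds)
  for (pair in list(c(1, 8), c(2, 25), c(9, 10))) {
    expect_equal(graph_distance(fx$topology, pair[1], pair[2]),
                 d[pair[1], pair[2]])
  }
  w <- build_dipeptide_water()
  expect_equal(graph_distance(w$topology, 1, w$water_o), Inf)
})

test_that("radicals are the valence-deficit atoms", {
  oct <- build_alkane(8)
  expect_equal(nrow(find_radicals(oct$topology)), 0)
  fx <- build_alkyl_radical(8, 3)
  rad <- find_radicals(fx$topology)
  expect_equal(rad$atom, 3)
  expect_equal(rad$unpaired, 1)

  # hydroxyl O bonded only to C (after H abstraction) is a radical
  at <- kmcreact:::atoms_frame(1:5, c("C", "O", "H", "H", "H"))
  t <- topology(at, kmcreact:::bonds_frame(c(1, 1, 1, 1), c(2, 3, 4, 5)))
  expect_equal(find_radicals(t)$atom, 2)

  at2 <- kmcreact:::atoms_frame(1:2, c("C", "S"))
  t2 <- topology(at2, kmcreact:::bonds_frame(1, 2))
  expect_error(find_radicals(t2, valence = c(C = 4)), "valence table")
})

test_that("radical detection is equivariant under atom reindexing", {
  fx <- build_alkyl_radical(6, 2)
  t <- fx$topology
  set.seed(42)
  perm <- sample(n <- nrow(t$atoms))  # perm[old] = new index
  at <- t$atoms
  at$index <- perm[at$index]
  at <- at[order(at$index), ]
  b <- t$bonds
  t2 <- topology(at, kmcreact:::bonds_frame(perm[b$ai], perm[b$aj],
                                            b$r0, b$kb, b$order))
  expect_setequal(find_radicals(t2)$atom, perm[find_radicals(t)$atom])
})

test_that("bonds with double-bond order count toward valence", {
  w <- build_dipeptide_water()
  expect_equal(nrow(find_radicals(w$topology)), 0)
  expect_length(validate_topology(w$topology), 0)
  expect_equal(length(unique(molecule_membership(w$topology))), 2)
})
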