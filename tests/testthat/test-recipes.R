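test_that("recipe validation reports violations as data", {
  e <- build_alkane(2)
  t <- e$topology
  expect_length(validate_recipe(t, recipe(list(step_break(1, 3)))), 0)
  expect_length(validate_recipe(t, recipe(list(step_bind(1, 2)))), 1)
  expect_length(validate_recipe(t, recipe(list(step_break(3, 4)))), 1)
  # edits earlier in the recipe count for later steps
  expect_length(validate_recipe(t, recipe(list(step_break(1, 2),
                                               step_bind(1, 2)))), 0)
  expect_error(apply_recipe(t, e$frame, recipe(list(step_break(3, 4)))),
               "no such bond")
})

test_that("ethane homolysis regenerates all dependent terms", {
  e <- build_alkane(2)
  pr <- apply_recipe(e$topology, e$frame, make_homolysis_recipe(e$topology, 1, 2))
  expect_equal(nrow(pr$topology$bonds), 6)
  expect_equal(nrow(pr$topology$angles), 6)
  expect_equal(nrow(pr$topology$dihedrals), 0)
  expect_equal(nrow(pr$topology$pairs), 0)
  expect_equal(sort(find_radicals(pr$topology)$atom), c(1, 2))
  expect_length(validate_topology(pr$topology), 0)
})

test_that("hydrogen atom transfer moves the radical and conserves bonds", {
  fx <- build_alkyl_radical(3, 1)
  t <- fx$topology
  h <- hydrogens_on(t, 3)[1]
  rec <- make_hat_recipe(t, h, 1, fx$frame)
  expect_equal(rec$steps[[1]]$kind, "Break")
  expect_equal(rec$steps[[4]]$kind, "Relax")
  pr <- apply_recipe(t, fx$frame, rec)
  expect_equal(nrow(pr$topology$bonds), nrow(t$bonds))
  expect_equal(find_radicals(pr$topology)$atom, 3)
  expect_length(validate_topology(pr$topology), 0)
  # placed hydrogen sits 1.1 A from the acceptor before relaxation
  pr0 <- apply_recipe(t, fx$frame, recipe(rec$steps[1:3], "hat"))
  expect_equal(sqrt(sum((pr0$frame$positions[h, ] -
                         pr0$frame$positions[1, ])^2)), 1.1, tolerance = 1e-8)
})

test_that("degenerate and role-mismatched constructions error", {
  fx <- build_alkyl_radical(3, 1)
  t <- fx$topology
  h_on_radical <- hydrogens_on(t, 1)[1]
  expect_error(make_hat_recipe(t, h_on_radical, 1, fx$frame), "already bonded")
  expect_error(make_hat_recipe(t, 2, 1, fx$frame), "not hydrogen")
  expect_error(make_hat_recipe(t, hydrogens_on(t, 3)[1], 2, fx$frame),
               "not a radical")
  w <- build_dipeptide_water()
  expect_error(make_hydrolysis_recipe(w$topology, w$peptide_n, w$peptide_c,
                                      w$water_o, w$water_h), "carbon and a nitrogen")
})

test_that("intermolecular transfer keeps the molecule count", {
  # propyl radical plus separate methane: H jumps between molecules
  fx <- build_alkyl_radical(3, 1)
  me <- regenerate_bonded_terms(parse_topology(methane_text()))
  n1 <- nrow(fx$topology$atoms)
  at <- rbind(fx$topology$atoms,
              transform(me$atoms, index = index + n1, residue_index = 2L))
  b2 <- me$bonds
  comb <- topology(at, kmcreact:::bonds_frame(
    c(fx$topology$bonds$ai, b2$ai + n1), c(fx$topology$bonds$aj, b2$aj + n1),
    c(fx$topology$bonds$r0, b2$r0), c(fx$topology$bonds$kb, b2$kb)))
  comb <- regenerate_bonded_terms(comb)
  me_xyz <- rbind(c(0, 0, 0), c(1.09, 0, 0), c(-0.36, 1.03, 0),
                  c(-0.36, -0.51, 0.89), c(-0.36, -0.51, -0.89))
  f <- frame(rbind(fx$frame$positions,
                   sweep(me_xyz, 2, c(8, 0, 0), `+`)))
  h <- hydrogens_on(comb, n1 + 1)[1]
  rec <- make_hat_recipe(comb, h, 1, f)
  pr <- apply_recipe(comb, f, rec)
  expect_equal(length(unique(molecule_membership(pr$topology))), 2)
  expect_equal(find_radicals(pr$topology)$atom, n1 + 1)
})

test_that("hydrolysis and homolysis of the same peptide bond differ in radicals", {
  w <- build_dipeptide_water()
  hyd <- apply_recipe(w$topology, w$frame,
                      make_hydrolysis_recipe(w$topology, w$peptide_c,
                                             w$peptide_n, w$water_o, w$water_h))
  expect_equal(length(unique(molecule_membership(hyd$topology))), 2)
  expect_equal(nrow(find_radicals(hyd$topology)), 0)
  expect_equal(nrow(hyd$topology$bonds), nrow(w$topology$bonds))

  hom <- apply_recipe(w$topology, w$frame,
                      make_homolysis_recipe(w$topology, w$peptide_c, w$peptide_n))
  expect_equal(length(unique(molecule_membership(hom$topology))), 3)
  expect_equal(sort(find_radicals(hom$topology)$atom),
               c(w$peptide_c, w$peptide_n))
})

test_that("dimerization closes exactly one new four-membered ring", {
  y <- build_pyrimidine_pair()
  pr <- apply_recipe(y$topology, y$frame,
                     make_dimerization_recipe(y$topology, y$c5a, y$c6a,
                                              y$c5b, y$c6b))
  expect_equal(nrow(pr$topology$bonds), nrow(y$topology$bonds) + 2)
  expect_equal(length(unique(molecule_membership(pr$topology))), 1)
  g <- igraph::graph_from_data_frame(pr$topology$bonds[, 1:2], directed = FALSE)
  expect_equal(igraph::girth(g)$girth, 4)
  expect_length(validate_topology(pr$topology), 0)
})

test_that("recipes conserve atoms and reverse edits restore the bond set", {
  fixtures <- list(
    list(fx = build_alkane(2), rec = function(fx) make_homolysis_recipe(fx$topology, 1, 2)),
    list(fx = build_dipeptide_water(),
         rec = function(fx) make_hydrolysis_recipe(fx$topology, fx$peptide_c,
                                                   fx$peptide_n, fx$water_o, fx$water_h)),
    list(fx = build_pyrimidine_pair(),
         rec = function(fx) make_dimerization_recipe(fx$topology, fx$c5a,
                                                     fx$c6a, fx$c5b, fx$c6b)))
  for (case in fixtures) {
    r <- case$rec(case$fx)
    pr <- apply_recipe(case$fx$topology, case$fx$frame, r)
    expect_equal(nrow(pr$topology$atoms), nrow(case$fx$topology$atoms))
    back <- apply_recipe(pr$topology, pr$frame, reverse_recipe(r))
    expect_equal(back$topology$bonds$ai, case$fx$topology$bonds$ai)
    expect_equal(back$topology$bonds$aj, case$fx$topology$bonds$aj)
  }
})

test_that("relax-only recipes leave the topology untouched and reduce strain", {
  fx <- build_alkyl_radical(4, 1)
  stretched <- fx$frame
  stretched$positions[2, ] <- stretched$positions[2, ] + c(0.3, 0, 0)
  pr <- apply_recipe(fx$topology, stretched, recipe(list(step_relax())))
  expect_equal(pr$topology$bonds, fx$topology$bonds)
  ff <- kmcreact:::ff_compile(fx$topology)
  expect_lt(kmcreact:::ff_energy(ff, pr$frame$positions)$total,
            kmcreact:::ff_energy(ff, stretched$positions)$total)
})

test_that("recipes serialize to lines and back", {
  fx <- build_alkyl_radical(3, 1)
  rec <- make_hat_recipe(fx$topology, hydrogens_on(fx$topology, 3)[1], 1, fx$frame)
  lines <- recipe_to_lines(rec)
  rec2 <- recipe_from_lines(lines, reaction_type = "hat")
  expect_equal(recipe_to_lines(rec2), lines)
  expect_equal(length(rec2$steps), 4)
})
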