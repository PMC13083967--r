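# Reactions as ordered elementary steps (Break, Bind, Place, Relax) applied
# to a topology plus a coordinate frame. Break/Bind edit the bond list,
# Place overwrites one atom's coordinates, Relax invokes a registered
# relaxation hook (default: steepest descent on the toy force field). After
# all bond edits, angles/dihedrals/pairs are regenerated once.

#' Elementary recipe steps
#'
#' @param i,j Atom indices (distinct) for `Break`/`Bind`.
#' @param atom Atom index for `Place`.
#' @param position Length-3 target position (A) for `Place`.
#' @return A `recipe_step` list with a `kind` field.
#' @name recipe_steps
NULL

#' @rdname recipe_steps
#' @export
step_break <- function(i, j) {
  stopifnot(i != j)
  structure(list(kind = "Break", i = as.integer(i), j = as.integer(j)),
            class = "recipe_step")
}

#' @rdname recipe_steps
#' @export
step_bind <- function(i, j) {
  stopifnot(i != j)
  structure(list(kind = "Bind", i = as.integer(i), j = as.integer(j)),
            class = "recipe_step")
}

#' @rdname recipe_steps
#' @export
step_place <- function(atom, position) {
  stopifnot(length(position) == 3, all(is.finite(position)))
  structure(list(kind = "Place", atom = as.integer(atom),
                 position = as.numeric(position)), class = "recipe_step")
}

#' @rdname recipe_steps
#' @export
step_relax <- function() {
  structure(list(kind = "Relax"), class = "recipe_step")
}

#' Construct a reaction recipe
#'
#' @param steps Non-empty list of recipe steps.
#' @param reaction_type Tag such as `"hat"`, `"homolysis"`, `"hydrolysis"`,
#'   `"dimerization"`.
#' @param provenance Named list recording where the rate came from (frame
#'   index, feature values, shift label, ...).
#' @return An object of class `recipe`.
#' @export
recipe <- function(steps, reaction_type = "generic", provenance = list()) {
  stopifnot(length(steps) >= 1,
            all(vapply(steps, inherits, logical(1), "recipe_step")))
  structure(list(steps = steps, reaction_type = reaction_type,
                 provenance = provenance), class = "recipe")
}

#' @export
print.recipe <- function(x, ...) {
  cat(sprintf("recipe <%s>: %s\n", x$reaction_type,
              paste(recipe_to_lines(x), collapse = "; ")))
  invisible(x)
}

#' Serialize / deserialize a recipe as text lines
#'
#' One step per line (`Break i j`, `Bind i j`, `Place atom x y z`,
#' `Relax`), for logging and replay.
#'
#' @param r A [recipe()].
#' @param lines Character vector as produced by `recipe_to_lines`.
#' @param reaction_type Tag for the deserialized recipe.
#' @return `recipe_to_lines`: character vector; `recipe_from_lines`: a
#'   [recipe()].
#' @export
recipe_to_lines <- function(r) {
  vapply(r$steps, function(s) {
    switch(s$kind,
           Break = sprintf("Break %d %d", s$i, s$j),
           Bind = sprintf("Bind %d %d", s$i, s$j),
           Place = sprintf("Place %d %.6f %.6f %.6f", s$atom,
                           s$position[1], s$position[2], s$position[3]),
           Relax = "Relax")
  }, character(1))
}

#' @rdname recipe_to_lines
#' @export
recipe_from_lines <- function(lines, reaction_type = "generic") {
  steps <- lapply(lines, function(s) {
    f <- strsplit(trimws(s), "\\s+")[[1]]
    switch(f[1],
           Break = step_break(as.integer(f[2]), as.integer(f[3])),
           Bind = step_bind(as.integer(f[2]), as.integer(f[3])),
           Place = step_place(as.integer(f[2]), as.numeric(f[3:5])),
           Relax = step_relax(),
           stop("recipe_from_lines: unknown step kind '", f[1], "'"))
  })
  recipe(steps, reaction_type = reaction_type)
}

has_bond <- function(t, i, j) {
  any(t$bonds$ai == min(i, j) & t$bonds$aj == max(i, j))
}

#' Validate a recipe against a topology
#'
#' Violations are returned as data, not raised: every `Break` must target
#' an existing bond, every `Bind` a non-existing bond between existing
#' atoms, every `Place` an existing atom. Bond edits earlier in the recipe
#' are taken into account when validating later steps.
#'
#' @param t A [topology()].
#' @param r A [recipe()].
#' @return Character vector of violations; empty if the recipe applies.
#' @export
validate_recipe <- function(t, r) {
  v <- character()
  idx <- t$atoms$index
  bonds <- t$bonds[, c("ai", "aj")]
  key <- function(i, j) paste(min(i, j), max(i, j))
  keys <- paste(bonds$ai, bonds$aj)
  for (s in r$steps) {
    if (s$kind %in% c("Break", "Bind")) {
      if (!all(c(s$i, s$j) %in% idx)) {
        v <- c(v, sprintf("%s %d-%d: unknown atom", s$kind, s$i, s$j))
        next
      }
      k <- key(s$i, s$j)
      if (s$kind == "Break") {
        if (!k %in% keys) {
          v <- c(v, sprintf("Break %d-%d: no such bond", s$i, s$j))
        } else keys <- setdiff(keys, k)
      } else {
        if (k %in% keys) {
          v <- c(v, sprintf("Bind %d-%d: bond already exists", s$i, s$j))
        } else keys <- c(keys, k)
      }
    } else if (s$kind == "Place") {
      if (!s$atom %in% idx) v <- c(v, sprintf("Place %d: unknown atom", s$atom))
    }
  }
  v
}

default_relax_hook <- function(t, f) minimize_frame(t, f)

#' Apply a recipe to a topology and coordinate frame
#'
#' Bond edits are applied in step order; bonded terms (angles, proper
#' dihedrals, 1-4 pairs) are regenerated once after the last `Break`/`Bind`.
#' `Place` overwrites the atom's coordinates; `Relax` calls `relax_hook`
#' on the current product state. Atoms are never created or deleted.
#'
#' @param t A [topology()].
#' @param f A [frame()].
#' @param r A [recipe()]; must validate cleanly.
#' @param relax_hook Function `(topology, frame) -> frame`; defaults to
#'   [minimize_frame()].
#' @return List with elements `topology` and `frame` for the product state.
#' @export
apply_recipe <- function(t, f, r, relax_hook = default_relax_hook) {
  v <- validate_recipe(t, r)
  if (length(v)) stop("apply_recipe: ", v[1])
  b <- t$bonds
  x <- f$positions
  edited <- FALSE
  regenerated <- FALSE
  t2 <- t
  regen <- function() {
    if (edited && !regenerated) {
      t2$bonds <<- b
      t2 <<- regenerate_bonded_terms(t2)
      b <<- t2$bonds
      regenerated <<- TRUE
    }
  }
  for (s in r$steps) {
    if (s$kind == "Break") {
      b <- b[!(b$ai == min(s$i, s$j) & b$aj == max(s$i, s$j)), , drop = FALSE]
      edited <- TRUE; regenerated <- FALSE
    } else if (s$kind == "Bind") {
      b <- rbind(b, data.frame(ai = min(s$i, s$j), aj = max(s$i, s$j),
                               r0 = NA_real_, kb = NA_real_, order = 1))
      b <- bonds_frame(b$ai, b$aj, b$r0, b$kb, b$order)
      edited <- TRUE; regenerated <- FALSE
    } else if (s$kind == "Place") {
      regen()
      x[s$atom, ] <- s$position
    } else if (s$kind == "Relax") {
      regen()
      fr <- relax_hook(t2, frame(x, time = f$time, box = f$box))
      x <- fr$positions
    }
  }
  regen()
  list(topology = t2, frame = frame(x, time = f$time, box = f$box))
}

#' Build a hydrogen atom transfer recipe
#'
#' Breaks the donor-hydrogen bond, binds the hydrogen to the radical
#' acceptor, places the hydrogen 1.1 A from the acceptor along the
#' donor-to-acceptor direction in the provenance frame, then relaxes.
#'
#' @param t A [topology()].
#' @param h Index of the transferring hydrogen (must be H with exactly one
#'   heavy-atom bond).
#' @param acceptor Index of the radical acceptor atom.
#' @param f The [frame()] the placement geometry is taken from.
#' @param frame_index Frame index recorded in the recipe provenance.
#' @return A [recipe()] with `reaction_type = "hat"`.
#' @export
make_hat_recipe <- function(t, h, acceptor, f, frame_index = NA_integer_) {
  if (t$atoms$element[h] != "H") stop("make_hat_recipe: atom ", h, " is not hydrogen")
  rad <- find_radicals(t)
  if (!acceptor %in% rad$atom) stop("make_hat_recipe: atom ", acceptor, " is not a radical")
  nb <- c(t$bonds$aj[t$bonds$ai == h], t$bonds$ai[t$bonds$aj == h])
  if (length(nb) != 1) stop("make_hat_recipe: hydrogen must have exactly one bond")
  donor <- nb[1]
  if (donor == acceptor) stop("make_hat_recipe: hydrogen already bonded to the acceptor")
  dvec <- f$positions[acceptor, ] - f$positions[donor, ]
  u <- if (sqrt(sum(dvec^2)) < 1e-9) c(1, 0, 0) else unit3(dvec)
  target <- f$positions[acceptor, ] - 1.1 * u  # 1.1 A on the donor side
  recipe(list(step_break(h, donor), step_bind(h, acceptor),
              step_place(h, target), step_relax()),
         reaction_type = "hat",
         provenance = list(h = h, donor = donor, acceptor = acceptor,
                           frame_index = frame_index))
}

#' Build a homolysis recipe
#'
#' Breaks one bond, producing two radical fragments, then relaxes.
#'
#' @param t A [topology()].
#' @param i,j Atoms of the bond to cleave.
#' @return A [recipe()] with `reaction_type = "homolysis"`.
#' @export
make_homolysis_recipe <- function(t, i, j) {
  if (!has_bond(t, i, j)) stop("make_homolysis_recipe: no bond ", i, "-", j)
  recipe(list(step_break(i, j), step_relax()), reaction_type = "homolysis",
         provenance = list(i = i, j = j))
}

#' Build a peptide hydrolysis recipe
#'
#' Base-catalysed peptide-bond scission with an explicit water as atom
#' donor: the C-N amide bond and one water O-H bond break, the water oxygen
#' caps the carbonyl carbon and the water hydrogen caps the amide nitrogen.
#' Atom count is conserved and the product is closed-shell.
#'
#' @param t A [topology()].
#' @param c Carbonyl carbon index.
#' @param n Amide nitrogen index (bonded to `c`).
#' @param water_o,water_h Water oxygen and one of its hydrogens.
#' @return A [recipe()] with `reaction_type = "hydrolysis"`.
#' @export
make_hydrolysis_recipe <- function(t, c, n, water_o, water_h) {
  if (t$atoms$element[c] != "C" || t$atoms$element[n] != "N") {
    stop("make_hydrolysis_recipe: c/n must be a carbon and a nitrogen")
  }
  if (t$atoms$element[water_o] != "O" || t$atoms$element[water_h] != "H") {
    stop("make_hydrolysis_recipe: water_o/water_h must be O and H")
  }
  if (!has_bond(t, c, n)) stop("make_hydrolysis_recipe: no C-N bond ", c, "-", n)
  if (!has_bond(t, water_o, water_h)) {
    stop("make_hydrolysis_recipe: water_h not bonded to water_o")
  }
  recipe(list(step_break(c, n), step_break(water_o, water_h),
              step_bind(water_o, c), step_bind(water_h, n), step_relax()),
         reaction_type = "hydrolysis",
         provenance = list(c = c, n = n, water_o = water_o, water_h = water_h))
}

#' Build a photodimerization recipe
#'
#' Closes the cyclobutane ring across two stacked double bonds by binding
#' C5a-C5b and C6a-C6b, then relaxes.
#'
#' @param t A [topology()].
#' @param c5a,c6a Ring atoms of the first double bond (must be bonded).
#' @param c5b,c6b Ring atoms of the second double bond (must be bonded).
#' @return A [recipe()] with `reaction_type = "dimerization"`.
#' @export
make_dimerization_recipe <- function(t, c5a, c6a, c5b, c6b) {
  if (!has_bond(t, c5a, c6a) || !has_bond(t, c5b, c6b)) {
    stop("make_dimerization_recipe: C5-C6 atoms must be bonded pairs")
  }
  if (has_bond(t, c5a, c5b) || has_bond(t, c6a, c6b)) {
    stop("make_dimerization_recipe: dimer bonds already present")
  }
  recipe(list(step_bind(c5a, c5b), step_bind(c6a, c6b), step_relax()),
         reaction_type = "dimerization",
         provenance = list(c5a = c5a, c6a = c6a, c5b = c5b, c6b = c6b))
}

#' Reverse a recipe's bond edits
#'
#' Swaps `Break` and `Bind` (in reverse order), dropping `Place`/`Relax`.
#' Applying a recipe and then its reverse restores the original bond set.
#'
#' @param r A [recipe()].
#' @return A [recipe()].
#' @export
reverse_recipe <- function(r) {
  steps <- rev(lapply(Filter(function(s) s$kind %in% c("Break", "Bind"), r$steps),
                      function(s) {
                        if (s$kind == "Break") step_bind(s$i, s$j) else step_break(s$i, s$j)
                      }))
  if (!length(steps)) steps <- list(step_relax())
  recipe(steps, reaction_type = paste0("reverse_", r$reaction_type))
}
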