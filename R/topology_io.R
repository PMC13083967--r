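# Section-based text dialect for topologies, mirroring the section names of
# GROMACS topology files: [atoms], [bonds], [angles], [dihedrals], [pairs].
# ';' starts a comment. Atom indices on disk are 1-based, same as in memory.
# Numeric parameters are written with 6 significant digits, which the
# round-trip contract guarantees.

#' Parse a topology from its text form
#'
#' @param text Either a single string containing the whole file (with
#'   newlines) or a character vector of lines.
#' @return A [topology()]. Missing `[angles]`/`[dihedrals]`/`[pairs]`
#'   sections yield empty tables, which [regenerate_bonded_terms()] can
#'   rebuild.
#' @seealso [write_topology()], [read_topology()]
#' @export
parse_topology <- function(text) {
  lines <- if (length(text) == 1 && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
  stripped <- sub(";.*$", "", lines)
  stripped <- trimws(stripped)

  section <- NA_character_
  rows <- list(atoms = list(), bonds = list(), angles = list(),
               dihedrals = list(), pairs = list())
  for (ln in seq_along(stripped)) {
    s <- stripped[ln]
    if (s == "") next
    if (grepl("^\\[", s)) {
      name <- tolower(trimws(gsub("\\[|\\]", "", s)))
      if (!name %in% names(rows)) {
        stop(sprintf("parse_topology: unknown section '%s' at line %d", name, ln))
      }
      section <- name
      next
    }
    if (is.na(section)) {
      stop(sprintf("parse_topology: content before any section at line %d", ln))
    }
    rows[[section]][[length(rows[[section]]) + 1L]] <- list(line = ln, fields = strsplit(s, "\\s+")[[1]])
  }

  num <- function(x, ln) {
    v <- suppressWarnings(as.numeric(x))
    if (any(is.na(v) & x != "NA")) {
      stop(sprintf("parse_topology: malformed number at line %d", ln))
    }
    v
  }
  int <- function(x, ln) {
    v <- suppressWarnings(as.integer(x))
    if (any(is.na(v))) stop(sprintf("parse_topology: malformed index at line %d", ln))
    v
  }

  if (!length(rows$atoms)) stop("parse_topology: missing [atoms] section")
  at <- do.call(rbind, lapply(rows$atoms, function(r) {
    f <- r$fields
    if (length(f) != 7) stop(sprintf("parse_topology: atom line %d needs 7 fields (index element type residue_index residue_name charge mass)", r$line))
    data.frame(index = int(f[1], r$line), element = f[2], type_label = f[3],
               residue_index = int(f[4], r$line), residue_name = f[5],
               charge = num(f[6], r$line), mass = num(f[7], r$line),
               stringsAsFactors = FALSE)
  }))
  at <- at[order(at$index), , drop = FALSE]
  rownames(at) <- NULL

  check_ref <- function(idx, ln) {
    if (!all(idx %in% at$index)) {
      stop(sprintf("parse_topology: reference to unknown atom at line %d", ln))
    }
    idx
  }

  parse_term <- function(entries, n_idx, n_par, build) {
    if (!length(entries)) return(build(NULL))
    build(lapply(entries, function(r) {
      f <- r$fields
      if (length(f) < n_idx || length(f) > n_idx + n_par) {
        stop(sprintf("parse_topology: malformed line %d (expected %d indices and up to %d parameters)",
                     r$line, n_idx, n_par))
      }
      idx <- check_ref(int(f[seq_len(n_idx)], r$line), r$line)
      par <- rep(NA_real_, n_par)
      extra <- length(f) - n_idx
      if (extra > 0) par[seq_len(extra)] <- num(f[n_idx + seq_len(extra)], r$line)
      c(idx, par)
    }))
  }

  bonds <- parse_term(rows$bonds, 2, 3, function(l) {
    if (is.null(l)) return(bonds_frame())
    m <- do.call(rbind, l)
    bonds_frame(m[, 1], m[, 2], m[, 3], m[, 4],
                ifelse(is.na(m[, 5]), 1, m[, 5]))
  })
  if (any(bonds$ai == bonds$aj)) stop("parse_topology: self-bond")

  angles <- parse_term(rows$angles, 3, 2, function(l) {
    if (is.null(l)) return(angles_frame())
    m <- do.call(rbind, l)
    angles_frame(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5])
  })

  # dihedral line: ai aj ak al funct [phi0 kphi mult]; funct 4 marks impropers
  dihedrals <- parse_term(rows$dihedrals, 4, 4, function(l) {
    if (is.null(l)) return(dihedrals_frame())
    m <- do.call(rbind, l)
    funct <- ifelse(is.na(m[, 5]), 1, m[, 5])
    dihedrals_frame(m[, 1], m[, 2], m[, 3], m[, 4], improper = funct == 4,
                    phi0 = ifelse(is.na(m[, 6]), 0, m[, 6]),
                    kphi = ifelse(is.na(m[, 7]), 0, m[, 7]),
                    mult = ifelse(is.na(m[, 8]), 3, m[, 8]))
  })

  pairs <- parse_term(rows$pairs, 2, 0, function(l) {
    if (is.null(l)) return(pairs_frame())
    m <- do.call(rbind, l)
    pairs_frame(m[, 1], m[, 2])
  })

  topology(at, bonds, angles, dihedrals, pairs)
}

fmt6 <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
}

#' Write a topology to its text form
#'
#' @param t A [topology()].
#' @param path Optional file path; when `NULL` the text is returned as a
#'   single string.
#' @return The file content, invisibly when written to `path`.
#' @export
write_topology <- function(t, path = NULL) {
  out <- c("[atoms]",
           "; index element type residue_index residue_name charge mass",
           sprintf("%d %s %s %d %s %s %s", t$atoms$index, t$atoms$element,
                   t$atoms$type_label, t$atoms$residue_index,
                   t$atoms$residue_name, fmt6(t$atoms$charge), fmt6(t$atoms$mass)))
  out <- c(out, "", "[bonds]", "; ai aj r0 kb order")
  if (nrow(t$bonds)) {
    out <- c(out, sprintf("%d %d %s %s %s", t$bonds$ai, t$bonds$aj,
                          fmt6(t$bonds$r0), fmt6(t$bonds$kb), fmt6(t$bonds$order)))
  }
  if (nrow(t$angles)) {
    out <- c(out, "", "[angles]", "; ai aj ak theta0 ktheta",
             sprintf("%d %d %d %s %s", t$angles$ai, t$angles$aj, t$angles$ak,
                     fmt6(t$angles$theta0), fmt6(t$angles$ktheta)))
  }
  if (nrow(t$dihedrals)) {
    d <- t$dihedrals
    out <- c(out, "", "[dihedrals]", "; ai aj ak al funct phi0 kphi mult",
             sprintf("%d %d %d %d %d %s %s %d", d$ai, d$aj, d$ak, d$al,
                     ifelse(d$improper, 4L, 1L), fmt6(d$phi0), fmt6(d$kphi),
                     d$mult))
  }
  if (nrow(t$pairs)) {
    out <- c(out, "", "[pairs]", "; ai aj",
             sprintf("%d %d", t$pairs$ai, t$pairs$aj))
  }
  text <- paste(c(out, ""), collapse = "\n")
  if (is.null(path)) return(text)
  writeLines(out, path)
  invisible(text)
}

#' @rdname parse_topology
#' @param path Path to a topology file.
#' @export
read_topology <- function(path) {
  parse_topology(readLines(path))
}
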