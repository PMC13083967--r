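# Conformational ensembles: ordered coordinate frames sharing one topology,
# produced by the toy stochastic-dynamics sampler or read from XYZ /
# multi-MODEL PDB files.

#' Construct a coordinate frame
#'
#' @param positions Numeric n x 3 matrix of positions, A.
#' @param time Frame time in ps (informational).
#' @param box Optional length-3 box vector, A.
#' @return An object of class `frame`.
#' @export
frame <- function(positions, time = 0, box = NULL) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, all(is.finite(positions)))
  if (!is.null(box)) stopifnot(length(box) == 3, all(is.finite(box)))
  structure(list(positions = unname(positions), time = as.numeric(time),
                 box = box), class = "frame")
}

#' Construct an ensemble of frames
#'
#' @param frames List of [frame()] objects with identical atom counts.
#' @param provenance Named list tagging how the ensemble was generated
#'   (sampler name, seed, settings).
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(frames, provenance = list()) {
  stopifnot(length(frames) >= 1)
  n <- nrow(frames[[1]]$positions)
  ok <- vapply(frames, function(f) nrow(f$positions) == n, logical(1))
  if (!all(ok)) stop("ensemble: frames differ in atom count")
  structure(list(frames = frames, provenance = provenance,
                 n_atoms = n), class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("ensemble: %d frame(s), %d atoms (%s)\n", length(x$frames),
              x$n_atoms, if (length(x$provenance)) x$provenance$sampler %||% "?" else "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sampler settings for the toy stochastic-dynamics integrator
#'
#' @param temperature Thermostat temperature, K.
#' @param friction Friction coefficient, 1/ps.
#' @param timestep Integration step, ps. The default (5e-4) keeps the
#'   stiffest bonds well inside the stability region of the overdamped
#'   Euler-Maruyama update, with a stationary-variance bias below 5 percent.
#' @param n_steps Number of integration steps.
#' @param stride Record a frame every `stride` steps.
#' @param seed Integer seed; identical seeds give bitwise-identical
#'   ensembles.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(temperature = 300, friction = 5, timestep = 5e-4,
                           n_steps = 1000, stride = 100, seed = 1) {
  stopifnot(timestep > 0, stride >= 1, temperature >= 0, friction > 0,
            n_steps >= 0)
  structure(list(temperature = temperature, friction = friction,
                 timestep = timestep, n_steps = as.integer(n_steps),
                 stride = as.integer(stride), seed = as.integer(seed)),
            class = "sampler_config")
}

#' Sample a conformational ensemble by overdamped Langevin dynamics
#'
#' Position (overdamped) Langevin dynamics on the toy force field:
#' `x <- x + mu dt F + sqrt(2 kB T mu dt) xi` with per-atom mobility
#' `mu = 1 / (friction * mass)`. The stationary distribution is the
#' Boltzmann distribution of the toy energy; dynamics realism is not part
#' of the contract. The initial frame is always recorded, then one frame
#' every `stride` steps.
#'
#' @param t A [topology()] with parameterized bonded terms.
#' @param f0 Initial [frame()].
#' @param cfg A [sampler_config()].
#' @return An [ensemble()] tagged with sampler provenance.
#' @export
toy_sd_sample <- function(t, f0, cfg) {
  stopifnot(inherits(cfg, "sampler_config"))
  if (nrow(f0$positions) != n_atoms(t)) {
    stop("toy_sd_sample: frame does not match topology atom count")
  }
  ff <- ff_compile(t)
  kBT <- 0.0019872 * cfg$temperature
  mu <- 1 / (cfg$friction * ff$mass)
  drift <- mu * cfg$timestep
  sigma <- sqrt(2 * kBT * mu * cfg$timestep)
  x <- f0$positions
  n <- ff$n
  rng <- rng_new(cfg$seed)
  frames <- list(frame(x, time = f0$time, box = f0$box))
  with_rng(rng, {
    for (s in seq_len(cfg$n_steps)) {
      F <- ff_forces(ff, x)
      if (!all(is.finite(F))) {
        stop("toy_sd_sample: non-finite force (divergence) at step ", s)
      }
      x <- x + F * drift + matrix(stats::rnorm(3L * n), n, 3) * sigma
      if (s %% cfg$stride == 0L) {
        frames[[length(frames) + 1L]] <-
          frame(x, time = f0$time + s * cfg$timestep, box = f0$box)
      }
    }
  })
  ensemble(frames, provenance = list(sampler = "toy_sd", seed = cfg$seed,
                                     temperature = cfg$temperature,
                                     friction = cfg$friction,
                                     timestep = cfg$timestep,
                                     n_steps = cfg$n_steps,
                                     stride = cfg$stride))
}

# ---- coordinate file I/O: XYZ and multi-MODEL PDB ----

#' Read coordinate frames from an XYZ or multi-MODEL PDB file
#'
#' Format is chosen by file extension (`.xyz` else PDB). Atom counts are
#' checked against the topology.
#'
#' @param path File path.
#' @param t A [topology()] the frames belong to.
#' @return An [ensemble()].
#' @export
read_frames <- function(path, t) {
  lines <- readLines(path)
  frames <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) {
    read_xyz_lines(lines)
  } else {
    read_pdb_lines(lines)
  }
  bad <- vapply(frames, function(f) nrow(f$positions) != n_atoms(t), logical(1))
  if (any(bad)) {
    stop(sprintf("read_frames: frame has wrong atom count (expected %d)", n_atoms(t)))
  }
  ensemble(frames, provenance = list(sampler = "file", path = path))
}

read_xyz_lines <- function(lines) {
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "") { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("read_frames: malformed XYZ atom count at line ", i)
    if (i + 1L + n > length(lines)) stop("read_frames: truncated XYZ frame at line ", i)
    block <- lines[(i + 2L):(i + 1L + n)]
    f <- do.call(rbind, lapply(block, function(s) {
      parts <- strsplit(trimws(s), "\\s+")[[1]]
      as.numeric(parts[2:4])
    }))
    if (any(!is.finite(f))) stop("read_frames: non-numeric XYZ coordinate near line ", i)
    frames[[length(frames) + 1L]] <- frame(f)
    i <- i + 2L + n
  }
  frames
}

read_pdb_lines <- function(lines) {
  frames <- list()
  cur <- list()
  flush <- function() {
    if (length(cur)) frames[[length(frames) + 1L]] <<- frame(do.call(rbind, cur))
    cur <<- list()
  }
  for (s in lines) {
    rec <- substr(s, 1, 6)
    if (rec %in% c("ATOM  ", "HETATM")) {
      cur[[length(cur) + 1L]] <- c(as.numeric(substr(s, 31, 38)),
                                   as.numeric(substr(s, 39, 46)),
                                   as.numeric(substr(s, 47, 54)))
    } else if (trimws(rec) %in% c("ENDMDL", "END")) {
      flush()
    }
  }
  flush()
  frames
}

#' Write an ensemble to an XYZ or multi-MODEL PDB file
#'
#' @param e An [ensemble()].
#' @param path Output path; `.xyz` selects XYZ, anything else PDB.
#' @param t A [topology()] supplying element symbols and residue data.
#' @return `path`, invisibly.
#' @export
write_frames <- function(e, path, t) {
  stopifnot(e$n_atoms == n_atoms(t))
  if (grepl("\\.xyz$", path, ignore.case = TRUE)) {
    out <- unlist(lapply(e$frames, function(f) {
      c(sprintf("%d", e$n_atoms), sprintf("t = %g ps", f$time),
        sprintf("%-2s %12.6f %12.6f %12.6f", t$atoms$element,
                f$positions[, 1], f$positions[, 2], f$positions[, 3]))
    }))
  } else {
    out <- unlist(lapply(seq_along(e$frames), function(k) {
      f <- e$frames[[k]]
      c(sprintf("MODEL     %4d", k),
        sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                t$atoms$index, substr(t$atoms$type_label, 1, 4),
                substr(t$atoms$residue_name, 1, 3), t$atoms$residue_index,
                f$positions[, 1], f$positions[, 2], f$positions[, 3],
                t$atoms$element),
        "ENDMDL")
    }))
    out <- c(out, "END")
  }
  writeLines(out, path)
  invisible(path)
}
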