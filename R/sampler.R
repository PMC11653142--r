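# Stand-in coarse-grained sampler. This is deliberately NOT the CABS
# lattice engine with its knowledge-based force field: it is a minimal
# off-lattice CA-bead Metropolis Monte Carlo model (harmonic virtual bonds,
# soft excluded volume, plus the flat-bottom restraint term) whose only job
# is to exercise restraint sets end-to-end at desk scale.

#' Sampler configuration
#'
#' Tunables of the stand-in CA Monte Carlo sampler. Energies are in kT
#' units (the temperature is dimensionless), distances in Angstrom.
#'
#' @param n_steps number of attempted single-bead moves.
#' @param snapshot_every record a frame every this many attempted moves.
#' @param temperature dimensionless kT.
#' @param move_sigma per-axis standard deviation (Angstrom) of the Gaussian
#'   bead displacement proposal.
#' @param bond_length ideal consecutive CA-CA virtual-bond length.
#' @param bond_k harmonic bond constant (energy per Angstrom squared).
#' @param ev_radius soft excluded-volume radius between non-bonded beads.
#' @param ev_k excluded-volume constant (energy per Angstrom squared).
#' @param seed integer RNG seed; fixed-seed runs are bit-reproducible.
#' @return a `SamplerConfig` list.
#' @export
sampler_config <- function(n_steps = 200000L, snapshot_every = 1000L,
                           temperature = 1.0, move_sigma = 0.35,
                           bond_length = 3.8, bond_k = 20,
                           ev_radius = 3.5, ev_k = 5, seed = 7503L) {
  stopifnot_scalar_number(n_steps, "n_steps", 0)
  stopifnot_scalar_number(snapshot_every, "snapshot_every", 1)
  stopifnot_scalar_number(temperature, "temperature", 0, strict = TRUE)
  stopifnot_scalar_number(move_sigma, "move_sigma", 0, strict = TRUE)
  stopifnot_scalar_number(bond_length, "bond_length", 0, strict = TRUE)
  stopifnot_scalar_number(bond_k, "bond_k", 0)
  stopifnot_scalar_number(ev_radius, "ev_radius", 0)
  stopifnot_scalar_number(ev_k, "ev_k", 0)
  if (n_steps > 0 && snapshot_every > n_steps)
    abort_flex("snapshot_every must not exceed n_steps", "spec_error")
  structure(list(n_steps = as.integer(n_steps),
                 snapshot_every = as.integer(snapshot_every),
                 temperature = temperature, move_sigma = move_sigma,
                 bond_length = bond_length, bond_k = bond_k,
                 ev_radius = ev_radius, ev_k = ev_k,
                 seed = as.integer(seed)), class = "SamplerConfig")
}

new_trajectory <- function(coords, frame_interval = 1L, ids = NULL,
                           energies = NULL, acceptance_rate = NA_real_) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (any(!is.finite(coords)))
    abort_flex("trajectory coordinates must be finite", "spec_error")
  structure(list(coords = coords, frame_interval = frame_interval,
                 ids = ids, energies = energies,
                 acceptance_rate = acceptance_rate), class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("Trajectory: %d frames x %d residues (frame interval %d)\n",
              d[1], d[2], x$frame_interval))
  if (!is.na(x$acceptance_rate))
    cat(sprintf("  sampler acceptance rate: %.3f\n", x$acceptance_rate))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `Trajectory`.
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Coordinates of one trajectory frame
#' @param traj a `Trajectory`.
#' @param f frame index (1-based).
#' @return n x 3 coordinate matrix.
#' @export
frame_coords <- function(traj, f) {
  matrix(traj$coords[f, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Pseudo-energy of a CA conformation
#'
#' Reference (pure R) evaluation of the sampler's energy: harmonic
#' consecutive-bond term, soft excluded volume between non-bonded beads
#' closer than the excluded-volume radius, and the flat-bottom restraint
#' term. The C++ sampler keeps an incrementally updated copy of this same
#' quantity.
#'
#' @param coords n x 3 CA coordinate matrix.
#' @param set a `RestraintSet` (or `NULL` for no restraints).
#' @param config a [sampler_config()].
#' @param chain optional chain id per residue (default: one chain).
#' @return total energy in kT units.
#' @export
pseudo_energy <- function(coords, set = NULL, config = sampler_config(),
                          chain = rep(1L, nrow(coords))) {
  n <- nrow(coords)
  e <- 0
  if (n >= 2L) {
    a <- seq_len(n - 1L)
    same <- chain[a] == chain[a + 1L]
    blen <- sqrt(rowSums((coords[a, , drop = FALSE] - coords[a + 1L, , drop = FALSE])^2))
    e <- e + sum(config$bond_k * (blen[same] - config$bond_length)^2)
    d <- as.matrix(stats::dist(coords))
    bonded <- abs(row(d) - col(d)) == 1L & outer(chain, chain, "==")
    close <- upper.tri(d) & !bonded & d < config$ev_radius
    e <- e + sum(config$ev_k * (config$ev_radius - d[close])^2)
  }
  if (!is.null(set) && nrow(set$restraints) > 0)
    e <- e + total_restraint_energy(coords, set)
  e
}

#' Run the stand-in CA Monte Carlo sampler
#'
#' Single-bead Gaussian-displacement Metropolis sampling under
#' [pseudo_energy()]. Snapshots are taken on the attempted-move schedule
#' (every `snapshot_every` moves), so the frame layout is independent of
#' acceptance history; the first frame is always the input conformation.
#' Runs are fully deterministic for a fixed seed. Not a CABS engine: see
#' the package vignette for what this stand-in does and does not model.
#'
#' @param structure a `ProteinStructure`; every residue must have a CA.
#' @param set a `RestraintSet` from [generate_restraints()], or `NULL`.
#' @param config a [sampler_config()].
#' @return a `Trajectory` with per-frame energies and the acceptance rate.
#' @export
run_sampler <- function(structure, set = NULL, config = sampler_config()) {
  res <- structure$residues
  if (any(is.na(res$x)))
    abort_flex("run_sampler requires a CA atom for every residue", "missing_score")
  coords <- ca_coords(structure)
  chain <- as.integer(factor(res$chain, levels = unique(res$chain)))
  rs <- if (is.null(set)) empty_restraint_frame() else set$restraints
  hw <- if (is.null(set)) 1 else set$config$flat_halfwidth %||% 1
  quad <- if (!is.null(set) && identical(set$config$penalty_shape, "quadratic")) 1L else 0L
  out <- with_seed(config$seed,
    .mc_sample(coords, chain,
               as.integer(rs$i), as.integer(rs$j),
               as.numeric(rs$d0), as.numeric(rs$slope_min), as.numeric(rs$slope_max),
               hw, quad,
               config$n_steps, config$snapshot_every,
               config$temperature, config$move_sigma,
               config$bond_length, config$bond_k,
               config$ev_radius, config$ev_k))
  if (isTRUE(out$diverged))
    abort_flex("sampler diverged: a coordinate moved more than 1000 Angstrom from the initial centroid",
               "divergence_error")
  new_trajectory(out$frames,
                 frame_interval = config$snapshot_every,
                 ids = res[, c("chain", "res_num", "icode", "res_name")],
                 energies = as.numeric(out$energies),
                 acceptance_rate = if (out$attempted > 0)
                   out$accepted / out$attempted else NA_real_)
}

#' Write a trajectory as multi-model PDB text
#'
#' CA-only MODEL/ENDMDL blocks, one per frame.
#'
#' @param traj a `Trajectory`.
#' @return character scalar of PDB text.
#' @export
write_trajectory_pdb <- function(traj) {
  d <- dim(traj$coords)
  ids <- traj$ids %||% data.frame(chain = "A", res_num = seq_len(d[2]),
                                  icode = "", res_name = "ALA")
  blocks <- vapply(seq_len(d[1]), function(f) {
    xyz <- frame_coords(traj, f)
    lines <- format_atom_line(seq_len(d[2]), ids$res_name, ids$chain,
                              ids$res_num, ids$icode,
                              xyz[, 1], xyz[, 2], xyz[, 3])
    paste(c(sprintf("MODEL     %4d", f), lines, "ENDMDL"), collapse = "\n")
  }, character(1))
  paste0(paste(c(blocks, "END"), collapse = "\n"), "\n")
}

#' Read a CA trajectory from multi-model PDB text
#'
#' @param pdb_text character scalar of multi-model PDB text.
#' @return a `Trajectory` over the CA atoms.
#' @export
read_trajectory_pdb <- function(pdb_text) {
  if (!nzchar(trimws(pdb_text))) abort_flex("empty PDB text", "malformed_input")
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(pdb_text, tf)
  pdb <- tryCatch(
    suppressWarnings(suppressMessages(bio3d::read.pdb(tf, multi = TRUE, verbose = FALSE))),
    error = function(e) abort_flex(paste("unparsable PDB text:", conditionMessage(e)),
                                   "malformed_input"))
  sel <- which(pdb$atom$elety == "CA")
  if (!length(sel)) abort_flex("no CA atoms in trajectory", "malformed_input")
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(nf, length(sel), 3L))
  for (k in seq_along(sel)) {
    cols <- (sel[k] - 1L) * 3L + 1:3
    coords[, k, ] <- xyz[, cols, drop = FALSE]
  }
  ids <- data.frame(chain = ifelse(is.na(pdb$atom$chain[sel]), "A", pdb$atom$chain[sel]),
                    res_num = pdb$atom$resno[sel],
                    icode = ifelse(is.na(pdb$atom$insert[sel]), "", pdb$atom$insert[sel]),
                    res_name = pdb$atom$resid[sel], stringsAsFactors = FALSE)
  new_trajectory(coords, ids = ids)
}

#' Write a trajectory as a plain text table
#'
#' Whitespace-separated columns: frame, residue index (1-based), x, y, z.
#'
#' @param traj a `Trajectory`.
#' @return character scalar.
#' @export
write_trajectory_table <- function(traj) {
  d <- dim(traj$coords)
  out <- c("# frame residue x y z")
  for (f in seq_len(d[1])) {
    xyz <- frame_coords(traj, f)
    out <- c(out, sprintf("%d %d %.3f %.3f %.3f", f, seq_len(d[2]),
                          xyz[, 1], xyz[, 2], xyz[, 3]))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Read a trajectory from the plain text table format
#'
#' @param text character scalar as written by [write_trajectory_table()].
#' @return a `Trajectory`.
#' @export
read_trajectory_table <- function(text) {
  df <- tryCatch(
    utils::read.table(text = text, comment.char = "#",
                      col.names = c("frame", "residue", "x", "y", "z")),
    error = function(e) abort_flex("malformed trajectory table", "malformed_input"))
  if (!all(vapply(df, is.numeric, logical(1))))
    abort_flex("malformed trajectory table: non-numeric fields", "malformed_input")
  frames <- sort(unique(df$frame))
  resid <- sort(unique(df$residue))
  coords <- array(NA_real_, c(length(frames), length(resid), 3L))
  fi <- match(df$frame, frames); ri <- match(df$residue, resid)
  coords[cbind(fi, ri, 1L)] <- df$x
  coords[cbind(fi, ri, 2L)] <- df$y
  coords[cbind(fi, ri, 3L)] <- df$z
  if (any(is.na(coords)))
    abort_flex("trajectory table has missing frame/residue cells", "malformed_input")
  new_trajectory(coords)
}
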