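# Synthetic fixtures: CA traces with scripted secondary structure and
# pLDDT profiles, plus trajectories with planted per-residue fluctuation
# magnitudes. These are statistical test articles, not physical models.

#' Describe one segment of a synthetic structure
#'
#' @param ss_class one of HELIX, SHEET, TURN, COIL.
#' @param length number of residues (>= 1).
#' @param plddt_level mean pLDDT of the segment, in [0, 100].
#' @param plddt_jitter standard deviation of per-residue pLDDT noise
#'   (values are clipped back into [0, 100]).
#' @return a `SegmentSpec` list.
#' @export
segment_spec <- function(ss_class, length, plddt_level = 90, plddt_jitter = 0) {
  if (!ss_class %in% SS_CLASSES)
    abort_flex("ss_class must be one of HELIX/SHEET/TURN/COIL", "spec_error")
  stopifnot_scalar_number(length, "length", 1)
  stopifnot_scalar_number(plddt_jitter, "plddt_jitter", 0)
  if (plddt_level < 0 || plddt_level > 100)
    abort_flex("plddt_level must lie in [0, 100]", "range_error")
  structure(list(ss_class = ss_class, length = as.integer(length),
                 plddt_level = plddt_level, plddt_jitter = plddt_jitter),
            class = "SegmentSpec")
}

rotate_about <- function(v, axis, angle) {
  # Rodrigues rotation of v about unit axis
  axis <- axis / sqrt(sum(axis^2))
  v * cos(angle) + pracma::cross(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

perp_unit <- function(dir) {
  cand <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- cand - sum(cand * dir) * dir
  u / sqrt(sum(u^2))
}

#' Build a synthetic CA structure from segment specifications
#'
#' Generates a continuous CA trace: HELIX segments follow ideal alpha-helix
#' geometry (1.5 Angstrom rise, 2.3 Angstrom radius, 100 degree twist per
#' residue, giving a 3.83 Angstrom CA-CA step), SHEET and COIL segments
#' take 3.8 Angstrom extended steps (coil directions get a small seeded
#' wobble so long coils are not collinear), and TURN segments bend the
#' chain direction through a smooth 90 degree arc. All consecutive CA
#' distances fall in [3.6, 4.0] Angstrom. Secondary-structure labels and
#' pLDDT values come straight from the segment specs; output is
#' deterministic per seed.
#'
#' @param segments list of [segment_spec()] objects (total length >= 5).
#' @param seed integer seed for pLDDT jitter and coil wobble.
#' @param chain chain identifier (single character).
#' @param source_id label stored on the structure.
#' @return a `ProteinStructure` with `ss` and `plddt` populated.
#' @examples
#' s <- make_toy_structure(list(
#'   segment_spec("HELIX", 10, 95), segment_spec("COIL", 5, 40),
#'   segment_spec("HELIX", 10, 95)), seed = 1)
#' table(s$residues$ss)
#' @export
make_toy_structure <- function(segments, seed = 7503L, chain = "A",
                               source_id = "toy") {
  if (!length(segments)) abort_flex("no segments given", "spec_error")
  segments <- lapply(segments, function(s) {
    if (!inherits(s, "SegmentSpec")) abort_flex("segments must be segment_spec objects",
                                                "spec_error")
    s
  })
  total <- sum(vapply(segments, function(s) s$length, integer(1)))
  if (total < 5L) abort_flex("total length must be >= 5", "spec_error")

  with_seed(seed, {
    pos <- c(0, 0, 0)
    dir <- c(0, 0, 1)
    nrm <- c(1, 0, 0)
    pts <- list(pos)
    ss <- character(0)
    plddt <- numeric(0)
    helix_t <- function(t) {
      th <- 100 * pi / 180
      c(2.3 * cos(th * t), 2.3 * sin(th * t), 1.5 * t)
    }
    first <- TRUE
    for (seg in segments) {
      L <- seg$length
      nsteps <- if (first) L - 1L else L
      if (seg$ss_class == "HELIX") {
        u <- nrm; w <- pracma::cross(dir, u)
        R <- cbind(u, w, dir)
        for (t in seq_len(max(nsteps, 0))) {
          delta <- as.numeric(R %*% (helix_t(t) - helix_t(t - 1)))
          pos <- pos + delta
          pts[[length(pts) + 1L]] <- pos
        }
        if (nsteps > 0) {
          last <- as.numeric(R %*% (helix_t(nsteps) - helix_t(nsteps - 1)))
          dir <- last / sqrt(sum(last^2))
          nrm <- perp_unit(dir)
        }
      } else if (seg$ss_class == "TURN") {
        ang <- (90 * pi / 180) / max(L, 1)
        for (t in seq_len(max(nsteps, 0))) {
          dir <- rotate_about(dir, nrm, ang)
          dir <- dir / sqrt(sum(dir^2))
          pos <- pos + 3.8 * dir
          pts[[length(pts) + 1L]] <- pos
        }
      } else {  # SHEET / COIL: extended steps
        wobble <- if (seg$ss_class == "COIL") 0.06 else 0
        for (t in seq_len(max(nsteps, 0))) {
          if (wobble > 0) {
            dir <- dir + stats::rnorm(3, 0, wobble)
            dir <- dir / sqrt(sum(dir^2))
          }
          pos <- pos + 3.8 * dir
          pts[[length(pts) + 1L]] <- pos
        }
        nrm <- perp_unit(dir)
      }
      ss <- c(ss, rep(seg$ss_class, L))
      pl <- seg$plddt_level + stats::rnorm(L, 0, seg$plddt_jitter)
      plddt <- c(plddt, pmin(pmax(pl, 0), 100))
      first <- FALSE
    }
    xyz <- do.call(rbind, pts)
    residues <- data.frame(
      chain = chain, res_num = seq_len(total), icode = "",
      res_name = "ALA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      plddt = plddt, ss = ss, stringsAsFactors = FALSE)
    new_protein_structure(residues, source_id = source_id)
  })
}

#' Generate a trajectory with planted per-residue fluctuations
#'
#' Each frame is the reference conformation plus independent isotropic
#' Gaussian noise with per-axis standard deviation `sigma / sqrt(3)`, so
#' the expected RMSF of residue i is exactly `sigma[i]`. Optionally a
#' random rigid motion (rotation + translation) is applied per frame, which
#' superposition should remove.
#'
#' @param structure a `ProteinStructure` (reference conformation).
#' @param sigma per-residue target RMSF in Angstrom (scalar or one per
#'   residue, all >= 0).
#' @param n_frames number of frames (>= 2).
#' @param seed integer seed.
#' @param rigid_motion add a random rigid motion per frame (default FALSE).
#' @return a `Trajectory`.
#' @export
make_planted_trajectory <- function(structure, sigma, n_frames = 100L,
                                    seed = 7503L, rigid_motion = FALSE) {
  ref <- ca_coords(structure)
  n <- nrow(ref)
  sigma <- rep_len(as.numeric(sigma), n)
  if (any(sigma < 0) || any(!is.finite(sigma)))
    abort_flex("planted sigma must be finite and >= 0", "spec_error")
  if (n_frames < 2L) abort_flex("n_frames must be >= 2", "spec_error")
  with_seed(seed, {
    coords <- array(NA_real_, c(n_frames, n, 3L))
    sd_axis <- sigma / sqrt(3)
    # all displacement noise is drawn first, so for a fixed seed the
    # underlying ensemble is identical with and without rigid motion
    for (f in seq_len(n_frames))
      coords[f, , ] <- ref + matrix(stats::rnorm(n * 3L, 0, sd_axis), n, 3L)
    if (rigid_motion) {
      for (f in seq_len(n_frames)) {
        R <- kabsch_rotation(matrix(stats::rnorm(9), 3), diag(3))  # random proper rotation
        coords[f, , ] <- coords[f, , ] %*% R +
          matrix(stats::rnorm(3, 0, 5), n, 3, byrow = TRUE)
      }
    }
    new_trajectory(coords,
                   ids = structure$residues[, c("chain", "res_num", "icode", "res_name")])
  })
}

#' Write a structure as AlphaFold-style PDB text
#'
#' PDB text with the per-residue pLDDT score in the B-factor column, as
#' AlphaFold model files carry it. Round-trips through
#' [parse_structure()] with `plddt_source = "bfactor"` (coordinates to 3
#' decimals, pLDDT to 2).
#'
#' @param structure a `ProteinStructure` with pLDDT present on every
#'   CA-bearing residue.
#' @return character scalar of PDB text.
#' @export
make_af_like_pdb <- function(structure) {
  r <- structure$residues
  if (any(is.na(r$plddt[!is.na(r$x)])))
    abort_flex("structure lacks pLDDT scores", "missing_score")
  write_structure_pdb(structure, plddt_as_bfactor = TRUE)
}

#' The standard helix-coil-helix benchmark fixture
#'
#' A 31-residue chain emulating a minimal packed fold: two 10-residue
#' helices at pLDDT 95 joined by a 3-residue low-confidence loop that bends
#' the chain through 180 degrees, so the helices pack antiparallel about
#' 10 Angstrom apart (within restraint range of each other), flanked by
#' 4-residue coil termini at pLDDT 40. Under category-mode restraints the
#' helix pair is rigidified - including inter-helix restraints that lock
#' the tertiary arrangement - while the loop and termini stay unrestrained
#' and fluctuate freely.
#'
#' @param seed integer seed.
#' @param helix_plddt,coil_plddt segment confidence levels.
#' @return a `ProteinStructure`.
#' @export
helix_coil_helix <- function(seed = 7503L, helix_plddt = 95, coil_plddt = 40) {
  make_toy_structure(list(
    segment_spec("COIL", 4, coil_plddt),
    segment_spec("HELIX", 10, helix_plddt),
    segment_spec("TURN", 2, coil_plddt),
    segment_spec("TURN", 1, coil_plddt),
    segment_spec("HELIX", 10, helix_plddt),
    segment_spec("COIL", 4, coil_plddt)), seed = seed,
    source_id = sprintf("helix-coil-helix-%d", seed))
}

#' Planted flexibility profile matching a structure's annotation
#'
#' Maps low-confidence coil/turn segments to high fluctuation and
#' high-confidence regular structure to low fluctuation: residues with
#' pLDDT below `low_cutoff` or labelled COIL get `flexible_sigma`, others
#' `rigid_sigma`. Mirrors the common observation that low-confidence loops
#' and termini are the mobile parts of a globular protein; levels are
#' configurable to construct counter-examples (e.g. a rigid low-pLDDT
#' helix).
#'
#' @param structure a `ProteinStructure` with `ss` and `plddt`.
#' @param rigid_sigma RMSF (Angstrom) planted on rigid residues.
#' @param flexible_sigma RMSF planted on flexible residues.
#' @param low_cutoff pLDDT below which a residue counts as flexible.
#' @return numeric vector of per-residue sigma.
#' @export
planted_sigma <- function(structure, rigid_sigma = 0.3, flexible_sigma = 1.2,
                          low_cutoff = 50) {
  r <- structure$residues
  flex <- r$ss %in% c("COIL", "TURN") | (!is.na(r$plddt) & r$plddt < low_cutoff)
  ifelse(flex, flexible_sigma, rigid_sigma)
}
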