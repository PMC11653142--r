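# Shared fixture builders used across test files.

# a small random multi-segment structure, <= 30 residues
random_toy <- function(seed) {
  withr::with_seed(seed, {
    n_seg <- sample(2:5, 1)
    segs <- lapply(seq_len(n_seg), function(i) {
      segment_spec(sample(c("HELIX", "SHEET", "TURN", "COIL"), 1),
                   sample(3:6, 1),
                   plddt_level = runif(1, 5, 100),
                   plddt_jitter = runif(1, 0, 8))
    })
    make_toy_structure(segs, seed = seed + 1L)
  })
}

# minimal hand-written PDB text: one CA ATOM record per row of `df`
# (df: chain, resno, x, y, z, b); optionally an extra non-CA atom
toy_pdb <- function(df, extra_n_atom_for = integer()) {
  lines <- character()
  serial <- 1L
  for (r in seq_len(nrow(df))) {
    if (r %in% extra_n_atom_for) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  N   ALA %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           N",
        serial, df$chain[r], df$resno[r], df$x[r] - 1, df$y[r], df$z[r], 1, df$b[r]))
      serial <- serial + 1L
    } else {
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
        serial, df$chain[r], df$resno[r], df$x[r], df$y[r], df$z[r], 1, df$b[r]))
      serial <- serial + 1L
    }
  }
  paste(c(lines, "END"), collapse = "\n")
}

# straight CA chain with a given step
straight_chain <- function(n, step = 3.8) {
  cbind(x = step * (seq_len(n) - 1), y = 0, z = 0)
}

structure_from_coords <- function(xyz, plddt = 80, ss = "COIL", chain = "A") {
  n <- nrow(xyz)
  flexrestrain:::new_protein_structure(data.frame(
    chain = chain, res_num = seq_len(n), icode = "", res_name = "ALA",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    plddt = rep_len(plddt, n), ss = rep_len(ss, n),
    stringsAsFactors = FALSE), source_id = "inline")
}

trajectory_from_frames <- function(frames) {
  arr <- array(NA_real_, c(length(frames), nrow(frames[[1]]), 3L))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  flexrestrain:::new_trajectory(arr)
}
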