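# Structure input: PDB parsing (via bio3d), pLDDT extraction, and
# secondary-structure assignment (DSSP collapse or CA-geometric fallback).

SS_CLASSES <- c("HELIX", "SHEET", "TURN", "COIL")

new_protein_structure <- function(residues, source_id = "") {
  stopifnot(is.data.frame(residues))
  needed <- c("chain", "res_num", "icode", "res_name", "x", "y", "z", "plddt", "ss")
  missing <- setdiff(needed, names(residues))
  if (length(missing))
    abort_flex(paste("residue table lacks columns:", paste(missing, collapse = ", ")),
               "spec_error")
  key <- paste(residues$chain, residues$res_num, residues$icode)
  if (anyDuplicated(key))
    abort_flex("residues must be unique by (chain, res_num, icode)", "spec_error")
  pl <- residues$plddt
  if (any(!is.na(pl) & (pl < 0 | pl > 100)))
    abort_flex("pLDDT values must lie in [0, 100]", "range_error")
  has_ca <- !is.na(residues$x)
  if (any(has_ca & (!is.finite(residues$x) | !is.finite(residues$y) | !is.finite(residues$z))))
    abort_flex("CA coordinates must be finite", "spec_error")
  structure(list(residues = residues, source_id = source_id),
            class = "ProteinStructure")
}

#' @export
print.ProteinStructure <- function(x, ...) {
  r <- x$residues
  cat(sprintf("ProteinStructure '%s': %d residues (%d with CA), chains: %s\n",
              x$source_id, nrow(r), sum(!is.na(r$x)),
              paste(unique(r$chain), collapse = ",")))
  cat(sprintf("  pLDDT: %s; secondary structure: %s\n",
              if (all(!is.na(r$plddt[!is.na(r$x)]))) "complete" else "absent/partial",
              if (all(!is.na(r$ss[!is.na(r$x)]))) "assigned" else "absent/partial"))
  invisible(x)
}

#' Number of residues in a structure
#' @param structure a `ProteinStructure`.
#' @return integer count.
#' @export
n_residues <- function(structure) nrow(structure$residues)

#' Extract the CA coordinate matrix of a structure
#'
#' @param structure a `ProteinStructure`.
#' @param drop_missing drop residues without a CA atom (default `TRUE`).
#' @return numeric matrix with one row per residue and columns x, y, z.
#' @export
ca_coords <- function(structure, drop_missing = TRUE) {
  r <- structure$residues
  if (drop_missing) r <- r[!is.na(r$x), , drop = FALSE]
  m <- as.matrix(r[, c("x", "y", "z")])
  rownames(m) <- NULL
  m
}

#' Parse a protein structure from PDB text
#'
#' Reads ATOM records from PDB-format text and builds a residue table with
#' one entry per residue. Residues lacking a CA atom are retained with
#' missing coordinates; for multi-model files only the first MODEL is used.
#' AlphaFold-style models store the per-residue pLDDT confidence score
#' (0-100) in the B-factor column; set `plddt_source = "bfactor"` to read it.
#'
#' @param pdb_text character scalar holding the PDB file contents.
#' @param plddt_source `"none"` (ignore B-factors), `"bfactor"` (interpret
#'   the B-factor column as pLDDT on the 0-100 scale), or `"sidecar"`
#'   (leave pLDDT empty here; scores arrive later via
#'   [load_plddt_sidecar()]).
#' @param source_id free-text label stored on the structure.
#' @return a `ProteinStructure`.
#' @examples
#' pdb <- paste0("ATOM      1  CA  ALA A   1       0.000   0.000   0.000",
#'               "  1.00 91.20           C\n")
#' s <- parse_structure(pdb, plddt_source = "bfactor")
#' s$residues$plddt
#' @export
parse_structure <- function(pdb_text, plddt_source = c("none", "bfactor", "sidecar"),
                            source_id = "pdb") {
  plddt_source <- match.arg(plddt_source)
  if (!is.character(pdb_text) || length(pdb_text) != 1L || !nzchar(trimws(pdb_text)))
    abort_flex("empty PDB text", "malformed_input")
  if (!grepl("^(ATOM|HETATM)", pdb_text) && !grepl("\n(ATOM|HETATM)", pdb_text))
    abort_flex("no ATOM/HETATM records found", "malformed_input")
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(pdb_text, tf)
  pdb <- tryCatch(
    suppressWarnings(suppressMessages(bio3d::read.pdb(tf, verbose = FALSE))),
    error = function(e) abort_flex(paste("unparsable PDB text:", conditionMessage(e)),
                                   "malformed_input")
  )
  atoms <- pdb$atom
  if (is.null(atoms) || nrow(atoms) == 0L)
    abort_flex("no ATOM records parsed", "malformed_input")
  # first altloc only
  atoms <- atoms[is.na(atoms$alt) | atoms$alt %in% c("", "A"), , drop = FALSE]
  atoms$chain[is.na(atoms$chain)] <- " "
  atoms$insert[is.na(atoms$insert)] <- ""
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  first_idx <- !duplicated(key)
  res_keys <- key[first_idx]
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$chain, ca$resno, ca$insert, sep = "\r")), , drop = FALSE]
  ca_key <- paste(ca$chain, ca$resno, ca$insert, sep = "\r")
  m <- match(res_keys, ca_key)
  residues <- data.frame(
    chain = atoms$chain[first_idx],
    res_num = atoms$resno[first_idx],
    icode = atoms$insert[first_idx],
    res_name = atoms$resid[first_idx],
    x = ca$x[m], y = ca$y[m], z = ca$z[m],
    plddt = NA_real_, ss = NA_character_,
    stringsAsFactors = FALSE
  )
  if (plddt_source == "bfactor") {
    b <- ifelse(is.na(m), atoms$b[first_idx], ca$b[m])
    if (any(!is.na(b) & (b < 0 | b > 100)))
      abort_flex("B-factor outside [0, 100] cannot be a pLDDT score", "range_error")
    residues$plddt <- b
  }
  new_protein_structure(residues, source_id = source_id)
}

#' Fill pLDDT scores from a sidecar TSV
#'
#' The sidecar holds one row per residue: `chain<TAB>res_num<TAB>plddt`.
#' Lines starting with `#` and an optional non-numeric header row are
#' skipped. Rows that match no residue are reported as warnings and ignored.
#'
#' @param structure a `ProteinStructure`.
#' @param tsv_text character scalar with the TSV contents.
#' @return the structure with `plddt` filled for matched residues.
#' @export
load_plddt_sidecar <- function(structure, tsv_text) {
  lines <- strsplit(tsv_text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) abort_flex("empty pLDDT sidecar", "malformed_input")
  fields <- strsplit(lines, "[\t ]+")
  res <- structure$residues
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    if (length(f) < 3L)
      abort_flex(sprintf("sidecar line %d: expected 3 fields", k), "malformed_input")
    score <- suppressWarnings(as.numeric(f[3]))
    resno <- suppressWarnings(as.integer(f[2]))
    if (is.na(score) || is.na(resno)) {
      # tolerate a header row: both fields non-numeric on the first line
      if (k == 1L && is.na(score) && is.na(resno)) next
      abort_flex(sprintf("sidecar line %d: non-numeric residue number or score", k),
                 "malformed_input")
    }
    if (score < 0 || score > 100)
      abort_flex(sprintf("sidecar line %d: pLDDT %.3f outside [0, 100]", k, score),
                 "range_error")
    hit <- which(res$chain == f[1] & res$res_num == resno)
    if (!length(hit)) {
      warning(sprintf("sidecar row for %s/%d matches no residue", f[1], resno),
              call. = FALSE)
      next
    }
    res$plddt[hit[1]] <- score
  }
  structure$residues <- res
  structure
}

DSSP8_TO_4 <- c(H = "HELIX", G = "HELIX", I = "HELIX",
                E = "SHEET", B = "SHEET",
                T = "TURN", S = "TURN",
                "-" = "COIL", " " = "COIL", C = "COIL")

#' Assign 4-state secondary structure from a DSSP string or file
#'
#' Accepts either a bare 8-state string (one character per CA-bearing
#' residue, in structure order) or a standard DSSP output file, and collapses
#' the 8 DSSP states to 4 classes: H/G/I to HELIX, E/B to SHEET, T/S to TURN
#' and everything else to COIL. The T/S-to-TURN choice keeps bends in the
#' moderately-flexible class used by category assignment.
#'
#' @param structure a `ProteinStructure`.
#' @param dssp8 character scalar: the 8-state string or a DSSP file's text.
#' @return the structure with `ss` set on CA-bearing residues.
#' @export
assign_ss_from_dssp <- function(structure, dssp8) {
  if (!is.character(dssp8) || length(dssp8) != 1L)
    abort_flex("dssp8 must be a single string", "malformed_input")
  if (grepl("#  RESIDUE", dssp8, fixed = TRUE)) {
    lines <- strsplit(dssp8, "\n", fixed = TRUE)[[1]]
    start <- grep("#  RESIDUE", lines, fixed = TRUE)[1] + 1L
    body <- lines[seq(start, length(lines))]
    body <- body[nchar(body) >= 17 & substr(body, 14, 14) != "!"]
    codes <- substr(body, 17, 17)
  } else {
    codes <- strsplit(gsub("\n", "", dssp8), "")[[1]]
  }
  res <- structure$residues
  idx <- which(!is.na(res$x))
  if (length(codes) != length(idx))
    abort_flex(sprintf("DSSP string length %d != %d CA-bearing residues",
                       length(codes), length(idx)), "length_mismatch")
  unknown <- setdiff(unique(codes), names(DSSP8_TO_4))
  if (length(unknown))
    abort_flex(paste("unknown DSSP codes:", paste(unknown, collapse = " ")),
               "unknown_code")
  res$ss[idx] <- unname(DSSP8_TO_4[codes])
  structure$residues <- res
  structure
}

#' Assign secondary structure from CA geometry
#'
#' A fixture-grade fallback that needs no external DSSP run: a residue
#' window is called helical when its i to i+3 and i to i+4 CA distances
#' match the alpha-helix signature (about 5.1 and 6.2 Angstrom). Residues in
#' qualifying windows become HELIX; everything else is COIL (strand pairing
#' cannot be detected from a lone CA trace, so SHEET is never produced
#' here). Helix segments shorter than 3 residues collapse to COIL. Chains
#' with fewer than 5 CA atoms are labelled all-COIL.
#'
#' @param structure a `ProteinStructure`.
#' @param d13 length-2 numeric, accepted range for the i,i+3 distance.
#' @param d14 length-2 numeric, accepted range for the i,i+4 distance.
#' @return the structure with `ss` set on CA-bearing residues.
#' @export
assign_ss_geometric <- function(structure, d13 = c(4.2, 5.8), d14 = c(5.2, 7.2)) {
  res <- structure$residues
  for (ch in unique(res$chain)) {
    idx <- which(res$chain == ch & !is.na(res$x))
    res$ss[idx] <- "COIL"
    n <- length(idx)
    if (n < 5L) next
    xyz <- as.matrix(res[idx, c("x", "y", "z")])
    helical <- logical(n)
    for (i in seq_len(n - 4L)) {
      a3 <- sqrt(sum((xyz[i, ] - xyz[i + 3L, ])^2))
      a4 <- sqrt(sum((xyz[i, ] - xyz[i + 4L, ])^2))
      if (a3 >= d13[1] && a3 <= d13[2] && a4 >= d14[1] && a4 <= d14[2])
        helical[i:(i + 4L)] <- TRUE
    }
    # collapse helix runs shorter than 3 residues
    r <- rle(helical)
    r$values[r$values & r$lengths < 3L] <- FALSE
    helical <- inverse.rle(r)
    res$ss[idx[helical]] <- "HELIX"
  }
  structure$residues <- res
  structure
}

format_atom_line <- function(serial, res_name, chain, res_num, icode, x, y, z,
                             occ = 1, b = 0) {
  sprintf("ATOM  %5d  CA  %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, res_name, chain, res_num,
          ifelse(nzchar(icode), icode, " "), x, y, z, occ, b)
}

#' Serialize a structure's CA trace as PDB text
#'
#' Writes one fixed-width ATOM record per CA-bearing residue. When
#' `plddt_as_bfactor` is `TRUE` and pLDDT is present, it is written to the
#' B-factor column (AlphaFold convention); otherwise the column is 0.00.
#'
#' @param structure a `ProteinStructure`.
#' @param plddt_as_bfactor write pLDDT into the B-factor column.
#' @return character scalar of PDB text.
#' @export
write_structure_pdb <- function(structure, plddt_as_bfactor = TRUE) {
  r <- structure$residues
  r <- r[!is.na(r$x), , drop = FALSE]
  b <- if (plddt_as_bfactor) ifelse(is.na(r$plddt), 0, r$plddt) else rep(0, nrow(r))
  lines <- format_atom_line(seq_len(nrow(r)), r$res_name, r$chain, r$res_num,
                            r$icode, r$x, r$y, r$z, b = b)
  paste0(paste(c(lines, "END"), collapse = "\n"), "\n")
}
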