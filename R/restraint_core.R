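# Restraint generation: flexibility categories, the nine restraint modes,
# the flat-bottom restraint energy, subsampling, and the restraint file
# format.

RESTRAINT_MODES <- c("ss2", "ss1", "all", "min", "max", "mean",
                     "plddt1", "plddt2", "category")

#' Rules mapping secondary structure + pLDDT to a flexibility category
#'
#' Residues are first classified by secondary structure into three base
#' levels: coil (0, most flexible), turn (1, moderately flexible) and
#' helix/sheet (2, most rigid). The pLDDT confidence then refines the
#' level: scores at or above `high_conf_cutoff` bump the category up by one
#' (less flexible), scores below `low_conf_cutoff` bump it down by one, and
#' the result is clamped to the 0-3 range (3 = rigid).
#'
#' @param high_conf_cutoff pLDDT at/above which confidence raises the
#'   category (default 90, the usual "very high confidence" band).
#' @param low_conf_cutoff pLDDT below which confidence lowers the category
#'   (default 50, the usual "low confidence" band).
#' @param base named integer vector of base categories per SS class.
#' @return a `CategoryRules` list.
#' @export
category_rules <- function(high_conf_cutoff = 90, low_conf_cutoff = 50,
                           base = c(COIL = 0L, TURN = 1L, HELIX = 2L, SHEET = 2L)) {
  if (!(low_conf_cutoff < high_conf_cutoff))
    abort_flex("low_conf_cutoff must be below high_conf_cutoff", "spec_error")
  if (!all(SS_CLASSES %in% names(base)) || !all(base %in% 0:2))
    abort_flex("base categories must cover all SS classes with values in 0..2",
               "spec_error")
  structure(list(high_conf_cutoff = high_conf_cutoff,
                 low_conf_cutoff = low_conf_cutoff,
                 base = base), class = "CategoryRules")
}

#' Assign flexibility categories from secondary structure and pLDDT
#'
#' @param ss character vector of SS classes (HELIX/SHEET/TURN/COIL).
#' @param plddt numeric vector of pLDDT scores in [0, 100].
#' @param rules a [category_rules()] object.
#' @return integer vector of categories in 0..3 (0 fully flexible,
#'   3 rigid). Monotonically non-decreasing in pLDDT for fixed `ss`.
#' @examples
#' assign_category(c("COIL", "HELIX", "TURN", "SHEET"), c(40, 95, 60, 45))
#' @export
assign_category <- function(ss, plddt, rules = category_rules()) {
  if (any(is.na(plddt))) abort_flex("pLDDT score absent", "missing_score")
  if (any(plddt < 0 | plddt > 100))
    abort_flex("pLDDT outside [0, 100]", "range_error")
  if (any(is.na(ss)) || !all(ss %in% SS_CLASSES))
    abort_flex("secondary-structure class absent or invalid", "missing_ss")
  base <- unname(rules$base[ss])
  bump <- ifelse(plddt >= rules$high_conf_cutoff, 1L,
                 ifelse(plddt < rules$low_conf_cutoff, -1L, 0L))
  pmin(pmax(base + bump, 0L), 3L)
}

#' Default category-pair strength matrix
#'
#' Symmetric 4x4 lookup giving the restraint weight for a residue pair from
#' their flexibility categories: 0.0 (no restraint) when either residue is
#' fully flexible, 1.0 (full strength) when both are in the two most rigid
#' categories, 0.5 (half strength) otherwise. Any symmetric matrix with
#' entries in [0, 1] may be substituted.
#'
#' @return a 4x4 numeric matrix with dimnames "0".."3".
#' @export
default_strength_matrix <- function() {
  m <- outer(0:3, 0:3, function(a, b) {
    lo <- pmin(a, b)
    ifelse(lo == 0, 0, ifelse(lo >= 2, 1, 0.5))
  })
  dimnames(m) <- list(as.character(0:3), as.character(0:3))
  m
}

#' Pairwise restraint weight from two flexibility categories
#'
#' @param cat_i,cat_j integer categories in 0..3 (vectorized).
#' @param matrix a symmetric 4x4 strength matrix, entries in [0, 1].
#' @return numeric weights in [0, 1]; symmetric in its two arguments.
#' @export
pair_strength <- function(cat_i, cat_j, matrix = default_strength_matrix()) {
  if (!isTRUE(all.equal(matrix, t(matrix))))
    abort_flex("strength matrix must be symmetric", "spec_error")
  if (any(matrix < 0 | matrix > 1))
    abort_flex("strength matrix entries must lie in [0, 1]", "spec_error")
  if (any(cat_i < 0 | cat_i > 3 | cat_j < 0 | cat_j > 3))
    abort_flex("categories must lie in 0..3", "spec_error")
  matrix[cbind(cat_i + 1L, cat_j + 1L)]
}

#' Restraint-generation configuration
#'
#' Bundles every tunable of the restraint generator. Defaults are the
#' optimized protocol values: Category mode, 11.5 Angstrom maximum restraint
#' distance, sequence gap 3, min_force 3.5 (penalty slope for too-short
#' distances) and max_force 0.5 (too-long distances), a 1 Angstrom
#' flat-bottom half-width, and seed 7503.
#'
#' @param mode restraint mode, one of `"ss2"`, `"ss1"`, `"all"`, `"min"`,
#'   `"max"`, `"mean"`, `"plddt1"`, `"plddt2"`, `"category"`.
#' @param max_distance maximum CA-CA distance (Angstrom) for a pair to be
#'   restrained.
#' @param min_seq_gap minimum sequence-index separation `j - i` within a
#'   chain for a pair to qualify.
#' @param min_force energy slope per Angstrom applied when a distance falls
#'   below the flat bottom.
#' @param max_force energy slope per Angstrom applied when a distance rises
#'   above the flat bottom.
#' @param flat_halfwidth half-width (Angstrom) of the zero-energy band
#'   around the ideal distance.
#' @param plddt_strength_floor weights below this are dropped in the
#'   min/max/mean modes (strict comparison: a weight equal to the floor is
#'   kept).
#' @param plddt_pair_cutoff pLDDT threshold for the plddt1/plddt2 modes
#'   (strictly-greater comparison).
#' @param drop_fraction fraction of restraints removed at random after
#'   generation (0 disables).
#' @param seed integer seed used by `drop_fraction` subsampling.
#' @param penalty_shape `"linear"` (default) or `"quadratic"` growth outside
#'   the flat bottom.
#' @param mean_floor apply the strength floor to the mean mode as well
#'   (default `TRUE`).
#' @param include_interchain also restrain residue pairs across chains
#'   (default `FALSE`; the gap rule then applies only within chains).
#' @param rules a [category_rules()] object (category mode only).
#' @param strength_matrix a 4x4 symmetric matrix (category mode only).
#' @return a `RestraintConfig` list.
#' @export
restraint_config <- function(mode = "category",
                             max_distance = 11.5,
                             min_seq_gap = 3L,
                             min_force = 3.5,
                             max_force = 0.5,
                             flat_halfwidth = 1.0,
                             plddt_strength_floor = 0.5,
                             plddt_pair_cutoff = 50,
                             drop_fraction = 0,
                             seed = 7503L,
                             penalty_shape = c("linear", "quadratic"),
                             mean_floor = TRUE,
                             include_interchain = FALSE,
                             rules = category_rules(),
                             strength_matrix = default_strength_matrix()) {
  mode <- match.arg(tolower(mode), RESTRAINT_MODES)
  penalty_shape <- match.arg(penalty_shape)
  stopifnot_scalar_number(max_distance, "max_distance", 0, strict = TRUE)
  stopifnot_scalar_number(min_seq_gap, "min_seq_gap", 1)
  stopifnot_scalar_number(min_force, "min_force", 0)
  stopifnot_scalar_number(max_force, "max_force", 0)
  stopifnot_scalar_number(flat_halfwidth, "flat_halfwidth", 0)
  stopifnot_scalar_number(drop_fraction, "drop_fraction", 0)
  if (drop_fraction > 1) abort_flex("drop_fraction must lie in [0, 1]", "spec_error")
  structure(list(mode = mode, max_distance = max_distance,
                 min_seq_gap = as.integer(min_seq_gap),
                 min_force = min_force, max_force = max_force,
                 flat_halfwidth = flat_halfwidth,
                 plddt_strength_floor = plddt_strength_floor,
                 plddt_pair_cutoff = plddt_pair_cutoff,
                 drop_fraction = drop_fraction, seed = as.integer(seed),
                 penalty_shape = penalty_shape, mean_floor = mean_floor,
                 include_interchain = include_interchain,
                 rules = rules, strength_matrix = strength_matrix),
            class = "RestraintConfig")
}

new_restraint_set <- function(restraints, config) {
  structure(list(restraints = restraints, config = config), class = "RestraintSet")
}

#' @export
print.RestraintSet <- function(x, ...) {
  cat(sprintf("RestraintSet: %d restraints (mode %s, max distance %.1f A, gap >= %d)\n",
              nrow(x$restraints),
              x$config$mode %||% "?",
              x$config$max_distance %||% NA_real_,
              x$config$min_seq_gap %||% NA_integer_))
  invisible(x)
}

#' Number of restraints in a set
#' @param set a `RestraintSet`.
#' @return integer count.
#' @export
n_restraints <- function(set) nrow(set$restraints)

empty_restraint_frame <- function() {
  data.frame(i = integer(), j = integer(),
             chain_i = character(), res_i = integer(), icode_i = character(),
             chain_j = character(), res_j = integer(), icode_j = character(),
             d0 = numeric(), weight = numeric(),
             slope_min = numeric(), slope_max = numeric(),
             stringsAsFactors = FALSE)
}

#' Generate distance restraints for a structure under a given mode
#'
#' Candidate pairs are all residue pairs (i, j) with both CA atoms present,
#' sequence separation `j - i >= min_seq_gap`, CA-CA distance at most
#' `max_distance` and (by default) lying in the same chain. Each mode then
#' assigns a weight in [0, 1]:
#' \describe{
#'   \item{ss2}{1.0 iff both residues are in regular secondary structure
#'     (helix or sheet).}
#'   \item{ss1}{1.0 iff at least one residue is.}
#'   \item{all}{1.0 for every candidate pair.}
#'   \item{min / max / mean}{the minimum / maximum / mean of the pair's
#'     pLDDT scores divided by 100; pairs whose weight falls below
#'     `plddt_strength_floor` are dropped (for `mean` this floor is
#'     controlled by `mean_floor`).}
#'   \item{plddt1 / plddt2}{1.0 iff at least one / both residues have pLDDT
#'     strictly above `plddt_pair_cutoff`.}
#'   \item{category}{weight from [assign_category()] and [pair_strength()];
#'     zero-weight pairs are omitted.}
#' }
#' Every emitted restraint stores the input CA-CA distance as its ideal
#' distance `d0` and per-side slopes `slope_min = weight * min_force`,
#' `slope_max = weight * max_force`. Restraints are ordered by (i, j); when
#' `drop_fraction > 0` a seeded random subsample is removed afterwards.
#'
#' @param structure a `ProteinStructure`; pLDDT must be present for the
#'   pLDDT-based modes, secondary structure for ss1/ss2/category.
#' @param config a [restraint_config()].
#' @return a `RestraintSet`. Indices `i`, `j` are 0-based positions in the
#'   residue list.
#' @export
generate_restraints <- function(structure, config = restraint_config()) {
  stopifnot(inherits(structure, "ProteinStructure"),
            inherits(config, "RestraintConfig"))
  res <- structure$residues
  has_ca <- !is.na(res$x)
  mode <- config$mode
  if (mode %in% c("min", "max", "mean", "plddt1", "plddt2", "category") &&
      any(is.na(res$plddt[has_ca])))
    abort_flex(sprintf("mode '%s' requires pLDDT for every CA-bearing residue", mode),
               "missing_score")
  if (mode %in% c("ss1", "ss2", "category") && any(is.na(res$ss[has_ca])))
    abort_flex(sprintf("mode '%s' requires secondary structure for every CA-bearing residue",
                       mode), "missing_ss")

  idx <- which(has_ca)                       # 1-based rows with CA
  n <- length(idx)
  if (n < 2L) return(new_restraint_set(empty_restraint_frame(), config))
  xyz <- as.matrix(res[idx, c("x", "y", "z")])
  dmat <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(idx, idx, "-"))
  same_chain <- outer(res$chain[idx], res$chain[idx], "==")
  ok <- upper.tri(dmat) & dmat <= config$max_distance &
    ((same_chain & sep >= config$min_seq_gap) |
       (config$include_interchain & !same_chain))
  pair <- which(ok, arr.ind = TRUE)
  if (!nrow(pair)) return(new_restraint_set(empty_restraint_frame(), config))
  a <- pair[, 1]; b <- pair[, 2]             # local indices into idx
  pl <- res$plddt[idx]; ss <- res$ss[idx]
  regular <- ss %in% c("HELIX", "SHEET")

  weight <- switch(
    mode,
    ss2 = ifelse(regular[a] & regular[b], 1, 0),
    ss1 = ifelse(regular[a] | regular[b], 1, 0),
    all = rep(1, length(a)),
    min = pmin(pl[a], pl[b]) / 100,
    max = pmax(pl[a], pl[b]) / 100,
    mean = (pl[a] + pl[b]) / 200,
    plddt1 = ifelse(pl[a] > config$plddt_pair_cutoff |
                      pl[b] > config$plddt_pair_cutoff, 1, 0),
    plddt2 = ifelse(pl[a] > config$plddt_pair_cutoff &
                      pl[b] > config$plddt_pair_cutoff, 1, 0),
    category = {
      cat <- assign_category(ss, pl, config$rules)
      pair_strength(cat[a], cat[b], config$strength_matrix)
    }
  )

  keep <- switch(
    mode,
    min = , max = weight >= config$plddt_strength_floor,
    mean = if (config$mean_floor) weight >= config$plddt_strength_floor
           else weight > 0,
    weight > 0
  )
  a <- a[keep]; b <- b[keep]; weight <- weight[keep]
  gi <- idx[a]; gj <- idx[b]
  # canonical i < j on global indices, then sort
  swap <- gi > gj
  tmp <- gi[swap]; gi[swap] <- gj[swap]; gj[swap] <- tmp
  ord <- order(gi, gj)
  gi <- gi[ord]; gj <- gj[ord]; weight <- weight[ord]
  d0 <- dmat[cbind(match(gi, idx), match(gj, idx))]
  rs <- data.frame(
    i = gi - 1L, j = gj - 1L,
    chain_i = res$chain[gi], res_i = res$res_num[gi], icode_i = res$icode[gi],
    chain_j = res$chain[gj], res_j = res$res_num[gj], icode_j = res$icode[gj],
    d0 = d0, weight = weight,
    slope_min = weight * config$min_force,
    slope_max = weight * config$max_force,
    stringsAsFactors = FALSE
  )
  set <- new_restraint_set(rs, config)
  if (config$drop_fraction > 0)
    set <- subsample_restraints(set, config$drop_fraction, config$seed)
  set
}

#' Randomly remove a fraction of restraints
#'
#' Removes exactly `round(drop_fraction * N)` restraints uniformly at random
#' without replacement, preserving the order of the survivors. Deterministic
#' for a fixed seed; the caller's RNG state is untouched.
#'
#' @param set a `RestraintSet`.
#' @param drop_fraction fraction in [0, 1] to remove.
#' @param seed integer seed.
#' @return the thinned `RestraintSet`.
#' @export
subsample_restraints <- function(set, drop_fraction, seed = set$config$seed %||% 7503L) {
  if (drop_fraction < 0 || drop_fraction > 1)
    abort_flex("drop_fraction must lie in [0, 1]", "spec_error")
  n <- nrow(set$restraints)
  n_drop <- round(drop_fraction * n)
  if (n_drop == 0) return(set)
  drop <- with_seed(seed, sample.int(n, n_drop))
  set$restraints <- set$restraints[-drop, , drop = FALSE]
  rownames(set$restraints) <- NULL
  set
}

#' Flat-bottom restraint energy
#'
#' Zero within `flat_halfwidth` of the ideal distance `d0`; outside the flat
#' bottom the energy grows from zero with slope `slope_min` (distances below
#' ideal) or `slope_max` (above ideal). Linear growth by default; the
#' quadratic variant uses the same coefficients on the squared excursion.
#' Continuous, non-negative, and non-decreasing in the excursion on each
#' side. All arguments are vectorized.
#'
#' @param d observed distance(s), Angstrom.
#' @param d0 ideal distance(s), Angstrom.
#' @param slope_min,slope_max per-side penalty coefficients (energy per
#'   Angstrom), already scaled by the restraint weight.
#' @param flat_halfwidth half-width of the zero-energy band (Angstrom).
#' @param shape `"linear"` or `"quadratic"`.
#' @return non-negative energy, same length as the broadcast inputs.
#' @examples
#' restraint_energy(9.5, d0 = 7, slope_min = 3.5, slope_max = 0.5)  # 0.5 * 1.5
#' @export
restraint_energy <- function(d, d0, slope_min, slope_max, flat_halfwidth = 1,
                             shape = c("linear", "quadratic")) {
  shape <- match.arg(shape)
  below <- (d0 - flat_halfwidth) - d   # > 0 when too short
  above <- d - (d0 + flat_halfwidth)   # > 0 when too long
  p <- if (shape == "linear") 1 else 2
  pmax(below, 0)^p * slope_min + pmax(above, 0)^p * slope_max
}

#' Total restraint energy of a conformation
#'
#' Sums [restraint_energy()] over a restraint set evaluated on a CA
#' coordinate matrix. By construction the input structure's own coordinates
#' score exactly zero (every distance equals its ideal value).
#'
#' @param coords numeric matrix (n x 3) of CA coordinates covering all
#'   restrained indices.
#' @param set a `RestraintSet`.
#' @param flat_halfwidth half-width of the flat bottom; defaults to the
#'   generating config's value.
#' @param shape penalty shape; defaults to the generating config's value.
#' @return total energy (non-negative scalar).
#' @export
total_restraint_energy <- function(coords, set,
                                   flat_halfwidth = set$config$flat_halfwidth %||% 1,
                                   shape = set$config$penalty_shape %||% "linear") {
  rs <- set$restraints
  if (!nrow(rs)) return(0)
  if (any(is.na(rs$i)) || max(rs$j) + 1L > nrow(coords))
    abort_flex("restrained residue lacks coordinates", "index_error")
  pi <- coords[rs$i + 1L, , drop = FALSE]
  pj <- coords[rs$j + 1L, , drop = FALSE]
  if (any(!is.finite(pi)) || any(!is.finite(pj)))
    abort_flex("restrained residue lacks coordinates", "index_error")
  d <- sqrt(rowSums((pi - pj)^2))
  sum(restraint_energy(d, rs$d0, rs$slope_min, rs$slope_max, flat_halfwidth, shape))
}

#' Serialize a restraint set to text
#'
#' One line per restraint, `"<chain>:<res_num[icode]> <chain>:<res_num[icode]>
#' <d0> <weight>"` with distances and weights printed to 3 decimals, after a
#' `#`-prefixed header carrying the generating configuration.
#'
#' @param set a `RestraintSet`.
#' @return character scalar.
#' @export
write_restraints <- function(set) {
  cfg <- set$config
  header <- c(
    "# flexrestrain restraint set",
    if (!is.null(cfg))
      sprintf("# mode=%s max_distance=%g min_seq_gap=%d min_force=%g max_force=%g flat_halfwidth=%g drop_fraction=%g seed=%d",
              cfg$mode, cfg$max_distance, cfg$min_seq_gap, cfg$min_force,
              cfg$max_force, cfg$flat_halfwidth, cfg$drop_fraction, cfg$seed)
  )
  rs <- set$restraints
  body <- sprintf("%s:%d%s %s:%d%s %.3f %.3f",
                  rs$chain_i, rs$res_i, rs$icode_i,
                  rs$chain_j, rs$res_j, rs$icode_j,
                  rs$d0, rs$weight)
  paste0(paste(c(header, body), collapse = "\n"), "\n")
}

#' Parse a restraint set from text
#'
#' Inverse of [write_restraints()]. Comment lines (`#`) are skipped. When a
#' structure is supplied the residue identities are resolved back to 0-based
#' sequence indices (and per-side slopes recomputed from `config`); without
#' one the indices are left missing.
#'
#' @param text character scalar with the restraint file contents.
#' @param structure optional `ProteinStructure` used to resolve indices.
#' @param config optional [restraint_config()] supplying min/max force for
#'   the slope columns (defaults to the standard configuration).
#' @return a `RestraintSet`.
#' @export
read_restraints <- function(text, structure = NULL, config = restraint_config()) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  rx <- "^\\s*(\\S+):(-?\\d+)([A-Za-z]?)\\s+(\\S+):(-?\\d+)([A-Za-z]?)\\s+(\\S+)\\s+(\\S+)\\s*$"
  rows <- lapply(which(keep), function(k) {
    m <- regmatches(lines[k], regexec(rx, lines[k]))[[1]]
    if (!length(m))
      abort_flex(sprintf("malformed restraint line %d: '%s'", k, lines[k]),
                 "malformed_input")
    d0 <- suppressWarnings(as.numeric(m[8]))
    w <- suppressWarnings(as.numeric(m[9]))
    if (is.na(d0) || is.na(w))
      abort_flex(sprintf("malformed restraint line %d: non-numeric field", k),
                 "malformed_input")
    if (w < 0 || w > 1)
      abort_flex(sprintf("restraint line %d: weight outside [0, 1]", k),
                 "range_error")
    data.frame(chain_i = m[2], res_i = as.integer(m[3]), icode_i = m[4],
               chain_j = m[5], res_j = as.integer(m[6]), icode_j = m[7],
               d0 = d0, weight = w, stringsAsFactors = FALSE)
  })
  rs <- if (length(rows)) do.call(rbind, rows) else
    empty_restraint_frame()[, c("chain_i", "res_i", "icode_i", "chain_j",
                                "res_j", "icode_j", "d0", "weight")]
  if (!is.null(structure)) {
    res <- structure$residues
    key <- paste(res$chain, res$res_num, res$icode, sep = "\r")
    mi <- match(paste(rs$chain_i, rs$res_i, rs$icode_i, sep = "\r"), key)
    mj <- match(paste(rs$chain_j, rs$res_j, rs$icode_j, sep = "\r"), key)
    if (any(is.na(mi)) || any(is.na(mj)))
      abort_flex("restraint references a residue absent from the structure",
                 "malformed_input")
    rs$i <- mi - 1L
    rs$j <- mj - 1L
  } else {
    rs$i <- NA_integer_
    rs$j <- NA_integer_
  }
  rs$slope_min <- rs$weight * config$min_force
  rs$slope_max <- rs$weight * config$max_force
  rs <- rs[, c("i", "j", "chain_i", "res_i", "icode_i",
               "chain_j", "res_j", "icode_j", "d0", "weight",
               "slope_min", "slope_max")]
  if (!is.null(structure)) rs <- rs[order(rs$i, rs$j), , drop = FALSE]
  rownames(rs) <- NULL
  new_restraint_set(rs, config)
}
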