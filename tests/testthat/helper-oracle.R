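# Independent brute-force oracles, written as literal rule application so
# they stay independent of the package's vectorized implementations.

# O(n^2) restraint reference: enumerate all residue pairs and apply the
# mode rules one pair at a time.
brute_force_restraints <- function(structure, config) {
  res <- structure$residues
  n <- nrow(res)
  rows <- list()
  for (a in seq_len(n - 1)) {
    for (b in seq(a + 1, n)) {
      if (is.na(res$x[a]) || is.na(res$x[b])) next
      if (res$chain[a] == res$chain[b]) {
        if ((b - a) < config$min_seq_gap) next
      } else if (!config$include_interchain) next
      d <- sqrt((res$x[a] - res$x[b])^2 + (res$y[a] - res$y[b])^2 +
                  (res$z[a] - res$z[b])^2)
      if (d > config$max_distance) next
      pa <- res$plddt[a]; pb <- res$plddt[b]
      sa <- res$ss[a]; sb <- res$ss[b]
      reg_a <- sa == "HELIX" || sa == "SHEET"
      reg_b <- sb == "HELIX" || sb == "SHEET"
      w <- switch(config$mode,
        ss2 = if (reg_a && reg_b) 1 else 0,
        ss1 = if (reg_a || reg_b) 1 else 0,
        all = 1,
        min = min(pa, pb) / 100,
        max = max(pa, pb) / 100,
        mean = (pa + pb) / 2 / 100,
        plddt1 = if (pa > config$plddt_pair_cutoff ||
                       pb > config$plddt_pair_cutoff) 1 else 0,
        plddt2 = if (pa > config$plddt_pair_cutoff &&
                       pb > config$plddt_pair_cutoff) 1 else 0,
        category = {
          cat1 <- oracle_category(sa, pa, config$rules)
          cat2 <- oracle_category(sb, pb, config$rules)
          lo <- min(cat1, cat2)
          if (lo == 0) 0 else if (lo >= 2) 1 else 0.5
        })
      drop <- switch(config$mode,
        min = , max = w < config$plddt_strength_floor,
        mean = if (config$mean_floor) w < config$plddt_strength_floor else w <= 0,
        w <= 0)
      if (drop) next
      rows[[length(rows) + 1L]] <- data.frame(i = a - 1L, j = b - 1L,
                                              d0 = d, weight = w)
    }
  }
  if (!length(rows))
    return(data.frame(i = integer(), j = integer(), d0 = numeric(),
                      weight = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$i, out$j), , drop = FALSE]
}

oracle_category <- function(ss, plddt, rules) {
  base <- if (ss == "COIL") 0 else if (ss == "TURN") 1 else 2
  bump <- if (plddt >= rules$high_conf_cutoff) 1 else
    if (plddt < rules$low_conf_cutoff) -1 else 0
  min(max(base + bump, 0), 3)
}

# textbook product-moment correlation, written from the summation formula
textbook_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# exhaustive proper-rotation grid search minimizing RMSD of P onto Q
# (both centered); used to check the reflection handling of the SVD fit
grid_best_rmsd <- function(P, Q, step_deg = 6) {
  angs <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  half <- seq(0, 180, by = step_deg) * pi / 180
  best <- Inf
  for (a in angs) for (b in half) for (g in angs) {
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
    Rz2 <- matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1), 3, byrow = TRUE)
    R <- Rz1 %*% Ry %*% Rz2
    rmsd <- sqrt(mean(rowSums((P %*% R - Q)^2)))
    if (rmsd < best) best <- rmsd
  }
  best
}

# per-coordinate RMSF reference: explicit loops over residues and frames
brute_force_rmsf <- function(arr) {
  nf <- dim(arr)[1]; nr <- dim(arr)[2]
  out <- numeric(nr)
  for (r in seq_len(nr)) {
    mx <- mean(arr[, r, 1]); my <- mean(arr[, r, 2]); mz <- mean(arr[, r, 3])
    acc <- 0
    for (f in seq_len(nf))
      acc <- acc + (arr[f, r, 1] - mx)^2 + (arr[f, r, 2] - my)^2 + (arr[f, r, 3] - mz)^2
    out[r] <- sqrt(acc / nf)
  }
  out
}

pair_key <- function(rs) paste(rs$i, rs$j, sep = "-")
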