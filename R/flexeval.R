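# Evaluation: Kabsch superposition, per-residue RMSF, and the
# best-of-replicas Pearson correlation protocol.

kabsch_rotation <- function(P, Q) {
  # rotation U (det +1) minimizing || P %*% U - Q ||_F for centered P, Q
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Superpose every trajectory frame onto a reference conformation
#'
#' Rigid-body least-squares (Kabsch) fit of each frame's CA coordinates
#' onto the reference; only proper rotations are used, so mirror images are
#' never produced (the reflection case is corrected through the sign of the
#' smallest singular value).
#'
#' @param traj a `Trajectory`.
#' @param reference n x 3 coordinate matrix (default: the first frame).
#' @return the superposed `Trajectory`.
#' @export
kabsch_superpose <- function(traj, reference = frame_coords(traj, 1)) {
  d <- dim(traj$coords)
  if (d[2] < 3L || nrow(reference) != d[2])
    abort_flex("superposition needs >= 3 shared residues", "length_mismatch")
  qc <- colMeans(reference)
  Q0 <- sweep(reference, 2, qc)
  sv <- svd(Q0)$d
  if (sum(sv > 1e-8 * max(sv[1], 1)) < 2L)
    abort_flex("reference conformation is collinear or coincident", "degenerate_input")
  out <- traj
  for (f in seq_len(d[1])) {
    P <- frame_coords(traj, f)
    pc <- colMeans(P)
    P0 <- sweep(P, 2, pc)
    out$coords[f, , ] <- P0 %*% kabsch_rotation(P0, Q0) +
      matrix(qc, d[2], 3, byrow = TRUE)
  }
  out
}

#' Per-residue root mean square fluctuation
#'
#' RMSF of residue i is the root of the mean (over frames) squared
#' displacement of its CA from that residue's average position. With
#' `superpose = TRUE` frames are first rigidly aligned to the mean
#' structure: frames are fit to the first frame, the frame-average
#' structure is computed, and all frames are re-fit to that mean (one
#' refinement pass).
#'
#' @param traj a `Trajectory` with at least 2 frames.
#' @param superpose remove global rigid-body motion first (default `TRUE`).
#' @return an `RMSFProfile`: list with `values` (Angstrom, one per residue)
#'   and the trajectory's residue `ids` when available.
#' @export
compute_rmsf <- function(traj, superpose = TRUE) {
  d <- dim(traj$coords)
  if (d[1] < 2L) abort_flex("RMSF needs at least 2 frames", "too_few_frames")
  if (superpose) {
    traj <- kabsch_superpose(traj, frame_coords(traj, 1))
    mean_xyz <- apply(traj$coords, c(2, 3), mean)
    traj <- kabsch_superpose(traj, mean_xyz)
  }
  mean_xyz <- apply(traj$coords, c(2, 3), mean)
  sq <- sweep(traj$coords, c(2, 3), mean_xyz)^2
  values <- sqrt(apply(sq, 2, sum) / d[1])
  structure(list(values = unname(values), ids = traj$ids), class = "RMSFProfile")
}

#' @export
print.RMSFProfile <- function(x, ...) {
  cat(sprintf("RMSFProfile: %d residues, mean %.3f A (range %.3f-%.3f)\n",
              length(x$values), mean(x$values), min(x$values), max(x$values)))
  invisible(x)
}

profile_values <- function(p) {
  if (inherits(p, "RMSFProfile")) p$values else as.numeric(p)
}

#' Correlation between two RMSF profiles
#'
#' Standard product-moment (Pearson) correlation by default; rank
#' (Spearman) correlation behind the `method` flag.
#'
#' @param a,b `RMSFProfile`s or numeric vectors of equal length >= 3.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return correlation in [-1, 1].
#' @export
pearson_r <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  a <- profile_values(a); b <- profile_values(b)
  if (length(a) != length(b) || length(a) < 3L)
    abort_flex("profiles must have equal length >= 3", "length_mismatch")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    abort_flex("correlation undefined for a constant profile", "constant_profile")
  stats::cor(a, b, method = method)
}

#' Best-of-replicas correlation between a prediction and references
#'
#' Correlates a predicted RMSF profile with each reference replica profile
#' and reports the maximum — the convention used when several independent
#' reference simulations of the same protein exist.
#'
#' @param pred predicted `RMSFProfile` (or numeric vector).
#' @param refs list of reference profiles, all matching `pred` in length.
#' @param method correlation flavor, see [pearson_r()].
#' @return an `EvalResult`: `per_replica_r`, `best_r` (their maximum),
#'   `mean_pred_rmsf` and `mean_ref_rmsf` (Angstrom).
#' @export
best_replica_correlation <- function(pred, refs, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!is.list(refs) || inherits(refs, "RMSFProfile")) refs <- list(refs)
  if (!length(refs)) abort_flex("need at least one reference profile", "length_mismatch")
  pv <- profile_values(pred)
  per <- vapply(refs, function(r) pearson_r(pv, r, method), numeric(1))
  structure(list(per_replica_r = per, best_r = max(per),
                 mean_pred_rmsf = mean(pv),
                 mean_ref_rmsf = mean(vapply(refs, function(r)
                   mean(profile_values(r)), numeric(1)))),
            class = "EvalResult")
}

#' @export
print.EvalResult <- function(x, ...) {
  cat(sprintf("EvalResult: best r = %.3f over %d replica(s) [%s]\n",
              x$best_r, length(x$per_replica_r),
              paste(sprintf("%.3f", x$per_replica_r), collapse = ", ")))
  cat(sprintf("  mean RMSF: prediction %.3f A, reference %.3f A\n",
              x$mean_pred_rmsf, x$mean_ref_rmsf))
  invisible(x)
}

#' Paired comparison of per-protein correlations between two methods
#'
#' Two-sided paired t-test on per-protein correlation values. When the
#' paired differences have zero variance the t statistic is undefined; by
#' convention the test then reports p = 1 for identical samples and p = 0
#' (statistic +/- Inf) for a constant non-zero difference, treating a
#' perfectly consistent shift as maximal evidence.
#'
#' @param rs_a,rs_b numeric vectors of correlations, paired by protein,
#'   equal length >= 3.
#' @return list with `statistic`, `p_value`, `df` and `mean_diff`.
#' @export
paired_comparison <- function(rs_a, rs_b) {
  if (length(rs_a) != length(rs_b) || length(rs_a) < 3L)
    abort_flex("paired samples must have equal length >= 3", "length_mismatch")
  dd <- rs_a - rs_b
  if (stats::sd(dd) == 0) {
    if (mean(dd) == 0)
      return(list(statistic = 0, p_value = 1, df = length(dd) - 1L, mean_diff = 0))
    return(list(statistic = sign(mean(dd)) * Inf, p_value = 0,
                df = length(dd) - 1L, mean_diff = mean(dd)))
  }
  t <- stats::t.test(rs_a, rs_b, paired = TRUE)
  list(statistic = unname(t$statistic), p_value = t$p.value,
       df = unname(t$parameter), mean_diff = unname(t$estimate))
}

#' Read an RMSF profile from 2-column text
#'
#' Whitespace-separated `residue rmsf` rows; `#` comments allowed.
#'
#' @param text character scalar.
#' @return an `RMSFProfile`.
#' @export
read_rmsf_profile <- function(text) {
  df <- tryCatch(
    utils::read.table(text = text, comment.char = "#",
                      col.names = c("residue", "rmsf")),
    error = function(e) abort_flex("malformed RMSF profile", "malformed_input"))
  if (any(df$rmsf < 0)) abort_flex("RMSF values must be >= 0", "range_error")
  structure(list(values = df$rmsf,
                 ids = data.frame(res_num = df$residue)), class = "RMSFProfile")
}

#' Write an RMSF profile as 2-column text
#'
#' @param profile an `RMSFProfile`.
#' @return character scalar.
#' @export
write_rmsf_profile <- function(profile) {
  res <- profile$ids$res_num %||% seq_along(profile$values)
  paste0(paste(c("# residue rmsf",
                 sprintf("%d %.4f", res, profile$values)), collapse = "\n"), "\n")
}
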