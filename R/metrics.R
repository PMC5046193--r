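# metrics: RMSE, residual SD, Pearson/Spearman correlations between predicted
# and measured affinities; heavy-atom pose RMSD (no superposition, no symmetry
# correction); redocking success rates; and the pose-error vs prediction-error
# correlation analysis.

.check_pair <- function(pred, meas) {
  if (length(pred) != length(meas))
    stop(sprintf("length mismatch: %d predictions vs %d measurements",
                 length(pred), length(meas)))
  if (!length(pred)) stop("empty input")
}

#' Root mean square error between predicted and measured affinities
#'
#' No linear fit is involved (unlike [sd_metric()]).
#'
#' @param pred,meas numeric vectors of equal length (pKd units).
#' @return RMSE in pKd units.
#' @export
rmse <- function(pred, meas) {
  .check_pair(pred, meas)
  sqrt(mean((pred - meas)^2))
}

#' Residual standard deviation of the measured-on-predicted regression
#'
#' Fits the simple linear model of measured on predicted affinity on the test
#' set and returns `sqrt(sum((fitted - meas)^2) / (N - 2))`.
#'
#' @param pred,meas numeric vectors of equal length, `N >= 3`; `pred` must not
#'   be constant.
#' @return SD in pKd units.
#' @export
sd_metric <- function(pred, meas) {
  .check_pair(pred, meas)
  n <- length(pred)
  if (n < 3) stop("sd_metric requires at least 3 points")
  vx <- sum((pred - mean(pred))^2)
  if (vx == 0) stop("sd_metric undefined for constant predictions")
  slope <- sum((pred - mean(pred)) * (meas - mean(meas))) / vx
  fitted <- mean(meas) + slope * (pred - mean(pred))
  sqrt(sum((fitted - meas)^2) / (n - 2))
}

#' Pearson correlation between predicted and measured affinities
#'
#' Computed from the product-moment form
#' `(N*sum(py) - sum(p)*sum(y)) / sqrt((N*sum(p^2) - sum(p)^2) * (N*sum(y^2) - sum(y)^2))`.
#'
#' @param pred,meas numeric vectors of equal length, `N >= 2`, both with
#'   nonzero variance.
#' @return correlation in `[-1, 1]`.
#' @export
rp <- function(pred, meas) {
  .check_pair(pred, meas)
  n <- length(pred)
  if (n < 2) stop("rp requires at least 2 points")
  num <- n * sum(pred * meas) - sum(pred) * sum(meas)
  den2 <- (n * sum(pred^2) - sum(pred)^2) * (n * sum(meas^2) - sum(meas)^2)
  if (den2 <= 0) stop("rp undefined: zero variance input")
  num / sqrt(den2)
}

#' Spearman rank correlation between predicted and measured affinities
#'
#' Pearson correlation of the rank vectors; ties receive average (mid) ranks.
#'
#' @param pred,meas numeric vectors of equal length, `N >= 2`, both with
#'   nonzero variance.
#' @return rank correlation in `[-1, 1]`.
#' @export
rs <- function(pred, meas) {
  .check_pair(pred, meas)
  rp(rank(pred, ties.method = "average"), rank(meas, ties.method = "average"))
}

#' Heavy-atom RMSD between two poses of the same ligand
#'
#' Plain coordinate root-mean-square deviation over heavy atoms in stored
#' order (docking convention: poses live in the same receptor frame, so no
#' superposition is applied; no symmetry-equivalent atom relabeling either,
#' which can overstate the error for topologically symmetric ligands).
#'
#' @param pose_a,pose_b [pose_record()]s with identical heavy-atom counts and
#'   atom correspondence by order.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(pose_a, pose_b) {
  a <- pose_a$atoms[pose_a$atoms$is_heavy, c("x", "y", "z"), drop = FALSE]
  b <- pose_b$atoms[pose_b$atoms$is_heavy, c("x", "y", "z"), drop = FALSE]
  if (nrow(a) != nrow(b))
    stop(sprintf("heavy-atom count mismatch: %d vs %d", nrow(a), nrow(b)))
  sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))
}

#' Redocking success rates of a set of pose sets
#'
#' A complex is a best-pose success when its best-scored docked pose has
#' RMSD strictly below `threshold` versus the crystal pose, and an any-pose
#' success when any docked pose does.
#'
#' @param pose_sets list of [pose_set()]s with crystal poses.
#' @param threshold success threshold in Angstrom (default 2).
#' @return list with `best_pose` and `any_pose` success fractions, plus the
#'   per-complex RMSD matrix entries used (`rmsds`, a list).
#' @export
success_rates <- function(pose_sets, threshold = 2) {
  rmsds <- lapply(pose_sets, function(ps) {
    if (is.null(ps$crystal)) stop("success_rates needs crystal poses")
    vapply(ps$docked, function(p) rmsd(ps$crystal, p), numeric(1))
  })
  best <- vapply(rmsds, function(r) r[1] < threshold, logical(1))
  any_ <- vapply(rmsds, function(r) any(r < threshold), logical(1))
  list(best_pose = mean(best), any_pose = mean(any_), rmsds = rmsds)
}

#' Build an evaluation report
#'
#' @param ids complex identifiers.
#' @param pred predicted affinities (pKd).
#' @param meas measured affinities (pKd).
#' @param pose_rmsd optional per-complex RMSD of the scored pose (Angstrom).
#' @return an `eval_report`: RMSE, SD, Rp, Rs plus a per-complex table with
#'   absolute errors, for the pose-error correlation analysis.
#' @export
eval_report <- function(ids, pred, meas, pose_rmsd = NA_real_) {
  .check_pair(pred, meas)
  structure(list(
    rmse = rmse(pred, meas), sd = sd_metric(pred, meas),
    rp = rp(pred, meas), rs = rs(pred, meas),
    per_complex = data.frame(
      id = ids, measured = meas, predicted = pred,
      abs_error = abs(pred - meas), rmsd = pose_rmsd,
      stringsAsFactors = FALSE)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: N=%d  RMSE=%.3f  SD=%.3f  Rp=%.3f  Rs=%.3f>\n",
              nrow(x$per_complex), x$rmse, x$sd, x$rp, x$rs))
  invisible(x)
}

#' Correlation between pose generation error and prediction error
#'
#' Pearson and Spearman correlations between each complex's docked-pose RMSD
#' and its absolute affinity prediction error.
#'
#' @param report an [eval_report()] whose per-complex table has `rmsd`.
#' @return list with `rp` and `rs`.
#' @export
error_rmsd_correlation <- function(report) {
  pc <- report$per_complex
  if (nrow(pc) < 3) stop("need at least 3 complexes")
  if (anyNA(pc$rmsd)) stop("report lacks per-complex pose RMSDs")
  list(rp = rp(pc$rmsd, pc$abs_error), rs = rs(pc$rmsd, pc$abs_error))
}
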