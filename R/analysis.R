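#' Least-squares superposition of two structures
#'
#' Optimal rigid-body fit (rotation + translation, proper rotation
#' enforced) of the mobile C-alpha trace onto the target, computed via
#' `bio3d::fit.xyz()`. The returned RMSD is the minimized C-alpha RMSD in
#' Angstrom, the convention structure-comparison scores are reported in.
#'
#' @param mobile,target [structure_model()]s with matching residue counts
#'   (>= 3 residues).
#' @return A `superposition` list: `fitted` (the mobile model moved onto
#'   the target, nm), `rmsd` (Angstrom), and per-residue `displacement`
#'   (Angstrom).
#' @examples
#' m <- make_folded_fixture(12, "helix", seed = 1)
#' superpose(m, m)$rmsd  # 0
#' @export
superpose <- function(mobile, target) {
  mobile <- as_structure_model(mobile)
  target <- as_structure_model(target)
  if (nrow(mobile) != nrow(target)) {
    abort("mobile and target must have the same number of residues.")
  }
  if (nrow(mobile) < 3) abort("need at least 3 residues to superpose.")
  fit <- suppressWarnings(bio3d::fit.xyz(
    fixed = xyz_flat_ang(target), mobile = xyz_flat_ang(mobile)))
  co <- matrix(as.numeric(fit), ncol = 3, byrow = TRUE)
  disp <- sqrt(rowSums((co - coords_matrix(target) * 10)^2))
  structure(list(
    fitted = structure_model(co / 10, res_id = mobile$res_id,
                             res_name = mobile$res_name,
                             label = attr(mobile, "label")),
    rmsd = sqrt(mean(disp^2)),
    displacement = disp
  ), class = "superposition")
}

#' Per-frame RMSD of a trajectory against a target
#'
#' Each frame is independently superposed onto the target; the score
#' series carries the ensemble temperature of the trajectory.
#'
#' @param traj A `trajectory_ensemble`.
#' @param target Target [structure_model()].
#' @param label Scenario label attached to the series.
#' @return A `score_series` tibble: `frame`, `time_ns`, `value`
#'   (RMSD, Angstrom), with attributes `scenario` and `temperature`.
#' @export
rmsd_series <- function(traj, target, label = "scenario") {
  frames <- trajectory_frames(traj)
  times <- dplyr::distinct(as_tibble(traj), .data$frame, .data$time_ns)
  vals <- unname(purrr::map_dbl(frames, ~superpose(.x, target)$rmsd))
  ord <- order(times$frame) # frames list is already in ascending frame order
  out <- tibble(frame = times$frame[ord], time_ns = times$time_ns[ord],
                value = vals)
  attr(out, "scenario") <- label
  attr(out, "temperature") <- attr(traj, "temperature")
  class(out) <- unique(c("score_series", class(tibble())))
  out
}

#' RMSD heatmap over replicas and time
#'
#' Stacks per-temperature RMSD series into the time-by-replica matrix the
#' replica overview heatmaps display, ordered by replica temperature.
#'
#' @param series_list List of `score_series` (one per temperature slot,
#'   low to high), e.g. from [rmsd_series()] on each [slot_trajectory()].
#' @return An `rmsd_heatmap` tibble: `replica`, `temperature`, `frame`,
#'   `time_ns`, `rmsd`.
#' @export
rmsd_heatmap <- function(series_list) {
  rows <- purrr::imap(series_list, function(s, i) {
    idx <- as.integer(i)
    tibble(replica = idx - 1L,
           temperature = attr(s, "temperature") %||% NA_real_,
           frame = s$frame, time_ns = s$time_ns, rmsd = s$value)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- unique(c("rmsd_heatmap", class(tibble())))
  out
}

#' Global Distance Test scores
#'
#' After a single global least-squares superposition, the per-residue
#' C-alpha displacement d_i is compared against the 20-cutoff schedule
#' 0.5, 1.0, ..., 10.0 Angstrom; P_x is the percentage of residues with
#' d_i <= x. The total score is GDT_TS = (P1 + P2 + P4 + P8) / 4 and the
#' high-accuracy score GDT_HA = (P0.5 + P1 + P2 + P4) / 4, both in
#' \[0, 100\]. A single global fit is used (not the iterative
#' maximal-subset search of CASP's LGA program), so scores for poor
#' models are slightly conservative.
#'
#' @inheritParams superpose
#' @return A `gdt_result` list: `cutoffs` tibble (`cutoff`, `fraction`),
#'   `ts`, `ha`, and the residue `displacement`s (Angstrom).
#' @examples
#' m <- make_folded_fixture(12, "helix", seed = 1)
#' gdt(m, m)$ts  # 100
#' @export
gdt <- function(mobile, target) {
  sup <- superpose(mobile, target)
  d <- sup$displacement
  cutoffs <- remd_defaults()$gdt_cutoffs_ang
  frac <- purrr::map_dbl(cutoffs, ~100 * mean(d <= .x))
  px <- stats::setNames(frac, format(cutoffs))
  p <- function(x) frac[match(x, cutoffs)]
  structure(list(
    cutoffs = tibble(cutoff = cutoffs, fraction = frac),
    ts = mean(c(p(1), p(2), p(4), p(8))),
    ha = mean(c(p(0.5), p(1), p(2), p(4))),
    displacement = d,
    rmsd = sup$rmsd
  ), class = "gdt_result")
}

#' @export
print.gdt_result <- function(x, ...) {
  cat(sprintf("<gdt_result> GDT_TS = %.2f, GDT_HA = %.2f (RMSD %.2f A)\n",
              x$ts, x$ha, x$rmsd))
  invisible(x)
}

#' Per-frame GDT scores of a trajectory
#'
#' @inheritParams rmsd_series
#' @return A tibble: `frame`, `time_ns`, `ts`, `ha`.
#' @export
gdt_series <- function(traj, target, label = "scenario") {
  frames <- trajectory_frames(traj)
  times <- dplyr::distinct(as_tibble(traj), .data$frame, .data$time_ns)
  res <- purrr::map(frames, gdt, target = target)
  ord <- order(times$frame) # frames list is already in ascending frame order
  out <- tibble(frame = times$frame[ord], time_ns = times$time_ns[ord],
                ts = unname(purrr::map_dbl(res, "ts")),
                ha = unname(purrr::map_dbl(res, "ha")))
  attr(out, "scenario") <- label
  attr(out, "temperature") <- attr(traj, "temperature")
  out
}

#' Topological accuracy call from a GDT total score
#'
#' A model is considered topologically accurate for GDT_TS strictly
#' above 50.
#'
#' @param ts GDT_TS score(s).
#' @return `"accurate"` or `"inaccurate"`, vectorized.
#' @export
classify_topology <- function(ts) {
  ifelse(ts > 50, "accurate", "inaccurate")
}
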