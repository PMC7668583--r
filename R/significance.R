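#' Nearest-rank percentiles of score series
#'
#' Computes per-scenario percentiles of GDT (or any) scores at the
#' requested levels using the nearest-rank (lower) method
#' (`stats::quantile(type = 1)`), so every reported percentile is a score
#' actually attained by some frame.
#'
#' @param scores Tibble with at least columns `scenario` and `value`; an
#'   optional `score` column (e.g. `"TS"` / `"HA"`) keeps score variants
#'   apart.
#' @param probs Percentile levels, in percent (default 80, 85, 90, 95,
#'   100).
#' @return Tibble: `scenario`, (`score`,) `pct`, `value`.
#' @export
gdt_percentiles <- function(scores, probs = c(80, 85, 90, 95, 100)) {
  if (!all(c("scenario", "value") %in% names(scores))) {
    abort("`scores` needs columns scenario and value.")
  }
  if (any(!is.finite(scores$value))) abort("scores must be finite.")
  keys <- intersect(c("scenario", "score"), names(scores))
  dplyr::reframe(
    dplyr::group_by(scores, dplyr::across(dplyr::all_of(keys))),
    pct = probs,
    value = stats::quantile(.data$value, probs / 100, type = 1, names = FALSE)
  )
}

#' Shaded / bold significance flags for percentile tables
#'
#' Applies the two-rule significance classification used for the
#' benchmark percentile tables: a scenario percentile P_x is *shaded*
#' when it is at least the reference percentile (P_x >= P_x,ref), and
#' *bold* (significantly greater) when it closes at least a fraction `w`
#' of the remaining headroom of the reference,
#' P_x >= P_x,ref + w (P_100,ref - P_x,ref), with w = 0.5 by default.
#' Both comparisons are inclusive. The reference row itself is exempt
#' from flagging.
#'
#' @param pct_tbl Percentile tibble from [gdt_percentiles()] (columns
#'   `scenario`, optional `score`, `pct`, `value`).
#' @param reference Scenario label of the reference row.
#' @param w Significance weight in \[0, 1\].
#' @return `pct_tbl` with logical columns `shaded` and `bold` and a
#'   `threshold` column (the bold cutoff).
#' @export
flag_significance <- function(pct_tbl, reference = "ref",
                              w = remd_defaults()$significance_w) {
  if (!reference %in% pct_tbl$scenario) {
    abort(sprintf("reference scenario '%s' not present.", reference))
  }
  keys <- intersect(c("score", "pct"), names(pct_tbl))
  ref <- pct_tbl[pct_tbl$scenario == reference, , drop = FALSE]
  ref_max <- ref[ref$pct == 100, c(setdiff(keys, "pct"), "value")]
  names(ref_max)[names(ref_max) == "value"] <- "ref_p100"
  ref <- ref[, c(keys, "value")]
  names(ref)[names(ref) == "value"] <- "ref_value"
  out <- dplyr::left_join(pct_tbl, ref, by = keys)
  out <- if (length(setdiff(keys, "pct")) > 0) {
    dplyr::left_join(out, ref_max, by = setdiff(keys, "pct"))
  } else {
    dplyr::mutate(out, ref_p100 = ref_max$ref_p100[1])
  }
  out <- dplyr::mutate(out,
    threshold = .data$ref_value + w * (.data$ref_p100 - .data$ref_value),
    shaded = .data$scenario != reference & .data$value >= .data$ref_value,
    bold = .data$scenario != reference & .data$value >= .data$threshold)
  cls <- class(pct_tbl)
  out <- out[, c(setdiff(names(pct_tbl), c("ref_value", "ref_p100")),
                 "threshold", "shaded", "bold")]
  class(out) <- unique(c("percentile_table", cls, class(tibble())))
  out
}

#' Percentile significance table from raw score series
#'
#' Composes [gdt_percentiles()] and [flag_significance()]: from per-frame
#' GDT scores of several scenarios (including the unbiased reference)
#' to the shaded/bold percentile table.
#'
#' @inheritParams gdt_percentiles
#' @inheritParams flag_significance
#' @return A `percentile_table` tibble.
#' @examples
#' scores <- tibble::tibble(
#'   scenario = rep(c("ref", "biased"), each = 20),
#'   value = c(seq(40, 97, 3), seq(70, 127, 3)))
#' percentile_table(scores, reference = "ref")
#' @export
percentile_table <- function(scores, reference = "ref",
                             w = remd_defaults()$significance_w,
                             probs = c(80, 85, 90, 95, 100)) {
  flag_significance(gdt_percentiles(scores, probs), reference, w)
}

#' Export a percentile table in wide benchmark layout
#'
#' One row per scenario, columns `P<score><pct>` plus shaded/bold masks
#' encoded as strings of `.`/`s`/`b` per column, mirroring how the
#' benchmark tables are printed.
#'
#' @param ptable A `percentile_table` (needs a `score` column).
#' @param path Optional CSV output path.
#' @return The wide tibble (invisibly if `path` is given).
#' @export
write_percentile_table <- function(ptable, path = NULL) {
  stopifnot("score" %in% names(ptable))
  wide <- tidyr::pivot_wider(
    dplyr::mutate(ptable, col = sprintf("P%s%d", .data$score, .data$pct)),
    id_cols = "scenario", names_from = "col", values_from = "value")
  mask <- dplyr::summarise(
    dplyr::group_by(ptable, .data$scenario),
    shaded_mask = paste(ifelse(.data$shaded, "s", "."), collapse = ""),
    bold_mask = paste(ifelse(.data$bold, "b", "."), collapse = ""))
  out <- dplyr::left_join(wide, mask, by = "scenario")
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Enrichment/depletion histogram between two score series
#'
#' Per-bin count difference Delta N = N_scenario - N_ref between a biased
#' scenario and the unbiased reference at the same temperature: positive
#' bins mark conformations the bias enriched, negative bins depleted
#' ones. The total of `delta_n` always equals the difference of series
#' lengths (zero for the equal-length series the comparison is designed
#' for).
#'
#' @param scenario,reference Numeric score vectors (e.g. per-frame RMSD,
#'   Angstrom) or `score_series` tibbles.
#' @param bin_width Bin width in the score unit (default 0.2).
#' @param bin_edges Optional explicit bin edges spanning both series.
#' @param truncate If `TRUE`, unequal-length series are truncated to the
#'   shorter; otherwise unequal lengths are an error.
#' @return A `delta_histogram` tibble: `bin_lo`, `bin_hi`, `mid`,
#'   `n_scenario`, `n_reference`, `delta_n`.
#' @export
delta_histogram <- function(scenario, reference, bin_width = 0.2,
                            bin_edges = NULL, truncate = FALSE) {
  sx <- if (is.data.frame(scenario)) scenario$value else scenario
  rx <- if (is.data.frame(reference)) reference$value else reference
  if (length(sx) != length(rx)) {
    if (!truncate) {
      abort(sprintf(paste0(
        "series lengths differ (%d vs %d); equal-length trajectories are ",
        "compared — set truncate = TRUE to clip to the shorter."),
        length(sx), length(rx)))
    }
    len <- min(length(sx), length(rx))
    sx <- sx[seq_len(len)]
    rx <- rx[seq_len(len)]
  }
  if (is.null(bin_edges)) {
    top <- max(sx, rx)
    bin_edges <- seq(0, bin_width * ceiling(top / bin_width + 1e-9),
                     by = bin_width)
  }
  if (min(sx, rx) < min(bin_edges) || max(sx, rx) > max(bin_edges)) {
    abort("bin edges must span both series.")
  }
  cs <- graphics::hist(sx, breaks = bin_edges, plot = FALSE)$counts
  cr <- graphics::hist(rx, breaks = bin_edges, plot = FALSE)$counts
  out <- tibble(
    bin_lo = utils::head(bin_edges, -1), bin_hi = bin_edges[-1],
    mid = (utils::head(bin_edges, -1) + bin_edges[-1]) / 2,
    n_scenario = cs, n_reference = cr, delta_n = cs - cr)
  class(out) <- unique(c("delta_histogram", class(tibble())))
  out
}

#' Local accuracy of the best frames of a trajectory
#'
#' Ranks frames by GDT_HA (descending), keeps the top `n_top`, and for
#' each reports the per-residue C-alpha displacement after the
#' least-squares fit, binned into distance classes (default edges 1, 2,
#' 4, 8 Angstrom, i.e. classes <1, 1-2, 2-4, 4-8, >8).
#'
#' @inheritParams rmsd_series
#' @param n_top Number of top-ranked frames to keep.
#' @param class_edges Distance class edges, Angstrom, increasing.
#' @return A `local_accuracy` tibble: `rank`, `frame`, `ha`, `res_id`,
#'   `displacement` (Angstrom), `class` (0-based class index).
#' @export
local_accuracy <- function(traj, target, n_top = 10,
                           class_edges = c(1, 2, 4, 8)) {
  if (is.unsorted(class_edges, strictly = TRUE)) {
    abort("`class_edges` must be strictly increasing.")
  }
  frames <- trajectory_frames(traj)
  res <- purrr::map(frames, gdt, target = target)
  ha <- unname(purrr::map_dbl(res, "ha"))
  frame_ids <- sort(unique(traj$frame))
  ord <- order(ha, decreasing = TRUE)[seq_len(min(n_top, length(ha)))]
  rows <- purrr::imap(ord, function(fidx, rank) {
    d <- res[[fidx]]$displacement
    tibble(rank = as.integer(rank), frame = frame_ids[fidx],
           ha = ha[fidx], res_id = frames[[fidx]]$res_id,
           displacement = d,
           class = findInterval(d, class_edges))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "class_edges") <- class_edges
  class(out) <- unique(c("local_accuracy", class(tibble())))
  out
}

#' Load a printed GDT percentile benchmark table
#'
#' Reads a wide benchmark CSV (columns `method`, `tpr`, `n_cp`,
#' `PTS80..PHA100` and, optionally, printed `bold_*` mask columns) into
#' the long format [flag_significance()] consumes. Two such tables — the
#' 20-residue Trp-Cage and 35-residue villin-headpiece benchmarks — ship
#' with the package under `inst/extdata/`.
#'
#' @param path CSV path, e.g.
#'   `system.file("extdata", "trp_cage_gdt_percentiles.csv",
#'   package = "remdguide")`.
#' @param method Keep only rows of this method (default `"REMD"`, the
#'   ensemble the significance rules are defined against); use `NULL`
#'   for all rows.
#' @return Long tibble: `scenario`, `method`, `tpr`, `n_cp`, `score`,
#'   `pct`, `value` and (if present) `printed_bold`.
#' @export
read_printed_percentiles <- function(path, method = "REMD") {
  wide <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(method)) wide <- wide[wide$method %in% method, , drop = FALSE]
  # the REMD reference row is the reference of the significance rules;
  # the MD rows are ordinary scenarios compared against it
  wide$scenario <- ifelse(wide$method == "REMD" & wide$tpr == "ref", "ref",
                          sprintf("%s_tpr%s_cp%s", wide$method, wide$tpr,
                                  wide$n_cp))
  val_cols <- grep("^P(TS|HA)\\d+$", names(wide), value = TRUE)
  long <- tidyr::pivot_longer(
    wide[, c("scenario", "method", "tpr", "n_cp", val_cols)],
    dplyr::all_of(val_cols), names_to = "col", values_to = "value")
  long$score <- sub("^P(TS|HA)\\d+$", "\\1", long$col)
  long$pct <- as.integer(sub("^P(TS|HA)(\\d+)$", "\\2", long$col))
  bold_cols <- grep("^bold_", names(wide), value = TRUE)
  if (length(bold_cols) > 0) {
    boldl <- tidyr::pivot_longer(
      wide[, c("scenario", bold_cols)], dplyr::all_of(bold_cols),
      names_to = "col", values_to = "printed_bold")
    boldl$col <- sub("^bold_", "", boldl$col)
    long <- dplyr::left_join(long, boldl, by = c("scenario", "col"))
    long$printed_bold <- long$printed_bold == 1
  }
  long$col <- NULL
  as_tibble(long[, c("scenario", "method", "tpr", "n_cp", "score", "pct",
                     "value", intersect("printed_bold", names(long)))])
}
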