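#' Tidy a GDT result
#'
#' One row per cutoff with the fraction of residues within it.
#'
#' @param x A `gdt_result`.
#' @param ... Unused.
#' @return A tibble: `cutoff` (Angstrom), `fraction` (percent).
#' @export
tidy.gdt_result <- function(x, ...) {
  x$cutoffs
}

#' @rdname tidy.gdt_result
#' @return `glance()`: a one-row tibble with `ts`, `ha`, `rmsd` and the
#'   topology call.
#' @export
glance.gdt_result <- function(x, ...) {
  tibble(ts = x$ts, ha = x$ha, rmsd = x$rmsd,
         topology = classify_topology(x$ts))
}

#' Tidy an REMD run
#'
#' `tidy()` returns the exchange log (one row per attempted swap);
#' `glance()` summarises acceptance per adjacent temperature pair and
#' overall.
#'
#' @param x A `remd_run` from [run_remd()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.remd_run <- function(x, ...) {
  as_tibble(x$exchanges)
}

#' @rdname tidy.remd_run
#' @export
glance.remd_run <- function(x, ...) {
  ex <- x$exchanges
  if (nrow(ex) == 0) {
    return(tibble(n_replicas = nrow(x$ladder), n_attempts = 0L,
                  n_accepted = 0L, acceptance = NA_real_))
  }
  tibble(n_replicas = nrow(x$ladder), n_attempts = nrow(ex),
         n_accepted = sum(ex$accepted), acceptance = mean(ex$accepted))
}

#' Per-pair exchange statistics of an REMD run
#'
#' @param run A `remd_run`.
#' @return Tibble: `slot_lo`, `slot_hi`, `attempts`, `accepted`, `rate`.
#' @export
exchange_statistics <- function(run) {
  ex <- run$exchanges
  if (nrow(ex) == 0) {
    return(tibble(slot_lo = integer(), slot_hi = integer(),
                  attempts = integer(), accepted = integer(),
                  rate = numeric()))
  }
  dplyr::summarise(
    dplyr::group_by(ex, .data$slot_lo, .data$slot_hi),
    attempts = dplyr::n(), accepted = sum(.data$accepted),
    rate = mean(.data$accepted), .groups = "drop")
}
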