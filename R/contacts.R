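#' Native contacts of a reference structure
#'
#' A residue pair (i, j) is a native contact when the reference C-alpha
#' distance r_ij is at most the cutoff (default 0.6 nm) and the sequence
#' separation |i - j| is at least `min_sep` (default 4), excluding
#' near-diagonal pairs that are trivially close through chain
#' connectivity.
#'
#' @param ref A [structure_model()] (the native/reference state).
#' @param cutoff Contact distance cutoff, nm.
#' @param min_sep Minimum sequence separation.
#' @return Tibble of contact pairs: `i`, `j` (i < j), `label`
#'   (`"native"`), `r_ref` (reference distance, nm), sorted by (i, j).
#' @examples
#' native_contacts(make_folded_fixture(20, "helix_loop_helix", seed = 1))
#' @export
native_contacts <- function(ref, cutoff = remd_defaults()$contact_cutoff_nm,
                            min_sep = remd_defaults()$min_seq_sep) {
  pairs <- all_pairs(ref, min_sep)
  out <- dplyr::filter(pairs, .data$r_ref <= cutoff)
  out$label <- rep("native", nrow(out))
  dplyr::arrange(out[, c("i", "j", "label", "r_ref")], .data$i, .data$j)
}

# every (i, j) pair with i < j and |i - j| >= min_sep, with reference distance
all_pairs <- function(ref, min_sep) {
  ref <- as_structure_model(ref)
  co <- coords_matrix(ref)
  n <- nrow(co)
  if (n < min_sep + 1) {
    return(tibble(i = integer(), j = integer(), r_ref = numeric()))
  }
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  ii <- ref$res_id[idx[, 1]]
  jj <- ref$res_id[idx[, 2]]
  keep <- abs(jj - ii) >= min_sep
  ii <- ii[keep]; jj <- jj[keep]
  ri <- idx[keep, 1]; rj <- idx[keep, 2]
  d <- sqrt(rowSums((co[ri, , drop = FALSE] - co[rj, , drop = FALSE])^2))
  tibble(i = pmin(ii, jj), j = pmax(ii, jj), r_ref = d)
}

#' Non-native candidate contacts
#'
#' All pairs with sequence separation >= `min_sep` that are neither native
#' contacts nor contact-map neighbors of a native contact: for each
#' native pair (i, j) every combination (i', j') with i' in {i-1, i, i+1}
#' and j' in {j-1, j, j+1} — up to nine cells — is excluded, so that
#' "non-native" restraints are not accidental near-hits.
#'
#' @inheritParams native_contacts
#' @return Tibble of candidate pairs with `label = "non_native"`.
#' @export
nonnative_candidates <- function(ref,
                                 cutoff = remd_defaults()$contact_cutoff_nm,
                                 min_sep = remd_defaults()$min_seq_sep) {
  pairs <- all_pairs(ref, min_sep)
  nat <- native_contacts(ref, cutoff, min_sep)
  excl <- neighbor_cells(nat)
  out <- dplyr::anti_join(pairs, excl, by = c("i", "j"))
  out$label <- rep("non_native", nrow(out))
  dplyr::arrange(out[, c("i", "j", "label", "r_ref")], .data$i, .data$j)
}

# the native cells plus their nine neighbor combinations, canonicalized i < j
neighbor_cells <- function(native) {
  if (nrow(native) == 0) return(tibble(i = integer(), j = integer()))
  grid <- tidyr::expand_grid(di = -1:1, dj = -1:1)
  cells <- tidyr::expand_grid(native[, c("i", "j")], grid)
  ip <- cells$i + cells$di
  jp <- cells$j + cells$dj
  dplyr::distinct(tibble(i = pmin(ip, jp), j = pmax(ip, jp)))
}

#' Sample a restraint set at a controlled true-positive rate
#'
#' Draws `round(tpr * n_total)` native contacts (half-up rounding, so a
#' 75% TPR set of 12 pairs holds 9 native + 3 non-native) and fills the
#' remainder with non-native candidates, each uniformly without
#' replacement. The draw is deterministic given `seed`, which is recorded
#' on the result for provenance.
#'
#' @param native,nonnative Contact tibbles from [native_contacts()] /
#'   [nonnative_candidates()].
#' @param n_total Total number of contact pairs to restrain.
#' @param tpr Nominal true-positive rate in \[0, 1\].
#' @param seed Integer RNG seed.
#' @param source Label of the structure the pools came from.
#' @return A `restraint_set` tibble (columns as the inputs) with
#'   attributes `tpr_nominal`, `seed`, `source`.
#' @examples
#' ref <- make_folded_fixture(20, "helix_loop_helix", seed = 1)
#' select_restraints(native_contacts(ref), nonnative_candidates(ref),
#'                   n_total = 8, tpr = 0.75, seed = 42)
#' @export
select_restraints <- function(native, nonnative, n_total, tpr, seed = 1,
                              source = "reference") {
  if (tpr < 0 || tpr > 1) abort("`tpr` must be within [0, 1].")
  n_total <- as.integer(n_total)
  n_nat <- round_half_up(tpr * n_total)
  n_non <- n_total - n_nat
  if (n_nat > nrow(native)) {
    abort(sprintf("requested %d native contacts but only %d available.",
                  n_nat, nrow(native)))
  }
  if (n_non > nrow(nonnative)) {
    abort(sprintf("requested %d non-native contacts but only %d available.",
                  n_non, nrow(nonnative)))
  }
  picked <- with_seed(seed, {
    nat <- native[sample.int(nrow(native), n_nat), , drop = FALSE]
    non <- nonnative[sample.int(nrow(nonnative), n_non), , drop = FALSE]
    dplyr::bind_rows(nat, non)
  })
  out <- dplyr::arrange(picked, .data$label, .data$i, .data$j)
  attr(out, "tpr_nominal") <- tpr
  attr(out, "seed") <- as.integer(seed)
  attr(out, "source") <- source
  class(out) <- unique(c("restraint_set", class(tibble())))
  out
}

round_half_up <- function(x) as.integer(floor(x + 0.5))

#' The bias-quality scenario grid
#'
#' The 14 benchmark scenarios of the performance study: an unbiased
#' reference plus every combination of true-positive rate
#' \{100, 75, 50\}% with \{6 (100% only), 12, 24, 36, 48\} contact pairs,
#' with their implied native / non-native counts.
#'
#' @return Tibble with columns `scenario`, `tpr`, `n_cp`, `n_native`,
#'   `n_nonnative`.
#' @export
scenario_grid <- function() {
  grid <- dplyr::bind_rows(
    tibble(tpr = NA_real_, n_cp = 0L),
    tidyr::expand_grid(tpr = 1, n_cp = c(6L, 12L, 24L, 36L, 48L)),
    tidyr::expand_grid(tpr = c(0.75, 0.5), n_cp = c(12L, 24L, 36L, 48L))
  )
  dplyr::mutate(grid,
    n_native = ifelse(is.na(.data$tpr), 0L,
                      round_half_up(.data$tpr * .data$n_cp)),
    n_nonnative = .data$n_cp - .data$n_native,
    scenario = ifelse(is.na(.data$tpr), "ref",
                      sprintf("tpr%03.0f_cp%02d", 100 * .data$tpr, .data$n_cp)),
    .before = 1
  )[, c("scenario", "tpr", "n_cp", "n_native", "n_nonnative")]
}

#' @rdname scenario_grid
#' @inheritParams native_contacts
#' @inheritParams select_restraints
#' @param n_cp Number of contact pairs for the scenario.
#' @export
build_scenario <- function(ref, tpr, n_cp, seed = 1,
                           cutoff = remd_defaults()$contact_cutoff_nm,
                           min_sep = remd_defaults()$min_seq_sep) {
  nat <- native_contacts(ref, cutoff, min_sep)
  non <- nonnative_candidates(ref, cutoff, min_sep)
  select_restraints(nat, non, n_total = n_cp,
                    tpr = if (is.na(tpr)) 0 else tpr, seed = seed,
                    source = attr(ref, "label") %||% "reference")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Boolean contact map
#'
#' Symmetric residue-by-residue matrix, TRUE where the C-alpha distance is
#' at or below `cutoff`; the diagonal band |i - j| < `min_sep` is masked
#' FALSE.
#'
#' @inheritParams native_contacts
#' @return Logical matrix with residue ids as dimnames.
#' @export
contact_map <- function(ref, cutoff = remd_defaults()$contact_cutoff_nm,
                        min_sep = remd_defaults()$min_seq_sep) {
  ref <- as_structure_model(ref)
  co <- coords_matrix(ref)
  d <- as.matrix(stats::dist(co))
  sep <- abs(outer(ref$res_id, ref$res_id, "-"))
  map <- d <= cutoff & sep >= min_sep
  dimnames(map) <- list(ref$res_id, ref$res_id)
  map
}

#' Read and write restraint files
#'
#' Plain CSV with header `i,j,label,r_ref_nm`; the selection seed and
#' nominal TPR travel in `# key: value` comment lines so a restraint file
#' is self-documenting.
#'
#' @param restraints A restraint/contact tibble.
#' @param path File path.
#' @return `write_restraints()`: `path`, invisibly. `read_restraints()`:
#'   a restraint tibble.
#' @export
write_restraints <- function(restraints, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tpr_nominal: %s",
                     attr(restraints, "tpr_nominal") %||% NA), con)
  writeLines(sprintf("# seed: %s", attr(restraints, "seed") %||% NA), con)
  writeLines("i,j,label,r_ref_nm", con)
  writeLines(sprintf("%d,%d,%s,%.6f", restraints$i, restraints$j,
                     restraints$label, restraints$r_ref), con)
  invisible(path)
}

#' @rdname write_restraints
#' @export
read_restraints <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  tab <- utils::read.csv(text = lines[!grepl("^#", lines)])
  out <- tibble(i = as.integer(tab$i), j = as.integer(tab$j),
                label = tab$label, r_ref = tab$r_ref_nm)
  seed <- sub("^# seed: ", "", grep("^# seed:", meta, value = TRUE))
  tpr <- sub("^# tpr_nominal: ", "", grep("^# tpr_nominal:", meta, value = TRUE))
  attr(out, "seed") <- suppressWarnings(as.integer(seed)[1])
  attr(out, "tpr_nominal") <- suppressWarnings(as.numeric(tpr)[1])
  class(out) <- unique(c("restraint_set", class(tibble())))
  out
}
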