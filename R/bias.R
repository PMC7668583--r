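#' Sigmoid bias potential parameters
#'
#' The contact restraint potential is V(r) = k * sigma(r) with the
#' logistic sigma(r) = A / (1 + exp(-alpha (r - r0))). With the defaults
#' (A = 1, alpha = 2.5 / nm, r0 = 1.6 nm, k = 10 kJ/mol, about 4 kT at
#' 300 K) the potential is attractive and short-ranged: the force peaks at
#' r0 and is negligible beyond about 2 r0 = 3.2 nm, which bounds the
#' damage a false-positive restraint can do. The well depth at the
#' native-contact distance 0.6 nm is on the order of a hydrogen bond.
#'
#' @param A Dimensionless plateau of the sigmoid (> 0).
#' @param alpha Steepness, 1/nm (> 0).
#' @param r0 Inflection distance, nm (> 0); the force maximum sits here.
#' @param k Force coefficient, kJ/mol (>= 0).
#' @return A `sigmoid_params` list.
#' @examples
#' p <- sigmoid_params()
#' sigmoid_energy(p$r0, p)  # half the plateau: k*A/2
#' @export
sigmoid_params <- function(A = 1, alpha = 2.5, r0 = 1.6, k = 10) {
  if (A <= 0 || alpha <= 0 || r0 <= 0 || k < 0) {
    abort("need A > 0, alpha > 0, r0 > 0, k >= 0.")
  }
  structure(list(A = A, alpha = alpha, r0 = r0, k = k),
            class = "sigmoid_params")
}

#' Sigmoid restraint energy and force
#'
#' `sigmoid_energy()` evaluates V(r) = k * A * plogis(alpha (r - r0)) in
#' kJ/mol; it is strictly increasing in r (pulling the pair together) and
#' bounded by the plateau k * A. `sigmoid_force()` returns the magnitude
#' of the attractive force |dV/dr| = k A alpha p (1 - p) in kJ/mol/nm; the
#' signed radial force on the pair is -dV/dr (inward). The logistic is
#' evaluated through `stats::plogis()`, which is stable for large
#' |alpha (r - r0)|.
#'
#' @param r Distance(s), nm (>= 0); vectorized.
#' @param params A [sigmoid_params()].
#' @return Numeric vector, kJ/mol (`sigmoid_energy`) or kJ/mol/nm
#'   (`sigmoid_force`).
#' @export
sigmoid_energy <- function(r, params = sigmoid_params()) {
  check_r(r)
  params$k * params$A * stats::plogis(params$alpha * (r - params$r0))
}

#' @rdname sigmoid_energy
#' @export
sigmoid_force <- function(r, params = sigmoid_params()) {
  check_r(r)
  p <- stats::plogis(params$alpha * (r - params$r0))
  params$k * params$A * params$alpha * p * (1 - p)
}

check_r <- function(r) {
  if (any(r < 0)) abort("distances must be non-negative.")
  invisible(r)
}

#' Tabulate the sigmoid potential on a uniform grid
#'
#' Produces the three columns an MD engine's tabulated bonded interaction
#' expects: distance, energy, and negative derivative (-dV/dr, i.e. the
#' signed radial force). The grid starts at 0. With the default spacing of
#' 0.002 nm, linear interpolation of the table reproduces the closed form
#' within 1e-6 kJ/mol.
#'
#' The table stores V(r) = k * A * sigma(r) for the `params` given. The
#' GROMACS convention — table holds the unit-strength sigma(r) and the
#' per-pair coefficient k sits on the interaction line — is obtained by
#' tabulating with `k = 1` and passing the real k to [patch_topology()].
#'
#' @param params A [sigmoid_params()].
#' @param r_max Upper end of the grid, nm (> r0).
#' @param spacing Grid spacing, nm.
#' @return A `tabulated_potential` tibble with columns `r`, `energy`,
#'   `neg_deriv`.
#' @export
tabulate_potential <- function(params = sigmoid_params(), r_max = 6,
                               spacing = 0.002) {
  if (spacing <= 0) abort("`spacing` must be positive.")
  if (spacing >= r_max) abort("`spacing` must be smaller than `r_max`.")
  if (r_max <= params$r0) abort("`r_max` must exceed the inflection r0.")
  r <- seq(0, r_max, by = spacing)
  out <- tibble(
    r = r,
    energy = sigmoid_energy(r, params),
    neg_deriv = -sigmoid_force(r, params)
  )
  attr(out, "params") <- params
  class(out) <- unique(c("tabulated_potential", class(tibble())))
  out
}

#' Engine-ready table files
#'
#' `write_table_file()` writes a tabulated potential in the three-column
#' whitespace dialect of GROMACS tabulated-bond files (`table_b<N>.xvg`):
#' `#` comment header, then fixed-decimal `r energy neg_deriv` rows.
#' `read_table_file()` reads it back.
#'
#' @param table A `tabulated_potential` from [tabulate_potential()].
#' @param path Output path.
#' @return `path` invisibly; `read_table_file()` returns the table tibble.
#' @export
write_table_file <- function(table, path) {
  p <- attr(table, "params")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# remdguide sigmoid restraint table",
    if (!is.null(p)) sprintf("# A=%g alpha=%g r0=%g k=%g", p$A, p$alpha,
                             p$r0, p$k),
    "# columns: r_nm  energy_kJ_mol  minus_dV_dr"
  ), con)
  writeLines(sprintf("%12.6f %18.10e %18.10e",
                     table$r, table$energy, table$neg_deriv), con)
  invisible(path)
}

#' @rdname write_table_file
#' @export
read_table_file <- function(path) {
  lines <- readLines(path)
  tab <- utils::read.table(text = lines[!grepl("^#", lines)],
                           col.names = c("r", "energy", "neg_deriv"))
  out <- as_tibble(tab)
  class(out) <- unique(c("tabulated_potential", class(tibble())))
  out
}

#' Patch a topology with tabulated restraint bonds
#'
#' Appends one tabulated-bond line per restrained pair to the
#' `[ bonds ]` section of a GROMACS-dialect topology: columns
#' `ai aj funct table_index k`, function type 9 (tabulated bond that does
#' not connect the atoms, the standard choice for restraints). Atom
#' indices are resolved from the topology's `[ atoms ]` section by
#' matching the CA atom of each restrained residue; all other topology
#' text is left byte-identical.
#'
#' @param topology_text Character vector of topology lines.
#' @param restraints Restraint tibble (columns `i`, `j`).
#' @param table_index Index N of the `table_b<N>.xvg` file.
#' @param k Force coefficient placed on each interaction line, kJ/mol.
#' @return The patched character vector of topology lines.
#' @export
patch_topology <- function(topology_text, restraints, table_index = 0,
                           k = sigmoid_params()$k) {
  if (nrow(restraints) == 0) return(topology_text)
  atoms <- parse_topology_atoms(topology_text)
  need <- unique(c(restraints$i, restraints$j))
  missing <- setdiff(need, atoms$resnr)
  if (length(missing) > 0) {
    abort(sprintf("residue(s) %s have no CA atom in the topology.",
                  paste(missing, collapse = ", ")))
  }
  idx <- stats::setNames(atoms$nr, atoms$resnr)
  lines <- sprintf("%6d %6d %5d %5d %12.6f",
                   idx[as.character(restraints$i)],
                   idx[as.character(restraints$j)],
                   9L, as.integer(table_index), k)
  sec <- grep("^\\s*\\[\\s*bonds\\s*\\]", topology_text)
  if (length(sec) == 0) {
    c(topology_text, "", "[ bonds ]",
      ";   ai     aj funct table            k", lines)
  } else {
    # insert at the end of the existing [ bonds ] section
    after <- sec[1]
    rest <- topology_text[seq(after + 1, length(topology_text))]
    next_sec <- grep("^\\s*\\[", rest)
    end <- if (length(next_sec) == 0) length(topology_text) else
      after + next_sec[1] - 1
    append(topology_text, lines, after = end)
  }
}

parse_topology_atoms <- function(topology_text) {
  sec <- grep("^\\s*\\[\\s*atoms\\s*\\]", topology_text)
  if (length(sec) == 0) abort("topology has no [ atoms ] section.")
  rest <- topology_text[seq(sec[1] + 1, length(topology_text))]
  next_sec <- grep("^\\s*\\[", rest)
  if (length(next_sec) > 0) rest <- rest[seq_len(next_sec[1] - 1)]
  rows <- rest[!grepl("^\\s*(;|$)", rest)]
  if (length(rows) == 0) abort("topology [ atoms ] section is empty.")
  fields <- strsplit(trimws(rows), "\\s+")
  tab <- tibble(
    nr = as.integer(purrr::map_chr(fields, 1)),
    resnr = as.integer(purrr::map_chr(fields, 3)),
    atom = purrr::map_chr(fields, 5)
  )
  tab[tab$atom == "CA", , drop = FALSE]
}
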