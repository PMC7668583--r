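#' Synthetic folded reference structures
#'
#' Generates idealized C-alpha traces with the geometric properties the
#' contact-guided method assumes: consecutive C-alpha distances near the
#' 0.38 nm virtual bond, and (for `helix_loop_helix`) a compact fold with
#' inter-helix native contacts under the 6 Angstrom / |i-j| >= 4
#' definition. These stand in for experimentally determined native states
#' so the whole pipeline is exercisable without downloads.
#'
#' The helical trace uses ideal alpha-helix geometry (rise 1.5 Angstrom
#' per residue, 100 degree turn, 2.3 Angstrom C-alpha radius). The
#' `helix_loop_helix` motif packs two antiparallel helices joined by a
#' short loop close enough that inter-helix C-alpha pairs fall below 6
#' Angstrom. A small seeded jitter (sd 0.02 Angstrom) makes distinct seeds
#' distinct while preserving the geometry.
#'
#' @param n_residues Number of residues (>= 8).
#' @param motif `"helix"` or `"helix_loop_helix"`.
#' @param seed Integer seed; same arguments + seed give identical
#'   coordinates.
#' @return A [structure_model()].
#' @examples
#' helix <- make_folded_fixture(12, "helix", seed = 1)
#' @export
make_folded_fixture <- function(n_residues,
                                motif = c("helix", "helix_loop_helix"),
                                seed = 1) {
  motif <- match.arg(motif)
  n_residues <- as.integer(n_residues)
  if (n_residues < 8) abort("need at least 8 residues for a folded fixture.")
  coords <- if (motif == "helix") {
    helix_trace(n_residues)
  } else {
    helix_loop_helix_trace(n_residues)
  }
  jitter <- with_seed(seed, matrix(stats::rnorm(3 * n_residues, sd = 0.002),
                                   ncol = 3))
  structure_model(coords + jitter,
                  label = sprintf("%s fixture (n=%d, seed=%d)",
                                  motif, n_residues, seed))
}

# ideal alpha-helix C-alpha trace, nm; axis along z
helix_trace <- function(n, rise = 0.15, turn_deg = 100, radius = 0.23,
                        phase = 0) {
  i <- seq_len(n) - 1
  ang <- phase + i * turn_deg * pi / 180
  cbind(radius * cos(ang), radius * sin(ang), i * rise)
}

# two antiparallel helices joined by a short loop, packed so that
# inter-helix C-alpha pairs below 0.6 nm exist without steric clashes
helix_loop_helix_trace <- function(n) {
  n_loop <- 3L
  n1 <- (n - n_loop) %/% 2L
  n2 <- n - n_loop - n1
  h1 <- helix_trace(n1)
  # second helix: axis offset in x, running back down in z
  h2 <- helix_trace(n2, phase = pi)
  h2 <- cbind(0.55 + h2[, 1], h2[, 2], max(h1[, 3]) - 0.1 - h2[, 3])
  # loop: linear bridge from h1 top to h2 top at virtual-bond spacing
  p_from <- h1[n1, ]
  p_to <- h2[1, ]
  ts <- seq_len(n_loop) / (n_loop + 1)
  arch <- cbind(0, 0.45 * sin(pi * ts), 0.25 * sin(pi * ts))
  loop <- outer(1 - ts, p_from) + outer(ts, p_to) + arch
  coords <- rbind(h1, loop, h2)
  # restore near-uniform virtual bonds along the loop region
  rescale_bonds(coords, target = 0.38, from = n1, to = n1 + n_loop + 1L)
}

# adjust consecutive distances in [from, to] toward target by moving beads
# along the local bond direction (simple iterative relaxation)
rescale_bonds <- function(coords, target, from, to, n_iter = 200) {
  for (iter in seq_len(n_iter)) {
    for (b in seq(from, to - 1)) {
      v <- coords[b + 1, ] - coords[b, ]
      d <- sqrt(sum(v^2))
      corr <- 0.5 * (d - target) * v / d
      coords[b + 1, ] <- coords[b + 1, ] - corr
      coords[b, ] <- coords[b, ] + corr
    }
  }
  coords
}

#' Synthetic unfolded starting structures
#'
#' Builds a self-avoiding random C-alpha chain: consecutive distances
#' exactly 0.38 nm, no pair with sequence separation >= 2 closer than
#' 0.45 nm, and no pair with separation >= 4 closer than 0.6 nm — so the
#' chain has zero native contacts by construction, mirroring an extended
#' high-RMSD start with no residual structure.
#'
#' Chain growth is a persistent random walk (new directions drawn within a
#' cone of the previous bond) with bounded retries; if a seed paints the
#' chain into a corner the function errors and suggests trying another.
#'
#' @param n_residues Chain length.
#' @param seed Integer seed; deterministic given `(n_residues, seed)`.
#' @return A [structure_model()].
#' @export
make_unfolded_fixture <- function(n_residues, seed = 1) {
  n_residues <- as.integer(n_residues)
  if (n_residues < 2) abort("need at least 2 residues.")
  bond <- 0.38
  res <- with_seed(seed, {
    for (restart in 1:80) {
      coords <- matrix(NA_real_, n_residues, 3)
      coords[1, ] <- 0
      dir <- random_unit()
      coords[2, ] <- coords[1, ] + bond * dir
      ok <- TRUE
      for (b in seq(3, length.out = max(0, n_residues - 2))) {
        placed <- FALSE
        for (try in 1:300) {
          cand_dir <- cone_sample(dir, max_angle = pi / 3)
          cand <- coords[b - 1, ] + bond * cand_dir
          prev <- coords[seq_len(b - 1), , drop = FALSE]
          d <- sqrt(rowSums((prev - matrix(cand, b - 1, 3, TRUE))^2))
          sep <- (b) - seq_len(b - 1)
          lim <- ifelse(sep >= 4, 0.62, ifelse(sep >= 2, 0.45, 0))
          if (all(d > lim)) {
            coords[b, ] <- cand
            dir <- cand_dir
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) break
    }
    if (!ok) abort(sprintf(
      "could not place a self-avoiding chain for seed %d; try another seed.",
      seed))
    coords
  })
  structure_model(res, label = sprintf("unfolded fixture (n=%d, seed=%d)",
                                       n_residues, seed))
}

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# unit vector uniform within a cone of half-angle max_angle around axis
cone_sample <- function(axis, max_angle) {
  cosang <- stats::runif(1, cos(max_angle), 1)
  sinang <- sqrt(1 - cosang^2)
  phi <- stats::runif(1, 0, 2 * pi)
  # orthonormal frame around axis
  a <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * axis) * axis
  u <- u / sqrt(sum(u^2))
  w <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  cosang * axis + sinang * (cos(phi) * u + sin(phi) * w)
}
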