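# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and bio3d) wherever they check one.

# brute-force native-contact scan: double loop over all residue pairs
brute_force_contacts <- function(model, cutoff = 0.6, min_sep = 4) {
  co <- as.matrix(model[, c("x", "y", "z")])
  ids <- model$res_id
  out <- list()
  for (a in seq_len(nrow(co) - 1)) {
    for (b in seq(a + 1, nrow(co))) {
      if (abs(ids[b] - ids[a]) < min_sep) next
      d <- sqrt(sum((co[a, ] - co[b, ])^2))
      if (d <= cutoff) out[[length(out) + 1]] <- c(ids[a], ids[b], d)
    }
  }
  if (length(out) == 0) {
    return(data.frame(i = integer(), j = integer(), r_ref = numeric()))
  }
  m <- do.call(rbind, out)
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]), r_ref = m[, 3])
}

# brute-force rigid-body RMSD minimization: centered coordinates, coarse
# rotation grid (Euler angles) refined by optim; independent of Kabsch/bio3d
brute_force_rmsd <- function(mobile, target) {
  A <- as.matrix(mobile[, c("x", "y", "z")])
  B <- as.matrix(target[, c("x", "y", "z")])
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  rotmat <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((A %*% t(rotmat(ang)) - B)^2)))
  grid <- seq(0, 2 * pi - 0.4, by = 0.4)
  best <- NULL
  best_val <- Inf
  for (a1 in grid) for (a2 in grid) for (a3 in grid) {
    v <- obj(c(a1, a2, a3))
    if (v < best_val) { best_val <- v; best <- c(a1, a2, a3) }
  }
  res <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  res2 <- stats::optim(res$par, obj, method = "BFGS",
                       control = list(reltol = 1e-14))
  min(res$value, res2$value) * 10  # nm -> Angstrom
}

# a tiny CA-only topology in GROMACS dialect, n sequential residues
toy_topology <- function(n) {
  c("[ moleculetype ]",
    "; name  nrexcl",
    "Protein 1",
    "",
    "[ atoms ]",
    ";  nr type resnr residue atom cgnr charge mass",
    sprintf("%4d  CA  %4d  ALA   CA  %4d  0.0  110.0", 1:n, 1:n, 1:n),
    "",
    "[ bonds ]",
    ";  ai  aj funct",
    sprintf("%4d %4d 1 0.38 8000", seq_len(n - 1), 2:n),
    "",
    "[ system ]",
    "Toy")
}

expect_tbl_equal <- function(a, b, tol = 1e-12) {
  testthat::expect_equal(as.data.frame(a), as.data.frame(b),
                         tolerance = tol, ignore_attr = TRUE)
}
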