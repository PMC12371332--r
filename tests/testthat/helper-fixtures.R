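# shared in-code fixtures

# minimal hand-written 3-residue PDB (ALA, GLY, VAL on chain A)
agv_pdb_text <- function() {
  paste(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      5  CA  GLY A   2       4.214   2.680   0.000  1.00  0.00           C",
    "ATOM      6  C   GLY A   2       5.712   2.409   0.000  1.00  0.00           C",
    "ATOM      7  N   VAL A   3       6.296   2.307   1.201  1.00  0.00           N",
    "ATOM      8  CA  VAL A   3       7.742   2.112   1.311  1.00  0.00           C",
    "ATOM      9  CB  VAL A   3       8.120   0.702   0.892  1.00  0.00           C",
    "END", sep = "\n")
}

# octahedral pocket of the grid worked example: six atoms at +-2 on each
# axis, one alpha sphere of radius 2 at the origin
octahedron_pocket <- function(shift = c(0, 0, 0)) {
  atoms <- tibble::tibble(
    chain_id = "A", res_name = "GLY", res_id = 1:6, icode = NA_character_,
    serial = 1:6, atom_name = "CA", element = "C",
    x = c(2, -2, 0, 0, 0, 0) + shift[[1]],
    y = c(0, 0, 2, -2, 0, 0) + shift[[2]],
    z = c(0, 0, 0, 0, 2, -2) + shift[[3]],
    occupancy = 1, is_heavy = TRUE, vdw_radius = 1.7)
  pocketlit:::new_geometric_pocket(
    1,
    tibble::tibble(x = shift[[1]], y = shift[[2]], z = shift[[3]], radius = 2),
    atoms)
}

# random small pocket for oracle-equivalence checks
random_pocket <- function(n_atoms = 20, n_spheres = 4) {
  atoms <- tibble::tibble(
    chain_id = "A", res_name = "GLY",
    res_id = seq_len(n_atoms), icode = NA_character_,
    serial = seq_len(n_atoms), atom_name = "CA", element = "C",
    x = runif(n_atoms, -6, 6), y = runif(n_atoms, -6, 6),
    z = runif(n_atoms, -6, 6),
    occupancy = 1, is_heavy = TRUE, vdw_radius = 1.7)
  spheres <- tibble::tibble(
    x = runif(n_spheres, -4, 4), y = runif(n_spheres, -4, 4),
    z = runif(n_spheres, -4, 4), radius = runif(n_spheres, 1, 4))
  pocketlit:::new_geometric_pocket(1, spheres, atoms)
}

# independent point-in-hull test: squared distance from p to conv(X) via a
# ridge-regularized QP over the simplex (quadprog), a different algorithm
# from the facet enumeration used by the package
hull_contains_qp <- function(X, p, tol = 1e-4) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- 2 * (X %*% t(X) + diag(1e-9, n))
  d <- 2 * as.numeric(X %*% p)
  A <- cbind(rep(1, n), diag(n))
  b0 <- c(1, rep(0, n))
  sol <- quadprog::solve.QP(D, d, A, b0, meq = 1)
  lam <- sol$solution
  sqrt(sum((as.numeric(t(X) %*% lam) - p)^2)) <= tol
}

# three-stage grid computed by plain loops over the lattice, predicate by
# predicate (sphere membership, hull membership, VdW clash)
brute_force_grid <- function(pocket, structure, spacing = 1.5) {
  heavy <- pocket$atoms[pocket$atoms$is_heavy, ]
  X <- cbind(heavy$x, heavy$y, heavy$z)
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  pts <- list()
  for (x in seq(lo[1], hi[1], by = spacing))
    for (y in seq(lo[2], hi[2], by = spacing))
      for (z in seq(lo[3], hi[3], by = spacing)) {
        p <- c(x, y, z)
        in_sphere <- FALSE
        for (s in seq_len(nrow(pocket$spheres))) {
          d <- sqrt(sum((p - c(pocket$spheres$x[s], pocket$spheres$y[s],
                               pocket$spheres$z[s]))^2))
          if (d <= pocket$spheres$radius[s] + 1e-9) in_sphere <- TRUE
        }
        if (!in_sphere) next
        if (!hull_contains_qp(X, p)) next
        clash <- FALSE
        if (!is.null(structure)) {
          for (a in seq_len(nrow(structure))) {
            d <- sqrt(sum((p - c(structure$x[a], structure$y[a],
                                 structure$z[a]))^2))
            if (d < structure$vdw_radius[a] - 1e-9) clash <- TRUE
          }
        }
        if (!clash) pts[[length(pts) + 1]] <- p
      }
  if (length(pts) == 0) return(matrix(0, 0, 3))
  do.call(rbind, pts)
}

sort_points <- function(m) {
  m <- as.matrix(m)
  dimnames(m) <- NULL
  if (nrow(m) == 0) return(m)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# residue ids as plain canonical keys (for set-level metric tests)
res_keyify <- function(ids) paste0("A|", ids, "|")

# standard two-pocket fixture spec used across tests
default_fixture <- function(seed = 1, n_chains = 2, decoys = 1) {
  fixture_spec(
    seed = seed, n_chains = n_chains, chain_len = 30,
    pockets = list(list(name = "inhibitor site", ids = 10:15,
                        type = "single")),
    decoys = decoys)
}
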