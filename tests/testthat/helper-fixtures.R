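# Programmatic fixtures and independent oracles used across the suite.

# ---- abstract feature-set builders -----------------------------------------

# feature set from a k x 3 coordinate matrix and a type letter vector
fs_from_coords <- function(id, types, xyz, dirs = NULL, conformer = 0L) {
  feats <- lapply(seq_along(types), function(i) {
    d <- if (!is.null(dirs)) dirs[[i]] else
      if (types[i] == "R") c(0, 0, 1) else NULL
    phk_feature(types[i], xyz[i, ], direction = d)
  })
  feature_set(id, conformer, feats)
}

random_fs <- function(id, types, box = 20, conformer = 0L) {
  xyz <- matrix(stats::runif(3 * length(types), -box / 2, box / 2),
                length(types), 3)
  fs_from_coords(id, types, xyz, conformer = conformer)
}

rotation_about_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

# ---- molfile builders -------------------------------------------------------

sdf_atom_line <- function(x, y, z, el)
  sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
          x, y, z, el)

sdf_block <- function(title, atoms, bonds, extra = character(0)) {
  c(title, "  phk", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
            length(atoms), length(bonds)),
    atoms, bonds, extra, "M  END", "$$$$")
}

benzene_sdf_lines <- function() {
  r <- 1.394
  ang <- (0:5) * pi / 3
  atoms <- mapply(function(a) sdf_atom_line(r * cos(a), r * sin(a), 0, "C"),
                  ang)
  bonds <- sprintf("%3d%3d%3d  0", 1:6, c(2:6, 1), rep(c(2, 1), 3))
  sdf_block("benzene", atoms, bonds)
}

acetate_sdf_lines <- function() {
  atoms <- c(sdf_atom_line(1.5, 0, 0, "C"), sdf_atom_line(0, 0, 0, "C"),
             sdf_atom_line(-0.6, 1.06, 0, "O"),
             sdf_atom_line(-0.6, -1.06, 0, "O"))
  bonds <- c("  1  2  1  0", "  2  3  2  0", "  2  4  1  0")
  sdf_block("acetate", atoms, bonds, extra = "M  CHG  1   4  -1")
}

write_sdf <- function(lines) {
  f <- tempfile(fileext = ".sdf")
  writeLines(lines, f)
  f
}

# ---- PDB builder ------------------------------------------------------------

pdb_atom <- function(serial, name, resid, chain, resno, x, y, z, el,
                     het = FALSE)
  sprintf("%-6s%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          if (het) "HETATM" else "ATOM", serial, name, resid, chain, resno,
          x, y, z, el)

write_pdb <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  f
}

# ---- independent oracles ----------------------------------------------------

# exhaustive type-preserving assignment search: plain enumeration over all
# injections, no pruning; independent of the package's backtracking matcher
oracle_assignments <- function(ref_types, ref_xyz, fs, tol) {
  tys <- vapply(fs$features, function(f) f$type, character(1))
  xyz <- feature_coords(fs)
  k <- length(ref_types)
  ref_d <- as.matrix(stats::dist(ref_xyz))
  cand <- lapply(ref_types, function(ty) which(tys == ty))
  grids <- do.call(expand.grid, c(cand, list(KEEP.OUT.ATTRS = FALSE)))
  res <- list()
  for (r in seq_len(nrow(grids))) {
    a <- as.integer(grids[r, ])
    if (anyDuplicated(a)) next
    ok <- TRUE
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      dij <- sqrt(sum((xyz[a[i], ] - xyz[a[j], ])^2))
      if (abs(dij - ref_d[i, j]) > tol) { ok <- FALSE; break }
    }
    if (ok) res[[length(res) + 1L]] <- a
  }
  res
}

oracle_has_match <- function(ref_types, ref_xyz, fs, tol)
  length(oracle_assignments(ref_types, ref_xyz, fs, tol)) > 0L

# brute-force minimum superposition RMSD over a rotation grid with local
# polish (Nelder-Mead on Euler angles); independent of the SVD solver
oracle_min_rmsd <- function(ref, mov, n_grid = 10) {
  euler_rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  A <- sweep(ref, 2, colMeans(ref))
  B <- sweep(mov, 2, colMeans(mov))
  obj <- function(ang) {
    Bf <- B %*% t(euler_rot(ang))
    sqrt(mean(rowSums((Bf - A)^2)))
  }
  angles <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  best <- Inf; best_ang <- c(0, 0, 0)
  for (a1 in angles) for (a2 in angles[angles <= pi]) for (a3 in angles) {
    v <- obj(c(a1, a2, a3))
    if (v < best) { best <- v; best_ang <- c(a1, a2, a3) }
  }
  polish <- stats::optim(best_ang, obj, method = "Nelder-Mead",
                         control = list(reltol = 1e-14, maxit = 5000))
  min(best, polish$value)
}

# single Michaelis-Menten reaction S -> P as an in-code network spec
mm_toy_spec <- function(Vm = 1, Km = 2, S0 = 10) {
  list(species = list(list(name = "S", init_um = S0, compartment = "cell"),
                      list(name = "P", init_um = 0, compartment = "cell")),
       reactions = list(list(id = "r1", reactants = list("S"),
                             products = list("P"),
                             law = list(type = "michaelis_menten",
                                        params = list(Vm = Vm, Km = Km)))),
       readouts = list("P"),
       conserved_moieties = list(list(name = "total",
                                      species = list("S", "P"))))
}

mass_action_toy_spec <- function(k = 0.5, S0 = 10) {
  list(species = list(list(name = "S", init_um = S0, compartment = "cell"),
                      list(name = "P", init_um = 0, compartment = "cell")),
       reactions = list(list(id = "r1", reactants = list("S"),
                             products = list("P"),
                             law = list(type = "mass_action",
                                        params = list(k = k)))),
       readouts = list("P"))
}
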