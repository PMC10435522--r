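# Shared fixture builders: idealized peptide geometry, tiny structure
# models, and synthetic profile constructors.

# place atom D given A-B-C with bond length r (C-D), angle ang (B-C-D, deg)
# and dihedral dih (A-B-C-D, deg): natural extension reference frame
nerf_place <- function(a, b, c, r, ang, dih) {
  ang <- ang * pi / 180
  dih <- dih * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- pracma_cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-r * cos(ang), r * sin(ang) * cos(dih), r * sin(ang) * sin(dih))
  c + cbind(bc, m, n) %*% d2
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

# idealized backbone (N, CA, C, O) plus CB for non-glycine residues;
# phi/psi default to the fully extended conformation
build_chain <- function(seq1, phi = 180, psi = 180, chain = "A") {
  res <- strsplit(seq1, "")[[1]]
  n_res <- length(res)
  rows <- list()
  # seed the first residue
  N <- c(0, 0, 0); CA <- c(1.458, 0, 0)
  C <- as.numeric(nerf_place(c(-1, 1, 0), N, CA, 1.525, 111.0, 45))
  prev <- list(N = N, CA = CA, C = C)
  for (i in seq_len(n_res)) {
    if (i > 1) {
      N <- as.numeric(nerf_place(prev$N, prev$CA, prev$C, 1.329, 116.2, psi))
      CA <- as.numeric(nerf_place(prev$CA, prev$C, N, 1.458, 121.7, 180))
      C <- as.numeric(nerf_place(prev$C, N, CA, 1.525, 111.0, phi))
      prev <- list(N = N, CA = CA, C = C)
    }
    O <- as.numeric(nerf_place(N, CA, C, 1.231, 120.5, if (i < n_res) psi + 180 else psi))
    atoms <- list(N = N, CA = CA, C = C, O = O)
    if (res[i] != "G") {
      atoms$CB <- as.numeric(nerf_place(C, N, CA, 1.53, 110.5, -122))
    }
    aa3 <- epimapr:::aa_one_to_three(res[i])
    for (nm in names(atoms)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        chain = chain, resno = i, resid = aa3, atom = nm,
        element = substr(nm, 1, 1),
        x = atoms[[nm]][1], y = atoms[[nm]][2], z = atoms[[nm]][3])
    }
  }
  dplyr::bind_rows(rows)
}

# a leucine-like side chain grafted on residue `resno` of a built chain:
# CB-CG-CD1/CD2 with idealized geometry, for substitution-impact tests
graft_leu <- function(atoms, resno) {
  res <- atoms[atoms$resno == resno, ]
  N <- unlist(res[res$atom == "N", c("x", "y", "z")])
  CA <- unlist(res[res$atom == "CA", c("x", "y", "z")])
  CB <- unlist(res[res$atom == "CB", c("x", "y", "z")])
  CG <- as.numeric(nerf_place(N, CA, CB, 1.53, 114, 180))
  CD1 <- as.numeric(nerf_place(CA, CB, CG, 1.52, 110.5, 60))
  CD2 <- as.numeric(nerf_place(CA, CB, CG, 1.52, 110.5, 180))
  add <- tibble::tibble(
    chain = res$chain[1], resno = resno, resid = "LEU",
    atom = c("CG", "CD1", "CD2"), element = "C",
    x = c(CG[1], CD1[1], CD2[1]), y = c(CG[2], CD1[2], CD2[2]),
    z = c(CG[3], CD1[3], CD2[3]))
  atoms$resid[atoms$resno == resno] <- "LEU"
  dplyr::bind_rows(atoms, add)
}

# an antigenicity-profile-shaped tibble with chosen positives, for
# consensus tests (honors the documented profile contract)
make_profile <- function(positions, scores, threshold, sequence, method = "emini",
                         window = 6) {
  out <- tibble::tibble(position = positions, score = scores,
                        positive = scores > threshold,
                        nonstandard = FALSE)
  attr(out, "method") <- method
  attr(out, "window") <- window
  attr(out, "threshold") <- threshold
  attr(out, "sequence") <- sequence
  out
}

# small labelled alignment resembling a seven-species ortholog panel with a
# platypus-style excluded record carrying a long insertion
toy_panel <- function() {
  base <- "MKTLLVAGSSWDERTYKLHNPQCEFGIRAD"
  mut <- function(s, at, to) {
    v <- strsplit(s, "")[[1]]; v[at] <- to; paste(v, collapse = "")
  }
  hum <- base
  rat <- base
  opo <- mut(base, 28, "S")                # outside the divergent block
  chk <- mut(mut(mut(base, 10, "F"), 12, "P"), 14, "K")
  frg <- mut(mut(mut(base, 10, "Y"), 12, "T"), 14, "Q")
  zeb <- mut(mut(mut(base, 10, "H"), 12, "A"), 14, "N")
  pla <- mut(base, 20, "X")
  tibble::tibble(
    species = c("human", "rat", "opossum", "platypus", "chicken", "frog", "zebrafish"),
    label = c("binder", "weak_binder", "weak_binder", "excluded",
              "non_binder", "non_binder", "non_binder"),
    offset = c(23, 22, 22, 23, 24, 16, 18),
    aligned = c(hum, rat, opo, pla, chk, frg, zeb))
}

expect_rel_error <- function(value, truth, tol) {
  testthat::expect_lt(abs(value - truth) / abs(truth), tol)
}
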