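# Coordinate-level interface operations: I/O, SASA, contacts, BSA,
# disulfides, H-bonds, superposition, substitution impact, span.

test_that("PDB round trip preserves coordinates; altloc resolves by occupancy", {
  ch <- build_chain("GAG")
  m <- structure_model(ch)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(m, f)
  back <- read_structure(f)
  expect_identical(nrow(back), nrow(m))
  expect_equal(back$x, round(m$x, 3))
  expect_equal(back$z, round(m$z, 3))

  # altloc: A at 0.6 kept over B at 0.4
  alt <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.60 10.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.40 10.00           C",
    "END")
  fa <- withr::local_tempfile(fileext = ".pdb")
  writeLines(alt, fa)
  ma <- read_structure(fa)
  expect_identical(nrow(ma), 1L)
  expect_identical(ma$x, 0)

  expect_error(read_structure("no-such-file.pdb"), "no such file")
})

test_that("minimal mmCIF atom_site loops parse with altloc and het handling", {
  cif <- c(
    "data_toy", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "ATOM 1 N N . ALA A 1 0.000 0.000 0.000 1.00 10.0",
    "ATOM 2 C CA A ALA A 1 1.458 0.000 0.000 0.70 10.0",
    "ATOM 3 C CA B ALA A 1 2.000 0.000 0.000 0.30 10.0",
    "HETATM 4 O O . HOH A 2 5.000 5.000 5.000 1.00 10.0",
    "#")
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(cif, f)
  m <- read_structure(f)
  expect_identical(nrow(m), 3L)             # altloc B dropped
  expect_identical(m$x[m$atom == "CA"], 1.458)
  expect_true(m$water[m$resid == "HOH"])
  expect_true(m$het[m$resid == "HOH"])
  bad <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_x", "_cell.length_a 10"), bad)
  expect_error(read_structure(bad), "atom_site")
})

test_that("SASA: closed forms, analytic oracle, caging, monotonicity, refinement", {
  # isolated carbon: 4*pi*(1.7+1.4)^2
  iso <- structure_model(data.frame(chain = "A", resno = 1, resid = "UNK",
                                    atom = "C1", element = "C", x = 0, y = 0, z = 0))
  expect_rel_error(compute_sasa(iso)$sasa, 4 * pi * 3.1^2, 0.02)

  # two-atom pair against the analytic two-sphere oracle
  pair <- structure_model(data.frame(chain = "A", resno = 1:2, resid = "UNK",
                                     atom = c("C1", "S1"), element = c("C", "S"),
                                     x = c(0, 3), y = 0, z = 0))
  num <- compute_sasa(pair)
  orc <- two_sphere_sasa_oracle(1.7, 1.8, 3, 1.4)
  expect_rel_error(num$sasa[1], orc[["area1"]], 0.02)
  expect_rel_error(num$sasa[2], orc[["area2"]], 0.02)

  # atom caged by 26 neighbors at 2.5 A is essentially buried
  g <- expand.grid(x = c(-2.5, 0, 2.5), y = c(-2.5, 0, 2.5), z = c(-2.5, 0, 2.5))
  cage <- structure_model(data.frame(chain = "A", resno = seq_len(27), resid = "UNK",
                                     atom = "C1", element = "C",
                                     x = g$x, y = g$y, z = g$z))
  center <- which(g$x == 0 & g$y == 0 & g$z == 0)
  expect_lt(compute_sasa(cage)$sasa[center], 1)

  # adding a neighbor can only reduce an atom's SASA
  three <- structure_model(data.frame(chain = "A", resno = 1:3, resid = "UNK",
                                      atom = "C1", element = "C",
                                      x = c(0, 3, -3), y = 0, z = 0))
  expect_lte(compute_sasa(three)$sasa[1], num$sasa[1] + 1e-9)

  # quadrature refinement 960 -> 4000 moves results by < 1%
  hx <- gen_helix_complex(seed = 2)
  s960 <- compute_sasa(hx$model, n_points = 960)
  s4000 <- compute_sasa(hx$model, n_points = 4000)
  expect_lt(abs(sum(s960$sasa) - sum(s4000$sasa)) / sum(s4000$sasa), 0.01)
})

test_that("relative accessibility: tripeptide exposure and neighbor monotonicity", {
  ch <- build_chain("GAG")
  m <- structure_model(ch)
  rsa <- relative_accessibility(m)
  central <- rsa$rsa[rsa$resno == 2]
  expect_gt(central, 80); expect_lt(central, 110)
  expect_identical(attr(rsa, "reference_set"), "theoretical-max-GXG")
  # stripping the flanking residues cannot decrease accessibility
  lone <- relative_accessibility(structure_model(ch[ch$resno == 2, ]))
  expect_gt(lone$rsa, central)
  expect_error(relative_accessibility(structure_model(
    data.frame(chain = "A", resno = 1, resid = "XYZ", atom = "CA",
               element = "C", x = 0, y = 0, z = 0))), "unknown residue")
})

test_that("contacts: inclusive cutoff boundary and brute-force equality", {
  mk <- function(d) structure_model(data.frame(
    chain = c("A", "B"), resno = 1, resid = "UNK", atom = "C1", element = "C",
    x = c(0, d), y = 0, z = 0))
  expect_identical(nrow(interface_contacts(mk(3.79), "A", "B")$pairs), 1L)
  expect_identical(nrow(interface_contacts(mk(3.80), "A", "B")$pairs), 1L)
  expect_identical(nrow(interface_contacts(mk(3.81), "A", "B")$pairs), 0L)

  # generator ground truth reproduced exactly
  hx <- gen_helix_complex(seed = 3, n_probe_atoms = 5)
  ct <- interface_contacts(hx$model, "A", "B")
  got <- ct$pairs[, c("resno_ag", "atom_ag", "resno_ab")]
  names(got) <- c("resno_ag", "atom_ag", "resno_probe")
  expect_identical(dplyr::arrange(got, resno_ag),
                   dplyr::arrange(hx$contacts[, c("resno_ag", "atom_ag", "resno_probe")],
                                  resno_ag))
  expect_identical(ct$epitope$resno, hx$designated)

  # brute-force all-pairs oracle on a random two-chain fixture
  withr::with_seed(17, {
    at <- tibble::tibble(chain = rep(c("A", "B"), each = 25), resno = rep(1:25, 2),
                         resid = "UNK", atom = "C1", element = "C",
                         x = runif(50, 0, 15), y = runif(50, 0, 15), z = runif(50, 0, 15))
  })
  mr <- structure_model(at)
  ctr <- interface_contacts(mr, "A", "B", cutoff = 5)
  brute <- 0L
  A <- at[at$chain == "A", ]; B <- at[at$chain == "B", ]
  for (i in 1:25) for (j in 1:25) {
    if (sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 + (A$z[i] - B$z[j])^2) <= 5) {
      brute <- brute + 1L
    }
  }
  expect_identical(nrow(ctr$pairs), brute)
  # monotone in cutoff
  expect_lte(nrow(interface_contacts(mr, "A", "B", cutoff = 4)$pairs), nrow(ctr$pairs))
})

test_that("BSA: separation zero, oracle agreement, partition symmetry", {
  far <- structure_model(data.frame(chain = c("A", "B"), resno = 1, resid = "UNK",
                                    atom = "C1", element = "C", x = c(0, 50), y = 0, z = 0))
  expect_equal(buried_surface_area(far, "A", "B")$total_bsa, 0)

  near <- structure_model(data.frame(chain = c("A", "B"), resno = 1, resid = "UNK",
                                     atom = "C1", element = "C", x = c(0, 3), y = 0, z = 0))
  b <- buried_surface_area(near, "A", "B", n_points = 4000)
  orc <- two_sphere_sasa_oracle(1.7, 1.7, 3, 1.4)
  truth <- sum(4 * pi * 3.1^2 - orc)
  expect_rel_error(b$total_bsa, truth, 0.02)
  expect_gte(b$total_bsa, 0)

  hx <- gen_helix_complex(seed = 4)
  b1 <- buried_surface_area(hx$model, "A", "B")
  b2 <- buried_surface_area(hx$model, "B", "A")
  expect_equal(b1$total_bsa, b2$total_bsa)
  expect_equal(b1$total_bsa, sum(b1$residues$dsasa))
  expect_error(buried_surface_area(hx$model, "A", "A"), "disjoint|overlap")
})

test_that("BSA on the toy complex matches the high-resolution generator truth", {
  hx <- gen_helix_complex(seed = 6, n_probe_atoms = 4, probe_distance = 3.2)
  b <- buried_surface_area(hx$model, "A", "B")
  expect_rel_error(b$total_bsa, hx$bsa, 0.02)
})

test_that("disulfides: canonical S-S length pairs once, nearest wins", {
  mk_cys <- function(xs) structure_model(tibble::tibble(
    chain = "A", resno = seq_along(xs), resid = "CYS", atom = "SG", element = "S",
    x = xs, y = 0, z = 0))
  one <- find_disulfides(mk_cys(c(0, 2.05)))
  expect_identical(nrow(one), 1L)
  expect_equal(one$distance, 2.05)
  expect_identical(nrow(find_disulfides(mk_cys(c(0, 4.0)))), 0L)
  # three SG in a row: nearest pair wins, third stays unpaired
  tri <- find_disulfides(mk_cys(c(0, 2.0, 4.2)))
  expect_identical(nrow(tri), 1L)
  expect_identical(c(tri$resno1, tri$resno2), c(1L, 2L))
  # the printed-pattern layout: pairs (72,77) and (101,128) in mature numbering
  m4 <- structure_model(tibble::tibble(
    chain = "E", resno = c(72, 77, 101, 128), resid = "CYS", atom = "SG",
    element = "S", x = c(0, 2.05, 30, 32.05), y = 0, z = 0))
  ss <- find_disulfides(m4)
  expect_identical(ss$mature1, c(72L, 101L))
  expect_identical(ss$mature2, c(77L, 128L))
})

test_that("H-bonds report donor/acceptor N-O pairs only", {
  m <- structure_model(tibble::tibble(
    chain = c("A", "A", "B", "B"), resno = c(1, 1, 1, 1),
    resid = c("SER", "ALA", "GLY", "ALA"),
    atom = c("OG", "CB", "N", "CB"), element = c("O", "C", "N", "C"),
    x = c(0, 0, 2.9, 2.9), y = c(0, 5, 0, 5), z = 0))
  hb <- find_hbonds(m, "A", "B")
  expect_identical(nrow(hb), 1L)
  expect_identical(hb$donor_atom, "N")      # backbone N donates to Ser OG
  expect_identical(hb$acceptor_atom, "OG")
  # the C-C pair at 2.9 A is never reported
  expect_false(any(hb$donor_atom == "CB" | hb$acceptor_atom == "CB"))
})

test_that("superposition: rigid invariance, oracle agreement, trimming, safeguards", {
  ch <- build_chain("GAGAG")
  m <- structure_model(ch)
  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- ch
  xyz <- as.matrix(ch[, c("x", "y", "z")]) %*% t(R)
  moved$x <- xyz[, 1] + 4; moved$y <- xyz[, 2] - 2; moved$z <- xyz[, 3] + 1
  s <- superpose(m, structure_model(moved))
  expect_lt(s$rmsd, 1e-6)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)

  # 4-point sets against the exhaustive rotation-search oracle
  for (seed in 1:3) {
    withr::with_seed(seed, {
      P <- matrix(rnorm(12), 4, 3)
      Q <- P %*% t(R) + matrix(rnorm(12, 0, 0.2), 4, 3)
    })
    mk <- function(X) structure_model(tibble::tibble(
      chain = "A", resno = 1:4, resid = "GLY", atom = "CA", element = "C",
      x = X[, 1], y = X[, 2], z = X[, 3]))
    skab <- superpose(mk(P), mk(Q))
    oracle <- rmsd_rotation_search(P, Q, grid_n = 16)
    expect_lt(abs(skab$rmsd - oracle), 1e-3)
    expect_lte(skab$rmsd, oracle + 1e-9)  # Kabsch is the optimum
  }

  # trimming drops a displaced outlier pair and reduces the RMSD
  ch12 <- build_chain("GAGAGAGAGAGA")
  m12 <- structure_model(ch12)
  out <- ch12
  out$x[out$resno == 6] <- out$x[out$resno == 6] + 25
  plain <- superpose(m12, structure_model(out))
  trimmed <- superpose(m12, structure_model(out), trim = TRUE)
  expect_lt(trimmed$rmsd, plain$rmsd)
  expect_gte(trimmed$cycles, 1)
  expect_lt(trimmed$n_pairs, plain$n_pairs)

  # mirrored coordinates must still produce a proper rotation
  mir <- ch; mir$x <- -mir$x
  sm <- superpose(m, structure_model(mir))
  expect_equal(det(sm$rotation), 1, tolerance = 1e-9)

  expect_error(superpose(m, structure_model(moved[moved$resno <= 2 &
                                                    moved$atom == "CA", ])), "3 corresponding")
})

test_that("sequence-alignment correspondence pairs renumbered chains", {
  ch <- build_chain("GAGAGA")
  m <- structure_model(ch)
  ren <- ch
  ren$resno <- ren$resno + 100
  s <- superpose(m, structure_model(ren), correspondence = "alignment")
  expect_lt(s$rmsd, 1e-6)
  expect_identical(s$n_pairs, 6L)
})

test_that("substitution impact: truncation rule, lost contacts and clash", {
  at <- graft_leu(build_chain("GALAG"), 3)
  leu <- at[at$resno == 3, ]
  cd2 <- unlist(leu[leu$atom == "CD2", c("x", "y", "z")])
  cd1 <- unlist(leu[leu$atom == "CD1", c("x", "y", "z")])
  probe <- tibble::tibble(
    chain = "B", resno = 1:2, resid = "PRB", atom = c("P1", "P2"), element = "C",
    x = c(cd2[1] + 3.0, cd1[1]), y = c(cd2[2], cd1[2]), z = c(cd2[3], cd1[3] + 3.0))
  m <- structure_model(dplyr::bind_rows(at, probe))

  # oracle: the contact list itself, filtered by the deleted-atom sets
  site_pairs <- interface_contacts(m, "A", "B")$pairs
  site_pairs <- site_pairs[site_pairs$resno_ag == 3, ]
  n_beyond_cb <- sum(site_pairs$atom_ag %in% c("CG", "CD1", "CD2"))
  n_cd2 <- sum(site_pairs$atom_ag == "CD2")
  expect_gt(n_beyond_cb, 0); expect_gt(n_cd2, 0)

  to_ala <- substitution_impact(m, "A", 3, "ALA", "A", "B")
  expect_setequal(to_ala$deleted_atoms, c("CG", "CD1", "CD2"))
  expect_identical(to_ala$lost_contacts, n_beyond_cb)

  to_ile <- substitution_impact(m, "A", 3, "ILE", "A", "B")
  expect_identical(to_ile$deleted_atoms, character(0))
  expect_identical(to_ile$lost_contacts, 0L)

  to_val <- substitution_impact(m, "A", 3, "VAL", "A", "B")
  expect_identical(to_val$deleted_atoms, "CD2")
  expect_identical(to_val$lost_contacts, n_cd2)
  expect_lte(to_ile$lost_contacts, to_val$lost_contacts)
  expect_lte(to_val$lost_contacts, to_ala$lost_contacts)

  # cross-interface atom at 2.5 A from a retained atom -> clash under chi1 scan
  close_probe <- tibble::tibble(chain = "B", resno = 3, resid = "PRB", atom = "P3",
                                element = "C", x = cd1[1] + 2.5, y = cd1[2], z = cd1[3])
  mc <- structure_model(dplyr::bind_rows(at, probe, close_probe))
  expect_true(substitution_impact(mc, "A", 3, "VAL", "A", "B")$clash)

  expect_error(substitution_impact(m, "A", 1, "ALA", "A", "B"), "glycine")
})

test_that("assembly span measures anchor C-alpha separation", {
  m <- structure_model(tibble::tibble(
    chain = c("G", "T"), resno = c(407, 1), resid = "ALA", atom = "CA",
    element = "C", x = 0, y = 0, z = c(0, 140)))
  sp <- assembly_span(m, list(chain = "G", resno = 407), list(chain = "T", resno = 1))
  expect_equal(sp$distance, 140)
  expect_equal(assembly_span(m, list(chain = "G", resno = 407),
                             list(chain = "G", resno = 407))$distance, 0)
  expect_error(assembly_span(m, list(chain = "G", resno = 1),
                             list(chain = "T", resno = 1)), "anchor")

  # two-arm fixture with a planted 140 A spacing between terminal anchors
  arm <- build_chain("GAGAG")
  arm2 <- arm; arm2$chain <- "T"; arm2$z <- arm2$z + 140
  m2 <- structure_model(dplyr::bind_rows(arm, arm2))
  sp2 <- assembly_span(m2, list(chain = "A", resno = 1), list(chain = "T", resno = 1))
  expect_equal(sp2$distance, 140, tolerance = 1e-4)
})

test_that("chain grouping separates complex copies in an asymmetric unit", {
  hx <- gen_helix_complex(seed = 8)
  copy2 <- as_tibble(hx$model)
  copy2$chain <- ifelse(copy2$chain == "A", "C", "D")
  copy2$x <- copy2$x + 100
  two <- structure_model(dplyr::bind_rows(as_tibble(hx$model), copy2))
  cg <- chain_groups(two)
  expect_identical(length(unique(cg$copy)), 2L)
  expect_identical(cg$copy[cg$chain == "A"], cg$copy[cg$chain == "B"])
  expect_false(cg$copy[cg$chain == "A"] == cg$copy[cg$chain == "C"])
})

test_that("interface report aggregates and exposes tidy/glance views", {
  hx <- gen_helix_complex(seed = 9)
  rep_ <- interface_report(hx$model, "A", "B")
  g <- glance(rep_)
  expect_identical(g$n_epitope, nrow(rep_$epitope))
  expect_equal(g$total_bsa, rep_$total_bsa)
  td <- tidy(rep_)
  expect_true(all(c("side", "dsasa", "in_contact_set") %in% names(td)))
  expect_s3_class(autoplot(rep_), "ggplot")
})
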