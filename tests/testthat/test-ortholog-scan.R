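# Differential conservation, surface filtering, patch/chimera design and
# antigenicity prediction.

write_panel_fasta <- function(panel, path) {
  writeLines(paste0(">", panel$species, "\n", panel$aligned), path)
}

test_that("alignment ingestion validates labels, lengths and the reference", {
  panel <- toy_panel()
  fa <- withr::local_tempfile(fileext = ".fasta")
  lb <- withr::local_tempfile(fileext = ".tsv")
  write_panel_fasta(panel, fa)
  readr::write_tsv(panel[, c("species", "label", "offset")], lb)
  p <- ingest_alignment(fa, lb, reference = "human")
  expect_identical(nrow(p), 7L)
  expect_identical(sum(p$label != "excluded"), 6L)

  # one record shorter -> error naming it
  bad <- panel
  bad$aligned[3] <- substr(bad$aligned[3], 1, 10)
  write_panel_fasta(bad, fa)
  expect_error(ingest_alignment(fa, lb), "opossum")

  # unknown label -> rejected
  write_panel_fasta(panel, fa)
  bad_lb <- panel[, c("species", "label", "offset")]
  bad_lb$label[2] <- "sometimes_binder"
  expect_error(ingest_alignment(fa, bad_lb), "unknown label")

  # missing record in the labels table -> named
  expect_error(ingest_alignment(fa, panel[-5, c("species", "label", "offset")]), "chicken")
})

test_that("mature/precursor conversion round-trips through the declared offset", {
  m <- structure_model(build_chain("AAAA"), mature_offsets = c(A = 23))
  mt <- author_to_mature(m, "A", 91:110)
  expect_identical(mt, 68:87)
  expect_identical(mature_to_author(m, "A", mt), 91:110)
})

test_that("pairwise identity counts non-dual-gap columns", {
  expect_equal(pairwise_identity("MKTWL", "MKTWL"), 100)
  expect_equal(pairwise_identity("ACD-", "ACE-"), 100 * 2 / 3)
  # unrelated random sequences sit near background; exhaustive count oracle
  set.seed(31)
  s1 <- paste(sample(epimapr:::AA1, 300, replace = TRUE), collapse = "")
  s2 <- paste(sample(epimapr:::AA1, 300, replace = TRUE), collapse = "")
  pid <- pairwise_identity(s1, s2)
  direct <- 100 * sum(strsplit(s1, "")[[1]] == strsplit(s2, "")[[1]]) / 300
  expect_equal(pid, direct)
  expect_gt(pid, 1); expect_lt(pid, 12)
  # global mode self-identity
  expect_equal(pairwise_identity("MKTWLVNQ", "MKTWLVNQ", mode = "global_align"), 100)
  expect_error(pairwise_identity("", "A"), "empty")
})

test_that("differential rule: single ungapped binder residue absent from all non-binders", {
  p <- toy_panel()
  d <- differential_positions(p, reference = "human")
  expect_identical(d$column[d$differential], c(10L, 12L, 14L))
  # excluded platypus X at 20 must not create a column
  expect_false(d$differential[20])
  # opossum (weak binder) difference at 28 blocks that column
  expect_false(d$differential[28])

  # gap handling: binder gap never differential, non-binder gap is dissimilar
  pg <- tibble::tibble(
    species = c("h", "n"), label = c("binder", "non_binder"), offset = 0,
    aligned = c("AC-D", "AGT-"))
  dg <- differential_positions(pg, reference = "h")
  expect_identical(dg$differential, c(FALSE, TRUE, FALSE, TRUE))
  expect_identical(dg$mature, c(1L, 2L, NA_integer_, 3L))

  expect_error(differential_positions(p[p$label != "non_binder", ]), "non_binder")
})

test_that("flagged set shrinks monotonically as non-binder species accumulate", {
  g <- gen_ortholog_panel(seq_length = 80, planted_interval = c(30, 40),
                          n_nonbinders = 3, within_binder_divergence = 0.15, seed = 13)
  p <- g$panel
  sub1 <- p[p$label == "binder" | p$species == "nonbinder_1", ]
  d1 <- differential_positions(sub1)
  d3 <- differential_positions(p)
  expect_true(all(d3$mature[d3$differential] %in% d1$mature[d1$differential]))
})

test_that("surface filter separates exposed, buried and unmapped positions", {
  # extended decapeptide: everything is solvent-exposed
  m <- structure_model(build_chain("AAAAAAAAAA"))
  sf <- surface_filter(1:10, m, rsa_threshold = 0.25)
  expect_identical(sf$exposed$mature, 1:10)
  expect_identical(nrow(sf$buried), 0L)

  # cage the central CB under a shell of dummy atoms -> buried at 0.25
  res5 <- build_chain("AAAAAAAAAA")
  cb <- unlist(res5[res5$resno == 5 & res5$atom == "CB", c("x", "y", "z")])
  sph <- epimapr:::sphere_points(40) * 3.0
  cage <- tibble::tibble(chain = "A", resno = 100 + seq_len(40), resid = "UNK",
                         atom = "QQ", element = "C",
                         x = sph[, 1] + cb[1], y = sph[, 2] + cb[2], z = sph[, 3] + cb[3])
  m2 <- structure_model(dplyr::bind_rows(res5, cage))
  sf2 <- surface_filter(c(5, 99), m2, rsa_threshold = 0.25)
  expect_true(5 %in% sf2$buried$mature)
  expect_identical(sf2$unmapped, 99)
  expect_error(surface_filter(c(98, 99), m2), "missing every")
})

test_that("patch clustering: single linkage, deterministic split, donor lookup", {
  # three mutually close positions plus one 30 A away
  mk_model <- function(xs) {
    structure_model(tibble::tibble(chain = "A", resno = seq_along(xs), resid = "ALA",
                                   atom = "CB", element = "C", x = xs, y = 0, z = 0))
  }
  panel <- tibble::tibble(
    species = c("human", "chicken"), label = c("binder", "non_binder"), offset = 0,
    aligned = c(strrep("S", 10), strrep("F", 10)))
  m <- mk_model(c(0, 5, 8, 40))
  cp <- cluster_patches(1:4, m, panel, "chicken", distance_cutoff = 10)
  expect_identical(nrow(cp$patches), 3L)
  expect_identical(unique(cp$patches$patch), "P1")
  expect_equal(cp$unpatched, 4)
  expect_identical(unique(cp$patches$ref_residue), "S")
  expect_identical(unique(cp$patches$donor_residue), "F")
  # partition: every input position in exactly one patch or unpatched
  expect_setequal(c(cp$patches$mature, cp$unpatched), 1:4)

  # six collinear at 9 A spacing, cutoff 10, max size 4 -> 4 + 2 split
  m6 <- mk_model(seq(0, 45, by = 9))
  cp6 <- cluster_patches(1:6, m6, panel, "chicken", distance_cutoff = 10,
                         size_range = c(2, 4))
  sizes <- table(cp6$patches$patch)
  expect_identical(sort(as.integer(sizes)), c(2L, 4L))
  expect_identical(cp6$patches$mature[cp6$patches$patch == "P1"], 1:4)

  # donor gapped -> dropped with warning
  panel_gap <- panel
  panel_gap$aligned[2] <- paste0("F-", strrep("F", 8))
  expect_warning(cpg <- cluster_patches(1:3, mk_model(c(0, 5, 8)), panel_gap, "chicken"),
                 "gapped")
  expect_false(2 %in% cpg$patches$mature)
})

test_that("chimera proposal merges runs, pads, and maps donor intervals", {
  # reference has 3 extra leading residues relative to the donor
  ref <- paste0("MAB", strrep("Q", 97))
  don <- paste0("---", strrep("Q", 97))
  panel <- tibble::tibble(species = c("human", "chicken"),
                          label = c("binder", "non_binder"), offset = 0,
                          aligned = c(ref, don))
  pos <- c(74, 77, 80, 81, 83, 84, 85, 87, 90, 92)
  ch <- propose_chimeras(pos, panel, "chicken", max_gap = 3)
  expect_identical(nrow(ch), 1L)
  expect_identical(c(ch$ref_start, ch$ref_end), c(74L, 92L))
  expect_identical(c(ch$donor_start, ch$donor_end), c(71L, 89L))

  # isolated position padded symmetrically to min_span
  ch1 <- propose_chimeras(50, panel, "chicken", min_span = 6)
  expect_equal(ch1$ref_end - ch1$ref_start + 1, 6)
  expect_true(ch1$ref_start <= 50 && ch1$ref_end >= 50)

  expect_identical(nrow(propose_chimeras(integer(0), panel, "chicken")), 0L)

  # donor interval round-trips through the alignment
  don_chars <- strsplit(don, "")[[1]]
  donor_cols <- which(cumsum(don_chars != "-") %in% c(ch$donor_start, ch$donor_end) &
                        don_chars != "-")
  ref_mature <- cumsum(strsplit(ref, "")[[1]] != "-")
  expect_identical(ref_mature[range(donor_cols)], c(74L, 92L))
})

test_that("antigenicity profiles follow the published windowed rules", {
  sc <- epimapr:::EMINI_SCALE
  em <- antigenicity_profile(strrep("K", 6), "emini")
  expect_identical(nrow(em), 1L)
  expect_equal(em$score, unname(sc[["K"]])^6 / mean(sc)^6)

  # constant-propensity 7-mer: window score is exactly the propensity
  ka <- antigenicity_profile(strrep("A", 7), "kolaskar_tongaonkar")
  expect_identical(nrow(ka), 1L)
  expect_equal(ka$score, unname(epimapr:::KOLASKAR_SCALE[["A"]]))

  expect_error(antigenicity_profile("KK", "emini"), "shorter")
  expect_warning(p <- antigenicity_profile("KKKXKKKK", "emini"), "non-standard")
  expect_true(any(p$nonstandard))

  # scored span is 1..(L - w + 1)
  hp <- antigenicity_profile(strrep("KDE", 10), "hydrophilicity")
  expect_identical(hp$position, 1:(30 - 7 + 1))
})

test_that("consensus regions are the common positive runs, ranked by excess", {
  seqq <- strrep("A", 40)
  all_pos <- make_profile(1:30, rep(2, 30), 1, seqq)
  all_pos2 <- make_profile(1:30, rep(3, 30), 1, seqq, method = "kolaskar_tongaonkar", window = 7)
  cr <- consensus_regions(list(all_pos, all_pos2), min_run = 4)
  expect_identical(nrow(cr), 1L)
  expect_identical(c(cr$start, cr$end), c(1L, 30L))

  # disjoint positives -> empty consensus
  a <- make_profile(1:30, c(rep(2, 10), rep(0, 20)), 1, seqq)
  b <- make_profile(1:30, c(rep(0, 20), rep(2, 10)), 1, seqq)
  expect_identical(nrow(consensus_regions(list(a, b))), 0L)

  # planted common run of 8 recovered exactly, and consensus is a subset of
  # every profile's positive set
  sc_a <- ifelse(seq_len(30) %in% 11:18, 2, 0)
  sc_b <- ifelse(seq_len(30) %in% c(5:20), 2, 0)
  pa <- make_profile(1:30, sc_a, 1, seqq)
  pb <- make_profile(1:30, sc_b, 1, seqq)
  cr2 <- consensus_regions(list(pa, pb), min_run = 4)
  expect_identical(c(cr2$start, cr2$end), c(11L, 18L))
  expect_true(all(seq(cr2$start, cr2$end) %in% pa$position[pa$positive]))
  expect_error(consensus_regions(list(pa, make_profile(1:5, rep(2, 5), 1, "SHORT"))),
               "different sequences")
})
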