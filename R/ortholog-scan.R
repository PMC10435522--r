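# Chimera/patch design from differential conservation across a labelled
# ortholog panel: alignment ingestion, identity, differential scan, surface
# filtering, patch clustering, chimera proposal.

PANEL_LABELS <- c("binder", "weak_binder", "non_binder", "excluded")

validate_panel <- function(panel, require_nonbinder = TRUE) {
  panel <- as_tibble(panel)
  need <- c("species", "label", "offset", "aligned")
  miss <- setdiff(need, names(panel))
  if (length(miss) > 0) abort(paste0("panel missing column(s): ", paste(miss, collapse = ", ")))
  bad <- setdiff(unique(panel$label), PANEL_LABELS)
  if (length(bad) > 0) abort(paste0("unknown label(s): ", paste(bad, collapse = ", ")))
  w <- nchar(panel$aligned)
  if (length(unique(w)) != 1) {
    off <- panel$species[w != stats::median(w)]
    abort(paste0("aligned sequences differ in length; offending record(s): ",
                 paste(off, collapse = ", ")))
  }
  analyzable <- panel[panel$label != "excluded", , drop = FALSE]
  if (sum(analyzable$label %in% c("binder", "weak_binder")) < 1) {
    abort("panel needs at least one binder")
  }
  if (require_nonbinder && sum(analyzable$label == "non_binder") < 1) {
    abort("panel needs at least one non_binder")
  }
  panel
}

#' Ingest a multiple sequence alignment with binder labels
#'
#' Reads an aligned FASTA and a labels table (`species`, `label`,
#' `offset`), validates lengths and labels, and returns an ortholog panel.
#' Excluded species are retained but ignored by every analysis. The offset
#' is the signal-peptide length: mature position 1 = precursor position
#' offset + 1.
#'
#' @param fasta path to an aligned FASTA (gap character `-`).
#' @param labels path to a TSV with columns `species`, `label`, `offset`,
#'   or a data frame of the same shape.
#' @param reference species used for mature numbering (must be present).
#' @return panel tibble (`species`, `label`, `offset`, `aligned`) with
#'   attribute `reference`.
#' @export
ingest_alignment <- function(fasta, labels, reference = "human") {
  seqs <- Biostrings::readAAStringSet(fasta)
  if (is.character(labels)) {
    labels <- readr::read_tsv(labels, show_col_types = FALSE)
  }
  labels <- as_tibble(labels)
  ids <- sub("\\s.*$", "", names(seqs))
  miss <- setdiff(ids, labels$species)
  if (length(miss) > 0) {
    abort(paste0("record(s) missing from labels table: ", paste(miss, collapse = ", ")))
  }
  panel <- tibble(species = ids, aligned = toupper(as.character(seqs))) %>%
    left_join(labels[, c("species", "label", "offset")], by = "species") %>%
    select("species", "label", "offset", "aligned")
  panel <- validate_panel(panel, require_nonbinder = FALSE)
  if (!reference %in% panel$species) {
    abort(paste0("reference species '", reference, "' not in alignment"))
  }
  attr(panel, "reference") <- reference
  panel
}

panel_reference <- function(panel, reference = NULL) {
  reference <- reference %||% attr(panel, "reference")
  if (is.null(reference)) {
    binders <- panel$species[panel$label %in% c("binder", "weak_binder")]
    reference <- binders[1]
  }
  if (!reference %in% panel$species) abort(paste0("reference '", reference, "' not in panel"))
  reference
}

# mature position of the reference residue at each alignment column
# (NA where the reference is gapped)
reference_mature_map <- function(panel, reference) {
  ref <- strsplit(panel$aligned[panel$species == reference], "")[[1]]
  m <- cumsum(ref != "-")
  m[ref == "-"] <- NA_integer_
  as.integer(m)
}

#' Percent identity between two sequences
#'
#' `aligned_columns` compares position by position, excluding columns
#' gapped in both sequences; `global_align` first performs Needleman-Wunsch
#' global alignment (BLOSUM62) on the ungapped sequences.
#'
#' @param seq_a,seq_b amino-acid strings (may contain `-` gaps).
#' @param mode `"aligned_columns"` (default) or `"global_align"`.
#' @param gap_open,gap_extend global-alignment gap penalties.
#' @return percent identity (identities / compared columns x 100).
#' @export
pairwise_identity <- function(seq_a, seq_b, mode = c("aligned_columns", "global_align"),
                              gap_open = 10, gap_extend = 0.5) {
  mode <- match.arg(mode)
  if (nchar(gsub("-", "", seq_a)) == 0 || nchar(gsub("-", "", seq_b)) == 0) {
    abort("empty sequence")
  }
  if (mode == "global_align") {
    al <- Biostrings::pairwiseAlignment(gsub("-", "", seq_a), gsub("-", "", seq_b),
                                        type = "global", substitutionMatrix = "BLOSUM62",
                                        gapOpening = gap_open, gapExtension = gap_extend)
    seq_a <- as.character(Biostrings::alignedPattern(al))
    seq_b <- as.character(Biostrings::alignedSubject(al))
  }
  if (nchar(seq_a) != nchar(seq_b)) abort("aligned_columns mode requires equal-length sequences")
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  compared <- !(a == "-" & b == "-")
  100 * sum(a == b & compared & a != "-") / sum(compared)
}

#' Differential conservation columns of an ortholog panel
#'
#' A column is differential when the binders (weak binders included) carry
#' one identical, ungapped residue and no non-binder carries that residue
#' (a non-binder gap counts as dissimilar). Excluded species are ignored.
#'
#' @param panel ortholog panel tibble.
#' @param reference species whose mature numbering is attached (default:
#'   the panel's reference attribute, else the first binder).
#' @return tibble with `column`, `mature`, `binder_residue`,
#'   `nonbinder_residues`, `differential`.
#' @export
differential_positions <- function(panel, reference = NULL) {
  panel <- validate_panel(panel, require_nonbinder = TRUE)
  reference <- panel_reference(panel, reference)
  use <- panel[panel$label != "excluded", , drop = FALSE]
  mat <- do.call(rbind, strsplit(use$aligned, ""))
  is_binder <- use$label %in% c("binder", "weak_binder")
  is_nb <- use$label == "non_binder"
  mature <- reference_mature_map(panel, reference)
  ncol_aln <- ncol(mat)
  binder_res <- character(ncol_aln)
  nb_res <- character(ncol_aln)
  diff_flag <- logical(ncol_aln)
  for (j in seq_len(ncol_aln)) {
    b <- mat[is_binder, j]
    nb <- mat[is_nb, j]
    ub <- unique(b)
    ok <- length(ub) == 1 && ub != "-" && !any(nb == ub)
    binder_res[j] <- if (length(ub) == 1) ub else paste(sort(ub), collapse = "/")
    nb_res[j] <- paste(nb, collapse = "")
    diff_flag[j] <- ok
  }
  tibble(column = seq_len(ncol_aln), mature = mature,
         binder_residue = binder_res, nonbinder_residues = nb_res,
         differential = diff_flag)
}

#' Filter candidate positions by surface exposure on a structural model
#'
#' Keeps mature positions whose relative solvent accessibility in the
#' model is at least `rsa_threshold`; positions absent from the model are
#' reported under `unmapped`, never silently dropped.
#'
#' @param positions integer vector of mature positions.
#' @param model a [structure_model()].
#' @param rsa_threshold RSA fraction in `[0, 1]` (default 0.25).
#' @param chain antigen chain id (default: first chain of the model).
#' @inheritParams compute_sasa
#' @return list with `exposed`, `buried` (tibbles: `mature`, `resno`,
#'   `resid`, `rsa`) and `unmapped` (integer vector).
#' @export
surface_filter <- function(positions, model, rsa_threshold = 0.25,
                           chain = NULL, probe = 1.4, n_points = 960) {
  stopifnot(length(positions) > 0)
  chain <- chain %||% unique(model$chain)[1]
  resno <- mature_to_author(model, chain, positions)
  present <- resno %in% model$resno[model$chain == chain]
  if (!any(present)) abort("structure is missing every queried residue")
  rsa <- relative_accessibility(model, residues = tibble(chain = chain, resno = resno[present]),
                                probe = probe, n_points = n_points)
  tab <- tibble(mature = positions[present], resno = resno[present]) %>%
    left_join(rsa %>% select("resno", "resid", "rsa"), by = "resno") %>%
    mutate(rsa = .data$rsa / 100)  # fraction, to match the threshold
  list(exposed = tab[tab$rsa >= rsa_threshold, , drop = FALSE],
       buried = tab[tab$rsa < rsa_threshold, , drop = FALSE],
       unmapped = positions[!present],
       rsa_threshold = rsa_threshold)
}

#' Cluster surface-exposed positions into patch-mutant designs
#'
#' Single-linkage clustering of representative atoms (C-beta; C-alpha for
#' glycine) at `distance_cutoff`; clusters are split deterministically by
#' ascending mature position into chunks of at most `size_range[2]`
#' residues, and chunks below `size_range[1]` are reported unpatched.
#' Donor residues come from the designated non-binder species at
#' alignment-equivalent columns; positions where the donor is gapped are
#' dropped with a warning.
#'
#' @param positions integer vector of mature positions (surface-exposed).
#' @param model a [structure_model()].
#' @param panel ortholog panel (for donor lookup).
#' @param donor_species donor (non-binder) species name.
#' @param distance_cutoff single-linkage distance (A, default 10).
#' @param size_range integer length-2, substitutions per patch (default 2-4).
#' @param chain antigen chain id in the model.
#' @param reference reference species for mature numbering.
#' @return list with `patches` (tibble: `patch`, `mature`, `ref_residue`,
#'   `donor_residue`, `donor_species`) and `unpatched` (integer vector).
#' @export
cluster_patches <- function(positions, model, panel, donor_species,
                            distance_cutoff = 10, size_range = c(2, 4),
                            chain = NULL, reference = NULL) {
  stopifnot(length(positions) > 0)
  chain <- chain %||% unique(model$chain)[1]
  reference <- panel_reference(panel, reference)
  donors <- donor_residues(panel, donor_species, positions, reference)
  gapped <- positions[is.na(donors$donor)]
  if (length(gapped) > 0) {
    warn(paste0("donor gapped at mature position(s) ", paste(gapped, collapse = ", "),
                "; dropped from patch design"))
  }
  keep <- !is.na(donors$donor)
  positions <- positions[keep]
  donors <- donors[keep, , drop = FALSE]
  if (length(positions) == 0) {
    return(list(patches = tibble(), unpatched = integer(0)))
  }
  h <- heavy_atoms(model)
  rep_atom <- purrr::map(positions, function(p) {
    rn <- mature_to_author(model, chain, p)
    res <- h[h$chain == chain & h$resno == rn, , drop = FALSE]
    if (nrow(res) == 0) abort(paste0("position ", p, " has no coordinates in chain ", chain))
    cb <- res[toupper(res$atom) == "CB", , drop = FALSE]
    if (nrow(cb) == 0) cb <- res[toupper(res$atom) %in% c("CA", "CEN"), , drop = FALSE]
    if (nrow(cb) == 0) cb <- res[1, , drop = FALSE]
    as.numeric(cb[1, c("x", "y", "z")])
  })
  xyz <- do.call(rbind, rep_atom)
  member <- if (length(positions) == 1) 1L else {
    cutree(hclust(dist(xyz), method = "single"), h = distance_cutoff)
  }
  patches <- NULL
  unpatched <- integer(0)
  pid <- 0
  for (cl in sort(unique(member))) {
    pos_cl <- sort(positions[member == cl])
    chunks <- split(pos_cl, ceiling(seq_along(pos_cl) / size_range[2]))
    for (ch_ in chunks) {
      if (length(ch_) < size_range[1]) {
        unpatched <- c(unpatched, ch_)
      } else {
        pid <- pid + 1
        patches <- bind_rows(patches, tibble(patch = paste0("P", pid), mature = ch_))
      }
    }
  }
  if (!is.null(patches)) {
    patches <- patches %>%
      left_join(donors, by = "mature") %>%
      rename(ref_residue = "ref", donor_residue = "donor") %>%
      mutate(donor_species = donor_species)
  } else {
    patches <- tibble()
  }
  list(patches = patches, unpatched = sort(unpatched))
}

# reference and donor residues at the alignment columns of mature positions
donor_residues <- function(panel, donor_species, positions, reference) {
  if (!donor_species %in% panel$species) abort(paste0("donor species '", donor_species, "' not in panel"))
  mature <- reference_mature_map(panel, reference)
  ref_chars <- strsplit(panel$aligned[panel$species == reference], "")[[1]]
  don_chars <- strsplit(panel$aligned[panel$species == donor_species], "")[[1]]
  cols <- match(positions, mature)
  if (anyNA(cols)) {
    abort(paste0("mature position(s) beyond reference sequence: ",
                 paste(positions[is.na(cols)], collapse = ", ")))
  }
  don <- don_chars[cols]
  don[don == "-"] <- NA_character_
  tibble(mature = positions, ref = ref_chars[cols], donor = don)
}

#' Propose contiguous chimera intervals from differential positions
#'
#' Maximal runs of differential positions with consecutive gaps at most
#' `max_gap` become intervals, padded symmetrically to `min_span` and
#' truncated at the right end to `max_span`. The donor interval is the
#' alignment-equivalent span in the donor species' mature numbering.
#'
#' @param positions sorted integer vector of differential mature positions.
#' @param panel ortholog panel.
#' @param donor_species donor (non-binder) species.
#' @param min_span,max_span,max_gap interval shape parameters
#'   (defaults 6, 20, 3).
#' @param reference reference species.
#' @return tibble with `id`, `ref_start`, `ref_end`, `donor_start`,
#'   `donor_end`, `donor_species`, `n_positions`.
#' @export
propose_chimeras <- function(positions, panel, donor_species,
                             min_span = 6, max_span = 20, max_gap = 3,
                             reference = NULL) {
  if (length(positions) == 0) {
    return(tibble(id = character(), ref_start = integer(), ref_end = integer(),
                  donor_start = integer(), donor_end = integer(),
                  donor_species = character(), n_positions = integer()))
  }
  reference <- panel_reference(panel, reference)
  positions <- sort(unique(as.integer(positions)))
  brk <- c(0, which(diff(positions) > max_gap), length(positions))
  runs <- purrr::map2(brk[-length(brk)] + 1, brk[-1], ~ positions[.x:.y])
  mature <- reference_mature_map(panel, reference)
  ref_len <- max(mature, na.rm = TRUE)
  don_chars <- strsplit(panel$aligned[panel$species == donor_species], "")[[1]]
  donor_mature <- cumsum(don_chars != "-")
  out <- purrr::imap(runs, function(run, i) {
    lo <- min(run); hi <- max(run)
    pad <- min_span - (hi - lo + 1)
    if (pad > 0) {
      lo <- lo - ceiling(pad / 2); hi <- hi + floor(pad / 2)
      if (lo < 1) { hi <- hi + (1 - lo); lo <- 1 }
      if (hi > ref_len) { lo <- max(1, lo - (hi - ref_len)); hi <- ref_len }
    }
    if (hi - lo + 1 > max_span) hi <- lo + max_span - 1
    cols <- match(c(lo, hi), mature)
    tibble(id = paste0("CH", i), ref_start = lo, ref_end = hi,
           donor_start = as.integer(donor_mature[cols[1]]),
           donor_end = as.integer(donor_mature[cols[2]]),
           donor_species = donor_species, n_positions = length(run))
  })
  bind_rows(out)
}
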