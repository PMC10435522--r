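#' Construct a structure model from an atom table
#'
#' A structure model is a tibble of atoms (one row per atom after altloc
#' resolution) with the class `structure_model` and an attribute
#' `mature_offsets`, a named numeric vector mapping chain id to the offset
#' between author residue numbering and mature numbering
#' (`mature = resno - offset`). Hydrogens and waters are carried but flagged
#' and excluded from every distance and surface computation by default.
#'
#' @param atoms data frame with at least `chain`, `resno`, `resid`, `atom`,
#'   `x`, `y`, `z`; optional `element`, `insert`, `occ`, `b`, `altloc`,
#'   `het`.
#' @param mature_offsets named numeric vector, chain -> numbering offset.
#' @return a `structure_model` tibble.
#' @export
structure_model <- function(atoms, mature_offsets = NULL) {
  atoms <- as_tibble(atoms)
  need <- c("chain", "resno", "resid", "atom", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    abort(paste0("atom table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("non-finite coordinates in atom table")
  }
  if (!"element" %in% names(atoms)) atoms$element <- guess_element(atoms$atom)
  if (!"insert" %in% names(atoms))  atoms$insert  <- ""
  if (!"occ" %in% names(atoms))     atoms$occ     <- 1
  if (!"b" %in% names(atoms))       atoms$b       <- 0
  if (!"altloc" %in% names(atoms))  atoms$altloc  <- ""
  if (!"het" %in% names(atoms))     atoms$het     <- FALSE
  atoms$het[is.na(atoms$het)] <- FALSE
  atoms$water    <- toupper(atoms$resid) %in% c("HOH", "WAT", "DOD", "H2O")
  atoms$hydrogen <- toupper(atoms$element) %in% c("H", "D")
  attr(atoms, "mature_offsets") <- mature_offsets
  class(atoms) <- c("structure_model", class(atoms))
  atoms
}

guess_element <- function(atom_name) {
  nm <- toupper(trimws(atom_name))
  el <- substr(gsub("[0-9']", "", nm), 1, 1)
  el[grepl("^(CL|BR|FE|ZN|MG|MN|NA|CA)$", nm)] <- substr(nm[grepl("^(CL|BR|FE|ZN|MG|MN|NA|CA)$", nm)], 1, 2)
  el[nm == "CA"] <- "C"  # protein C-alpha, not calcium, in this package's context
  el
}

#' @export
print.structure_model <- function(x, ...) {
  h <- heavy_atoms(x)
  cat("<structure_model> ", nrow(x), " atoms (", nrow(h), " heavy, non-water), chains: ",
      paste(unique(x$chain), collapse = " "), "\n", sep = "")
  NextMethod()
}

# heavy, non-water atoms: the default universe for all geometry
heavy_atoms <- function(model) {
  model[!model$hydrogen & !model$water, , drop = FALSE]
}

#' Read a structure from PDB or mmCIF
#'
#' PDB files are parsed with \pkg{bio3d}; mmCIF with a minimal `atom_site`
#' loop reader. Alternate locations are resolved to the highest-occupancy
#' conformer (ties broken by altloc letter, 'A' first). Waters and hydrogens
#' are retained but flagged; HETATM records (ligands, glycans) are kept with
#' `het = TRUE`.
#'
#' @param path file path ending in `.pdb` or `.cif` (optionally `.ent`).
#' @param mature_offsets optional named numeric vector, chain -> offset
#'   between author and mature numbering.
#' @return a [structure_model()].
#' @export
read_structure <- function(path, mature_offsets = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  ext <- tolower(tools::file_ext(path))
  atoms <- switch(ext,
    pdb = ,
    ent = read_pdb_atoms(path),
    cif = read_cif_atoms(path),
    abort(paste0("unrecognized structure format '.", ext, "' for ", path))
  )
  atoms <- resolve_altloc(atoms)
  structure_model(atoms, mature_offsets = mature_offsets)
}

read_pdb_atoms <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) abort(paste0("malformed PDB file ", path, ": ", conditionMessage(e))))
  a <- pdb$atom
  tibble(
    chain = as.character(a$chain), resno = as.integer(a$resno),
    resid = as.character(a$resid), insert = ifelse(is.na(a$insert), "", as.character(a$insert)),
    atom = as.character(a$elety),
    element = ifelse(is.na(a$elesy) | a$elesy == "", guess_element(a$elety), as.character(a$elesy)),
    x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o), b = ifelse(is.na(a$b), 0, a$b),
    altloc = ifelse(is.na(a$alt), "", as.character(a$alt)),
    het = a$type == "HETATM"
  )
}

# Minimal mmCIF reader: the _atom_site loop only, enough for deposited
# coordinate files. Field order is taken from the loop header.
read_cif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (length(hdr_idx) == 0) abort(paste0("no _atom_site loop found in ", path))
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  body_start <- max(hdr_idx) + 1
  rows <- character(0)
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "loop_") || startsWith(ln, "_")) break
    rows <- c(rows, ln)
  }
  if (length(rows) == 0) abort(paste0("empty _atom_site loop in ", path))
  mat <- do.call(rbind, strsplit(rows, "[[:space:]]+"))
  if (ncol(mat) != length(fields)) {
    abort(paste0("mmCIF _atom_site row width (", ncol(mat), ") does not match header (",
                 length(fields), ") in ", path))
  }
  colnames(mat) <- fields
  g <- function(f, alt = NULL) {
    if (f %in% fields) mat[, f] else if (!is.null(alt) && alt %in% fields) mat[, alt] else rep(NA_character_, nrow(mat))
  }
  dot_na <- function(v) ifelse(v %in% c(".", "?"), "", v)
  tibble(
    chain = dot_na(g("auth_asym_id", "label_asym_id")),
    resno = as.integer(dot_na(g("auth_seq_id", "label_seq_id"))),
    resid = dot_na(g("auth_comp_id", "label_comp_id")),
    insert = dot_na(g("pdbx_PDB_ins_code")),
    atom = gsub('"', "", dot_na(g("auth_atom_id", "label_atom_id"))),
    element = dot_na(g("type_symbol")),
    x = as.numeric(g("Cartn_x")), y = as.numeric(g("Cartn_y")), z = as.numeric(g("Cartn_z")),
    occ = suppressWarnings(as.numeric(dot_na(g("occupancy")))),
    b = suppressWarnings(as.numeric(dot_na(g("B_iso_or_equiv")))),
    altloc = dot_na(g("label_alt_id")),
    het = g("group_PDB") == "HETATM"
  ) %>%
    mutate(occ = ifelse(is.na(.data$occ), 1, .data$occ),
           b = ifelse(is.na(.data$b), 0, .data$b),
           element = ifelse(.data$element == "", guess_element(.data$atom), .data$element))
}

# keep one conformer per (chain, resno, insert, atom): highest occupancy,
# ties broken by altloc letter
resolve_altloc <- function(atoms) {
  atoms %>%
    mutate(.ord = row_number()) %>%
    arrange(.data$chain, .data$resno, .data$insert, .data$atom,
            dplyr::desc(.data$occ), .data$altloc) %>%
    distinct(.data$chain, .data$resno, .data$insert, .data$atom, .keep_all = TRUE) %>%
    arrange(.data$.ord) %>%
    select(-".ord")
}

#' Write a structure model to a PDB file
#'
#' @param model a [structure_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  m <- as_tibble(model)
  rec <- ifelse(m$het, "HETATM", "ATOM")
  lines <- sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, seq_len(nrow(m)),
                   ifelse(nchar(m$atom) < 4, paste0(" ", m$atom), m$atom), " ",
                   m$resid, m$chain, m$resno, ifelse(m$insert == "", " ", m$insert),
                   m$x, m$y, m$z, m$occ, m$b, m$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# mature numbering helpers -------------------------------------------------

chain_offset <- function(model, chain) {
  off <- attr(model, "mature_offsets")
  if (is.null(off) || is.na(off[chain] %||% NA)) 0 else unname(off[chain])
}

#' Convert author residue numbers to mature numbering (and back)
#'
#' `mature = resno - offset` where the per-chain offset is declared on the
#' model (signal-peptide length in the usual case).
#'
#' @param model a [structure_model()].
#' @param chain chain id.
#' @param resno author residue numbers.
#' @param mature mature residue numbers.
#' @return integer vector of converted positions.
#' @export
author_to_mature <- function(model, chain, resno) {
  as.integer(resno - chain_offset(model, chain))
}

#' @rdname author_to_mature
#' @export
mature_to_author <- function(model, chain, mature) {
  as.integer(mature + chain_offset(model, chain))
}

#' Group chains into complex copies by spatial proximity
#'
#' Chains whose heavy atoms approach each other within `cutoff` are placed
#' in the same group; an asymmetric unit with two copies of a complex
#' yields two groups. Single-linkage on the chain graph.
#'
#' @param model a [structure_model()].
#' @param cutoff inter-chain contact distance in Angstrom (default 5).
#' @return tibble with `chain` and `copy` (group index).
#' @export
chain_groups <- function(model, cutoff = 5) {
  h <- heavy_atoms(model)
  h <- h[!h$het, , drop = FALSE]
  chains <- unique(h$chain)
  k <- length(chains)
  if (k == 0) abort("no polymer chains in model")
  adj <- diag(TRUE, k)
  if (k > 1) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      a <- as.matrix(h[h$chain == chains[i], c("x", "y", "z")])
      b <- as.matrix(h[h$chain == chains[j], c("x", "y", "z")])
      adj[i, j] <- adj[j, i] <- min_cross_dist(a, b) <= cutoff
    }
  }
  # connected components by repeated expansion
  comp <- rep(NA_integer_, k)
  cur <- 0
  for (i in seq_len(k)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1
    frontier <- i
    comp[i] <- cur
    while (length(frontier) > 0) {
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & is.na(comp))
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  tibble(chain = chains, copy = comp)
}

min_cross_dist <- function(a, b) {
  # chunked to keep memory flat on big chains
  best <- Inf
  step <- 2000
  for (s in seq(1, nrow(a), by = step)) {
    aa <- a[s:min(s + step - 1, nrow(a)), , drop = FALSE]
    d2 <- outer(rowSums(aa^2), rep(1, nrow(b))) +
      outer(rep(1, nrow(aa)), rowSums(b^2)) - 2 * aa %*% t(b)
    best <- min(best, sqrt(max(0, min(d2))))
  }
  best
}
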