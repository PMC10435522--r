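# Antibody-antigen interface delineation: contacts, buried surface area,
# hydrogen bonds, disulfides, substitution impact, assembly span.

check_partition <- function(model, antigen_chains, antibody_chains) {
  if (length(antigen_chains) == 0 || length(antibody_chains) == 0) {
    abort("both partition sides must be non-empty")
  }
  if (length(intersect(antigen_chains, antibody_chains)) > 0) {
    abort("partition sides overlap: chains must be disjoint")
  }
  present <- unique(model$chain)
  miss <- setdiff(c(antigen_chains, antibody_chains), present)
  if (length(miss) > 0) {
    abort(paste0("partition chain(s) absent from model: ", paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Cross-interface atomic contacts and the epitope/paratope they define
#'
#' A residue pair is in contact when any heavy-atom pair across the
#' partition is within `cutoff` (inclusive). Antigen-side residues of at
#' least one contact form the epitope; antibody-side residues the paratope.
#'
#' @param model a [structure_model()].
#' @param antigen_chains,antibody_chains character vectors of chain ids.
#' @param cutoff contact distance in Angstrom, inclusive (default 3.8).
#' @return list with `pairs` (atom-level tibble with distances), `epitope`
#'   and `paratope` residue tibbles (author + mature numbering).
#' @export
interface_contacts <- function(model, antigen_chains, antibody_chains, cutoff = 3.8) {
  check_partition(model, antigen_chains, antibody_chains)
  h <- heavy_atoms(model)
  ag <- h[h$chain %in% antigen_chains, , drop = FALSE]
  ab <- h[h$chain %in% antibody_chains, , drop = FALSE]
  if (nrow(ag) == 0 || nrow(ab) == 0) abort("empty partition side after heavy-atom filtering")
  A <- as.matrix(ag[, c("x", "y", "z")])
  B <- as.matrix(ab[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  pairs <- tibble(
    chain_ag = ag$chain[hit[, 1]], resno_ag = ag$resno[hit[, 1]],
    resid_ag = ag$resid[hit[, 1]], atom_ag = ag$atom[hit[, 1]],
    chain_ab = ab$chain[hit[, 2]], resno_ab = ab$resno[hit[, 2]],
    resid_ab = ab$resid[hit[, 2]], atom_ab = ab$atom[hit[, 2]],
    distance = sqrt(pmax(0, d2[hit]))
  ) %>% arrange(.data$chain_ag, .data$resno_ag, .data$chain_ab, .data$resno_ab, .data$distance)
  epitope <- pairs %>%
    distinct(chain = .data$chain_ag, resno = .data$resno_ag, resid = .data$resid_ag) %>%
    mutate(mature = purrr::map2_int(.data$chain, .data$resno, ~ author_to_mature(model, .x, .y))) %>%
    arrange(.data$chain, .data$resno)
  paratope <- pairs %>%
    distinct(chain = .data$chain_ab, resno = .data$resno_ab, resid = .data$resid_ab) %>%
    mutate(mature = purrr::map2_int(.data$chain, .data$resno, ~ author_to_mature(model, .x, .y))) %>%
    arrange(.data$chain, .data$resno)
  list(pairs = pairs, epitope = epitope, paratope = paratope, cutoff = cutoff)
}

#' Buried surface area of an interface
#'
#' BSA = SASA(antigen alone) + SASA(antibody alone) - SASA(complex),
#' reported in total and per residue (delta-SASA). Burial fraction is
#' delta-SASA over the free-state residue SASA; residues exceeding
#' `burial_flag` are flagged as interface cores.
#'
#' @inheritParams interface_contacts
#' @param probe probe radius (A).
#' @param n_points quadrature points per atom.
#' @param burial_flag burial-fraction threshold for flagging (default 0.75).
#' @return list of class `interface_report` section: `total_bsa` (A^2) and
#'   `residues` tibble (side, chain, resno, resid, mature, sasa_free,
#'   sasa_complex, dsasa, burial_fraction, core).
#' @export
buried_surface_area <- function(model, antigen_chains, antibody_chains,
                                probe = 1.4, n_points = 960, burial_flag = 0.75) {
  check_partition(model, antigen_chains, antibody_chains)
  sub_model <- function(chains) {
    m <- model[model$chain %in% chains, , drop = FALSE]
    attr(m, "mature_offsets") <- attr(model, "mature_offsets")
    class(m) <- class(model)
    m
  }
  both <- sub_model(c(antigen_chains, antibody_chains))
  free_ag <- residue_sasa(sub_model(antigen_chains), probe = probe, n_points = n_points)
  free_ab <- residue_sasa(sub_model(antibody_chains), probe = probe, n_points = n_points)
  cplx <- residue_sasa(both, probe = probe, n_points = n_points)
  free <- bind_rows(
    mutate(free_ag, side = "antigen"),
    mutate(free_ab, side = "antibody")
  ) %>% rename(sasa_free = "sasa")
  res <- free %>%
    left_join(cplx %>% select("chain", "resno", "insert", sasa_complex = "sasa"),
              by = c("chain", "resno", "insert")) %>%
    mutate(dsasa = .data$sasa_free - .data$sasa_complex)
  if (any(res$dsasa < -1e-6)) {
    neg <- sum(res$dsasa < -1e-6)
    warn(paste0(neg, " residue(s) with negative delta-SASA (quadrature noise); clamped to 0"))
  }
  res$dsasa <- pmax(0, res$dsasa)
  res$burial_fraction <- ifelse(res$sasa_free > 0, res$dsasa / res$sasa_free, 0)
  res$core <- res$burial_fraction > burial_flag
  res <- res %>%
    select("side", "chain", "resno", "resid", "mature", "sasa_free",
           "sasa_complex", "dsasa", "burial_fraction", "core") %>%
    arrange(.data$side, .data$chain, .data$resno)
  list(total_bsa = sum(res$dsasa), residues = res,
       probe = probe, n_points = n_points, burial_flag = burial_flag)
}

#' Disulfide bridges
#'
#' Cysteine pairs with an Sg-Sg distance at or below `cutoff`; each Sg
#' participates in at most one pair (nearest wins).
#'
#' @param model a [structure_model()].
#' @param cutoff Sg-Sg distance in Angstrom (default 2.3).
#' @return tibble with both partners in author and mature numbering plus the
#'   Sg-Sg distance.
#' @export
find_disulfides <- function(model, cutoff = 2.3) {
  h <- heavy_atoms(model)
  sg <- h[toupper(h$resid) == "CYS" & toupper(h$atom) == "SG", , drop = FALSE]
  empty <- tibble(chain1 = character(), resno1 = integer(), mature1 = integer(),
                  chain2 = character(), resno2 = integer(), mature2 = integer(),
                  distance = numeric())
  if (nrow(sg) < 2) return(empty)
  X <- as.matrix(sg[, c("x", "y", "z")])
  D <- as.matrix(dist(X))
  D[upper.tri(D, diag = TRUE)] <- Inf
  cand <- which(D <= cutoff, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  cand <- cand[order(D[cand]), , drop = FALSE]
  used <- logical(nrow(sg))
  keep <- matrix(0L, 0, 2)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used[i] && !used[j]) {
      keep <- rbind(keep, c(j, i))  # lower resno first by construction of dist order below
      used[i] <- used[j] <- TRUE
    }
  }
  out <- tibble(
    chain1 = sg$chain[keep[, 1]], resno1 = sg$resno[keep[, 1]],
    chain2 = sg$chain[keep[, 2]], resno2 = sg$resno[keep[, 2]],
    distance = D[cbind(keep[, 2], keep[, 1])]
  ) %>%
    mutate(mature1 = purrr::map2_int(.data$chain1, .data$resno1, ~ author_to_mature(model, .x, .y)),
           mature2 = purrr::map2_int(.data$chain2, .data$resno2, ~ author_to_mature(model, .x, .y))) %>%
    select("chain1", "resno1", "mature1", "chain2", "resno2", "mature2", "distance")
  # order partners within a pair by (chain, resno)
  swap <- out$chain1 > out$chain2 | (out$chain1 == out$chain2 & out$resno1 > out$resno2)
  if (any(swap)) {
    tmp <- out[swap, ]
    out[swap, c("chain1", "resno1", "mature1")] <- tmp[, c("chain2", "resno2", "mature2")]
    out[swap, c("chain2", "resno2", "mature2")] <- tmp[, c("chain1", "resno1", "mature1")]
  }
  arrange(out, .data$chain1, .data$resno1)
}

hb_role_atoms <- function(resid, atom, role = c("donor", "acceptor")) {
  role <- match.arg(role)
  resid <- toupper(resid); atom <- toupper(atom)
  if (role == "donor") {
    backbone <- atom == "N" & resid != "PRO"
    side <- purrr::map2_lgl(resid, atom, function(r, a) a %in% (HB_DONORS[[r]] %||% character(0)))
  } else {
    backbone <- atom %in% c("O", "OXT")
    side <- purrr::map2_lgl(resid, atom, function(r, a) a %in% (HB_ACCEPTORS[[r]] %||% character(0)))
  }
  backbone | side
}

#' Hydrogen bonds across an interface
#'
#' Donor-acceptor heavy-atom pairs (N/O/S from per-residue role tables)
#' within `cutoff`; no angular criterion, since deposited structures at
#' typical resolution carry no hydrogens.
#'
#' @inheritParams interface_contacts
#' @param cutoff donor-acceptor distance in Angstrom (default 3.5).
#' @return tibble of donor/acceptor atoms with residue identity on both
#'   sides and the distance.
#' @export
find_hbonds <- function(model, antigen_chains, antibody_chains, cutoff = 3.5) {
  check_partition(model, antigen_chains, antibody_chains)
  h <- heavy_atoms(model)
  side <- function(chains) h[h$chain %in% chains & !h$het, , drop = FALSE]
  ag <- side(antigen_chains); ab <- side(antibody_chains)
  one_direction <- function(don, acc) {
    d_ok <- hb_role_atoms(don$resid, don$atom, "donor")
    a_ok <- hb_role_atoms(acc$resid, acc$atom, "acceptor")
    don <- don[d_ok, , drop = FALSE]; acc <- acc[a_ok, , drop = FALSE]
    if (nrow(don) == 0 || nrow(acc) == 0) return(NULL)
    D <- as.matrix(don[, c("x", "y", "z")]); A <- as.matrix(acc[, c("x", "y", "z")])
    d2 <- outer(rowSums(D^2), rep(1, nrow(A))) +
      outer(rep(1, nrow(D)), rowSums(A^2)) - 2 * D %*% t(A)
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hit) == 0) return(NULL)
    tibble(
      donor_chain = don$chain[hit[, 1]], donor_resno = don$resno[hit[, 1]],
      donor_resid = don$resid[hit[, 1]], donor_atom = don$atom[hit[, 1]],
      acceptor_chain = acc$chain[hit[, 2]], acceptor_resno = acc$resno[hit[, 2]],
      acceptor_resid = acc$resid[hit[, 2]], acceptor_atom = acc$atom[hit[, 2]],
      distance = sqrt(pmax(0, d2[hit]))
    )
  }
  out <- bind_rows(one_direction(ag, ab), one_direction(ab, ag))
  if (nrow(out) == 0) return(out)
  arrange(out, .data$donor_chain, .data$donor_resno, .data$distance)
}

#' Full interface report
#'
#' Convenience wrapper combining [interface_contacts()],
#' [buried_surface_area()], [find_hbonds()] and [find_disulfides()] into
#' one object with tidy/glance/autoplot methods.
#'
#' @inheritParams buried_surface_area
#' @param contact_cutoff contact distance (A, default 3.8).
#' @param hbond_cutoff donor-acceptor distance (A, default 3.5).
#' @param ss_cutoff disulfide Sg-Sg distance (A, default 2.3).
#' @return object of class `interface_report`.
#' @export
interface_report <- function(model, antigen_chains, antibody_chains,
                             contact_cutoff = 3.8, probe = 1.4, n_points = 960,
                             burial_flag = 0.75, hbond_cutoff = 3.5, ss_cutoff = 2.3) {
  ct <- interface_contacts(model, antigen_chains, antibody_chains, cutoff = contact_cutoff)
  bsa <- buried_surface_area(model, antigen_chains, antibody_chains,
                             probe = probe, n_points = n_points, burial_flag = burial_flag)
  hb <- find_hbonds(model, antigen_chains, antibody_chains, cutoff = hbond_cutoff)
  ss <- find_disulfides(model, cutoff = ss_cutoff)
  out <- list(
    epitope = ct$epitope, paratope = ct$paratope, contacts = ct$pairs,
    total_bsa = bsa$total_bsa, residues = bsa$residues,
    hbonds = hb, disulfides = ss,
    config = list(contact_cutoff = contact_cutoff, probe = probe,
                  n_points = n_points, burial_flag = burial_flag,
                  hbond_cutoff = hbond_cutoff, ss_cutoff = ss_cutoff,
                  rsa_reference = "theoretical-max-GXG",
                  antigen_chains = antigen_chains, antibody_chains = antibody_chains)
  )
  class(out) <- "interface_report"
  out
}

#' @export
print.interface_report <- function(x, ...) {
  cat("<interface_report>\n")
  cat("  epitope:  ", nrow(x$epitope), " residues\n", sep = "")
  cat("  paratope: ", nrow(x$paratope), " residues\n", sep = "")
  cat("  total BSA: ", round(x$total_bsa, 1), " A^2\n", sep = "")
  cat("  H-bonds: ", nrow(x$hbonds), "; disulfides: ", nrow(x$disulfides), "\n", sep = "")
  invisible(x)
}

#' Impact of a residue substitution on the interface
#'
#' Common-atom truncation model: side-chain heavy atoms (canonical order)
#' beyond the first `min(n_old, n_new)` are deleted, and interface contacts
#' involving deleted atoms are counted lost. A clash is flagged when, under
#' idealized chi1 sampling (rotation of atoms distal to C-beta about the
#' CA-CB axis through 0/60/-60/180 degrees), any retained side-chain atom
#' approaches a cross-interface atom below `clash_factor` times the sum of
#' vdW radii.
#'
#' @param model a [structure_model()].
#' @param chain,resno site of the substitution (author numbering).
#' @param new_resid three-letter code of the substituting residue type.
#' @param antigen_chains,antibody_chains interface partition.
#' @param cutoff contact cutoff (A).
#' @param clash_factor fraction of summed vdW radii defining a clash.
#' @return list: `deleted_atoms`, `lost_contacts` (count),
#'   `lost_contact_pairs` (tibble), `clash` (logical), `clash_pairs`.
#' @export
substitution_impact <- function(model, chain, resno, new_resid,
                                antigen_chains, antibody_chains,
                                cutoff = 3.8, clash_factor = 0.8) {
  site <- heavy_atoms(model)
  site <- site[site$chain == chain & site$resno == resno, , drop = FALSE]
  if (nrow(site) == 0) abort(paste0("site ", chain, ":", resno, " absent from model"))
  old_resid <- toupper(site$resid[1])
  if (old_resid == "GLY") abort("substitution_impact: glycine has no side chain")
  new_resid <- toupper(new_resid)
  old_sc <- SIDECHAIN_ATOMS[[old_resid]] %||% abort(paste0("unknown residue type ", old_resid))
  new_sc <- SIDECHAIN_ATOMS[[new_resid]] %||% abort(paste0("unknown residue type ", new_resid))
  n_keep <- min(length(old_sc), length(new_sc))
  deleted <- old_sc[seq_along(old_sc) > n_keep]
  deleted <- deleted[deleted %in% site$atom]

  ct <- interface_contacts(model, antigen_chains, antibody_chains, cutoff = cutoff)
  on_antigen <- chain %in% antigen_chains
  p <- ct$pairs
  if (on_antigen) {
    lost <- p[p$chain_ag == chain & p$resno_ag == resno & p$atom_ag %in% deleted, , drop = FALSE]
  } else {
    lost <- p[p$chain_ab == chain & p$resno_ab == resno & p$atom_ab %in% deleted, , drop = FALSE]
  }

  # chi1 sampling of retained atoms distal to CB about the CA-CB axis
  clash_pairs <- NULL
  kept_names <- old_sc[seq_len(n_keep)]
  distal <- setdiff(kept_names, "CB")
  ca <- site[site$atom == "CA", c("x", "y", "z")]
  cb <- site[site$atom == "CB", c("x", "y", "z")]
  other_side <- heavy_atoms(model)
  opp_chains <- if (on_antigen) antibody_chains else antigen_chains
  other_side <- other_side[other_side$chain %in% opp_chains, , drop = FALSE]
  if (nrow(ca) == 1 && nrow(cb) == 1 && length(distal) > 0 && nrow(other_side) > 0) {
    axis_o <- as.numeric(ca[1, ]); axis_p <- as.numeric(cb[1, ])
    mobile <- site[site$atom %in% distal, , drop = FALSE]
    oxyz <- as.matrix(other_side[, c("x", "y", "z")])
    orad <- vdw_radius(other_side$element)
    mrad <- vdw_radius(mobile$element)
    for (ang in c(0, 60, -60, 180) * pi / 180) {
      rot <- rotate_about_axis(as.matrix(mobile[, c("x", "y", "z")]), axis_o, axis_p, ang)
      d <- sqrt(outer(rowSums(rot^2), rep(1, nrow(oxyz))) +
                  outer(rep(1, nrow(rot)), rowSums(oxyz^2)) - 2 * rot %*% t(oxyz))
      lim <- outer(mrad, orad, "+") * clash_factor
      hit <- which(d < lim, arr.ind = TRUE)
      if (nrow(hit) > 0) {
        clash_pairs <- bind_rows(clash_pairs, tibble(
          atom = mobile$atom[hit[, 1]],
          other_chain = other_side$chain[hit[, 2]],
          other_resno = other_side$resno[hit[, 2]],
          other_atom = other_side$atom[hit[, 2]],
          chi1_deg = round(ang * 180 / pi),
          distance = d[hit]
        ))
      }
    }
  }
  list(
    site = paste0(chain, ":", resno, " ", old_resid, "->", new_resid),
    deleted_atoms = deleted,
    lost_contacts = nrow(lost),
    lost_contact_pairs = lost,
    clash = !is.null(clash_pairs) && nrow(clash_pairs) > 0,
    clash_pairs = clash_pairs %||% tibble()
  )
}

# rotate points about the axis through `origin` toward `point` by angle (rad)
rotate_about_axis <- function(xyz, origin, point, angle) {
  u <- point - origin
  u <- u / sqrt(sum(u^2))
  c_ <- cos(angle); s_ <- sin(angle)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) * c_ + s_ * K + (1 - c_) * (u %*% t(u))
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, "+")
}

#' Distance between two anchor residues of an assembly
#'
#' Euclidean distance between the C-alpha atoms of two anchors, e.g. the
#' membrane-proximal termini of the two target chains engaged by a
#' bispecific antibody.
#'
#' @param model a [structure_model()].
#' @param anchor_a,anchor_b lists `list(chain =, resno =)`.
#' @return named list with `distance` (A) and the anchor identities.
#' @export
assembly_span <- function(model, anchor_a, anchor_b) {
  get_ca <- function(an) {
    h <- heavy_atoms(model)
    ca <- h[h$chain == an$chain & h$resno == an$resno & toupper(h$atom) == "CA", , drop = FALSE]
    if (nrow(ca) == 0) abort(paste0("anchor ", an$chain, ":", an$resno, " has no C-alpha in model"))
    as.numeric(ca[1, c("x", "y", "z")])
  }
  a <- get_ca(anchor_a); b <- get_ca(anchor_b)
  list(distance = sqrt(sum((a - b)^2)), anchor_a = anchor_a, anchor_b = anchor_b)
}
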