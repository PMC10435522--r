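# Shrake-Rupley solvent-accessible surface area with a deterministic
# golden-spiral quadrature. Hydrogens and waters never enter the sphere set.

# deterministic, approximately uniform unit-sphere point set
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# core quadrature: xyz (n x 3), radii (n), returns per-atom SASA (A^2)
sasa_core <- function(xyz, radii, probe = 1.4, n_points = 960) {
  n <- nrow(xyz)
  if (n == 0) return(numeric(0))
  pts <- sphere_points(n_points)
  rr <- radii + probe
  out <- numeric(n)
  # neighbor lists via squared-distance threshold, chunked
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 + (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rr + rr[i])^2 & d2 > 0)
    if (length(nb) == 0) {
      out[i] <- 4 * pi * rr[i]^2
      next
    }
    p <- pts * rr[i]
    p[, 1] <- p[, 1] + xyz[i, 1]; p[, 2] <- p[, 2] + xyz[i, 2]; p[, 3] <- p[, 3] + xyz[i, 3]
    nbx <- xyz[nb, , drop = FALSE]
    # points buried if inside any neighbor's probe-expanded sphere
    d2p <- outer(rowSums(p^2), rep(1, length(nb))) +
      outer(rep(1, n_points), rowSums(nbx^2)) - 2 * p %*% t(nbx)
    buried <- rowSums(sweep(d2p, 2, rr[nb]^2, "<")) > 0
    out[i] <- 4 * pi * rr[i]^2 * mean(!buried)
  }
  out
}

#' Solvent-accessible surface area per atom
#'
#' Shrake-Rupley quadrature over a deterministic golden-spiral point set.
#' Hydrogens and waters are excluded from both the evaluated set and the
#' occluding sphere set.
#'
#' @param model a [structure_model()].
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points quadrature points per atom (default 960).
#' @param radius_default radius for elements missing from the vdW table.
#' @return the heavy-atom tibble with a `sasa` column (A^2).
#' @export
compute_sasa <- function(model, probe = 1.4, n_points = 960, radius_default = 1.8) {
  h <- heavy_atoms(model)
  if (nrow(h) == 0) abort("no heavy, non-water atoms in model")
  xyz <- as.matrix(h[, c("x", "y", "z")])
  radii <- vdw_radius(h$element, default = radius_default)
  h$sasa <- sasa_core(xyz, radii, probe = probe, n_points = n_points)
  as_tibble(h)
}

#' Solvent-accessible surface area per residue
#'
#' @inheritParams compute_sasa
#' @return tibble with `chain`, `resno`, `resid`, `mature`, `sasa`.
#' @export
residue_sasa <- function(model, probe = 1.4, n_points = 960, radius_default = 1.8) {
  per_atom <- compute_sasa(model, probe = probe, n_points = n_points,
                           radius_default = radius_default)
  per_atom %>%
    group_by(.data$chain, .data$resno, .data$insert, .data$resid) %>%
    summarise(sasa = sum(.data$sasa), .groups = "drop") %>%
    mutate(mature = purrr::map2_int(.data$chain, .data$resno,
                                    ~ author_to_mature(model, .x, .y)))
}

#' Relative solvent accessibility of residues
#'
#' Residue SASA divided by the type-specific theoretical maximum
#' (Gly-X-Gly reference set), in percent. The reference-set id is recorded
#' on the output.
#'
#' @param model a [structure_model()].
#' @param residues optional tibble with `chain` and `resno` restricting the
#'   output; default all residues.
#' @inheritParams compute_sasa
#' @return tibble with `chain`, `resno`, `resid`, `mature`, `sasa`,
#'   `max_asa`, `rsa` (percent); attribute `reference_set`.
#' @export
relative_accessibility <- function(model, residues = NULL, probe = 1.4,
                                   n_points = 960, radius_default = 1.8) {
  rs <- residue_sasa(model, probe = probe, n_points = n_points,
                     radius_default = radius_default)
  if (!is.null(residues)) {
    rs <- dplyr::semi_join(rs, as_tibble(residues), by = c("chain", "resno"))
    if (nrow(rs) == 0) abort("none of the requested residues are present in the model")
  }
  one <- aa_three_to_one(rs$resid)
  if (any(one == "X")) {
    bad <- unique(rs$resid[one == "X"])
    abort(paste0("unknown residue type(s) for RSA: ", paste(bad, collapse = ", ")))
  }
  rs$max_asa <- unname(MAX_ASA_TIEN[one])
  rs$rsa <- 100 * rs$sasa / rs$max_asa
  attr(rs, "reference_set") <- "theoretical-max-GXG"
  rs
}

#' Analytic SASA oracle for two intersecting spheres
#'
#' Closed-form spherical-cap areas of two probe-inflated spheres; used to
#' validate the numeric quadrature.
#'
#' @param r1,r2 van der Waals radii (A) of the two atoms.
#' @param d center-center distance (A).
#' @param probe probe radius (A).
#' @return named numeric vector `c(area1, area2)` of exposed areas (A^2).
#' @export
two_sphere_sasa_oracle <- function(r1, r2, d, probe = 1.4) {
  stopifnot(r1 > 0, r2 > 0, probe > 0, d >= 0)
  R1 <- r1 + probe
  R2 <- r2 + probe
  full <- c(area1 = 4 * pi * R1^2, area2 = 4 * pi * R2^2)
  if (d >= R1 + R2) return(full)
  if (d == 0 && R1 == R2) {
    abort("degenerate coincident spheres of equal radius")
  }
  if (d + R1 <= R2) return(c(area1 = 0, area2 = full[["area2"]]))
  if (d + R2 <= R1) return(c(area1 = full[["area1"]], area2 = 0))
  # intersecting: cap height h_i = R_i - (d^2 + R_i^2 - R_j^2) / (2 d)
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  c(area1 = 4 * pi * R1^2 - 2 * pi * R1 * h1,
    area2 = 4 * pi * R2^2 - 2 * pi * R2 * h2)
}
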