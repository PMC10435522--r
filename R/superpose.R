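# Least-squares rigid-body superposition (Kabsch) with optional iterative
# trimming of poorly fitting pairs.

# P, Q: n x 3 matrices of paired coordinates; returns rotation (applied to
# P after centering), translation, and RMSD of R %*% P + t vs Q
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), nrow(P) >= 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cq - as.numeric(R %*% cp)
  fitted <- sweep(P %*% t(R), 2, t_vec, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd, fitted = fitted)
}

ca_table <- function(model) {
  h <- heavy_atoms(model)
  h <- h[toupper(h$atom) == "CA" & !h$het, , drop = FALSE]
  h[, c("chain", "resno", "resid", "x", "y", "z")]
}

pair_by_numbering <- function(ca_a, ca_b, chain_map) {
  ca_a$chain_b <- unname(chain_map[ca_a$chain])
  merged <- merge(ca_a, ca_b, by.x = c("chain_b", "resno"), by.y = c("chain", "resno"),
                  suffixes = c("_a", "_b"))
  merged[order(merged$chain_b, merged$resno), , drop = FALSE]
}

pair_by_alignment <- function(ca_a, ca_b, chain_map) {
  out <- NULL
  for (ch in names(chain_map)) {
    a <- ca_a[ca_a$chain == ch, , drop = FALSE]
    b <- ca_b[ca_b$chain == chain_map[[ch]], , drop = FALSE]
    if (nrow(a) == 0 || nrow(b) == 0) next
    sa <- paste(aa_three_to_one(a$resid), collapse = "")
    sb <- paste(aa_three_to_one(b$resid), collapse = "")
    al <- Biostrings::pairwiseAlignment(sa, sb, type = "global",
                                        substitutionMatrix = "BLOSUM62",
                                        gapOpening = 10, gapExtension = 0.5)
    pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    ia <- cumsum(pa != "-"); ib <- cumsum(pb != "-")
    keep <- pa != "-" & pb != "-"
    idx_a <- ia[keep]; idx_b <- ib[keep]
    m <- cbind(a[idx_a, c("x", "y", "z")], b[idx_b, c("x", "y", "z")])
    names(m) <- c("x_a", "y_a", "z_a", "x_b", "y_b", "z_b")
    m$chain_b <- chain_map[[ch]]; m$resno <- b$resno[idx_b]
    out <- rbind(out, m)
  }
  out
}

#' Superpose two structures on corresponding C-alpha atoms
#'
#' Correspondence is by identical chain mapping and residue number
#' (`correspondence = "numbering"`) or by per-chain global sequence
#' alignment when numbering differs (`"alignment"`). Optional iterative
#' trimming drops pairs deviating more than `trim_factor` times the current
#' RMSD, re-fits, and repeats until stable, `max_cycles` reached, or the
#' pair count would fall below `min_frac` of the initial pairs.
#'
#' @param model_a,model_b [structure_model()] objects.
#' @param chain_map named character vector mapping chains of `model_a` to
#'   chains of `model_b`; default identity over shared chain ids.
#' @param correspondence `"numbering"` or `"alignment"`.
#' @param trim logical; iterative trimming (default FALSE).
#' @param trim_factor multiple of current RMSD beyond which pairs drop.
#' @param max_cycles maximum trimming cycles (default 5).
#' @param min_frac floor on retained pairs as a fraction of initial pairs.
#' @return object of class `superposition`: rotation, translation, `rmsd`,
#'   `n_pairs`, `cycles`, and per-pair deviations of the final fit.
#' @export
superpose <- function(model_a, model_b, chain_map = NULL,
                      correspondence = c("numbering", "alignment"),
                      trim = FALSE, trim_factor = 2, max_cycles = 5, min_frac = 0.5) {
  correspondence <- match.arg(correspondence)
  ca_a <- ca_table(model_a); ca_b <- ca_table(model_b)
  if (is.null(chain_map)) {
    shared <- intersect(unique(ca_a$chain), unique(ca_b$chain))
    if (length(shared) == 0) abort("no shared chain ids; provide chain_map")
    chain_map <- setNames(shared, shared)
  }
  pairs <- if (correspondence == "numbering") {
    pair_by_numbering(ca_a, ca_b, chain_map)
  } else {
    pair_by_alignment(ca_a, ca_b, chain_map)
  }
  if (is.null(pairs) || nrow(pairs) < 3) abort("fewer than 3 corresponding C-alpha pairs")
  P <- as.matrix(pairs[, c("x_a", "y_a", "z_a")])
  Q <- as.matrix(pairs[, c("x_b", "y_b", "z_b")])
  n0 <- nrow(P)
  keep <- rep(TRUE, n0)
  fit <- kabsch(P, Q)
  cycles <- 0
  if (trim) {
    for (cyc in seq_len(max_cycles)) {
      dev <- sqrt(rowSums((fit$fitted - Q[keep, , drop = FALSE])^2))
      drop_these <- dev > trim_factor * fit$rmsd
      if (!any(drop_these)) break
      new_keep <- keep
      new_keep[which(keep)[drop_these]] <- FALSE
      if (sum(new_keep) < max(3, ceiling(min_frac * n0))) break
      keep <- new_keep
      fit <- kabsch(P[keep, , drop = FALSE], Q[keep, , drop = FALSE])
      cycles <- cyc
    }
  }
  dev <- sqrt(rowSums((fit$fitted - Q[keep, , drop = FALSE])^2))
  out <- list(rotation = fit$rotation, translation = fit$translation,
              rmsd = fit$rmsd, n_pairs = sum(keep), n_initial = n0,
              cycles = cycles, deviations = dev)
  class(out) <- "superposition"
  out
}

#' @export
print.superposition <- function(x, ...) {
  cat("<superposition> RMSD ", signif(x$rmsd, 4), " A over ", x$n_pairs,
      " C-alpha pairs (", x$n_initial, " initial, ", x$cycles, " trim cycles)\n", sep = "")
  invisible(x)
}

#' Brute-force rotation-search RMSD oracle
#'
#' Independent check of the closed-form superposition: optimizes RMSD over
#' rotations parameterized by Euler angles, a coarse grid followed by local
#' refinement. Intended for small point sets in tests.
#'
#' @param P,Q n x 3 matrices of paired points.
#' @param grid_n grid resolution per angle.
#' @return minimal RMSD found.
#' @export
rmsd_rotation_search <- function(P, Q, grid_n = 24) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  euler_R <- function(a, b, g) {
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
    Rz2 <- matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(ang) {
    R <- euler_R(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  best <- Inf; best_ang <- c(0, 0, 0)
  as_ <- seq(0, 2 * pi, length.out = grid_n + 1)[-(grid_n + 1)]
  bs_ <- seq(0, pi, length.out = max(2, grid_n %/% 2))
  for (a in as_) for (b in bs_) for (g in as_) {
    v <- obj(c(a, b, g))
    if (v < best) { best <- v; best_ang <- c(a, b, g) }
  }
  ref <- stats::optim(best_ang, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  min(best, ref$value)
}
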