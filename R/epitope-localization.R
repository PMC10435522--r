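# Tiling-peptide epitope localization: tile generation, positivity calls,
# interval intersection, competition curves, and evidence integration.

#' Generate overlapping tiling peptides
#'
#' Tiles of `length` residues at every `step` offset over a coverage
#' interval in precursor coordinates; tile k starts at
#' `coverage[1] + step * (k - 1)`. A final truncated tile is added when the
#' full-length tiles do not reach the coverage end. Both precursor and
#' mature coordinates are populated (`mature = precursor - offset`; mature
#' values of zero or below fall inside the signal peptide).
#'
#' @param sequence precursor amino-acid sequence covering the coverage
#'   interval.
#' @param length peptide length in residues (default 20).
#' @param step start-to-start offset (default 5, i.e. overlap 15).
#' @param coverage precursor interval covered (default the full sequence).
#' @param offset signal-peptide offset (mature 1 = precursor offset + 1).
#' @return tibble with `tile`, `start`, `end`, `mature_start`,
#'   `mature_end`, `sequence`.
#' @export
tile_peptides <- function(sequence, length = 20, step = 5,
                          coverage = NULL, offset = 0) {
  if (step < 1 || step > length) abort("step must satisfy 1 <= step <= length")
  L <- nchar(sequence)
  coverage <- coverage %||% c(1, L)
  if (coverage[1] < 1 || coverage[1] > coverage[2]) abort("coverage interval is empty or invalid")
  if (coverage[2] > L) abort("coverage extends beyond sequence end")
  starts <- seq(coverage[1], coverage[2] - length + 1, by = step)
  ends <- starts + length - 1
  if (max(ends) < coverage[2]) {
    starts <- c(starts, max(starts) + step)
    ends <- c(ends, coverage[2])
  }
  tibble(
    tile = seq_along(starts), start = as.integer(starts), end = as.integer(ends),
    mature_start = as.integer(starts - offset), mature_end = as.integer(ends - offset),
    sequence = substring(sequence, starts, ends)
  )
}

#' Call peptide positivity against plate background
#'
#' A tile is positive when its signal is at least `fold` times the
#' background mean AND at least `z` background standard deviations above
#' the background mean; both component criteria are recorded.
#'
#' @param signals tibble with `tile` and `signal`.
#' @param background_mean,background_sd,background_n background statistics
#'   from no-antigen/control wells (`background_n >= 2` required when the
#'   sd is used).
#' @param fold fold-over-background threshold (default 3).
#' @param z z-score threshold (default 5).
#' @return the signal tibble with `fold_pass`, `z_pass`, `positive`.
#' @export
classify_peptide_binding <- function(signals, background_mean, background_sd,
                                     background_n = 2, fold = 3, z = 5) {
  if (background_mean <= 0) abort("background mean must be positive")
  if (background_n < 2) abort("need at least 2 background wells for an sd")
  signals <- as_tibble(signals)
  signals %>%
    mutate(fold_pass = .data$signal >= fold * background_mean,
           z_pass = .data$signal >= background_mean + z * background_sd,
           positive = .data$fold_pass & .data$z_pass)
}

#' Localize the epitope from positive tiles
#'
#' For each block of mutually overlapping positive tiles: the intersection
#' of their mature intervals (the minimal epitope-containing region) and
#' their union. Non-contiguous positive blocks are reported separately and
#' flagged multi-site, never merged.
#'
#' @param tiles tibble of positive tiles with `mature_start`,
#'   `mature_end` (e.g. filtered output of [classify_peptide_binding()]
#'   joined to [tile_peptides()]).
#' @return tibble with one row per block: `block`, `n_tiles`,
#'   `intersection_start`, `intersection_end`, `union_start`, `union_end`;
#'   attribute `multi_site`.
#' @export
localize_from_tiles <- function(tiles) {
  tiles <- as_tibble(tiles)
  if (nrow(tiles) == 0) abort("no positive tiles to localize from")
  tiles <- arrange(tiles, .data$mature_start)
  block <- integer(nrow(tiles))
  block[1] <- 1L
  run_end <- tiles$mature_end[1]
  for (i in seq_len(nrow(tiles))[-1]) {
    if (tiles$mature_start[i] <= run_end) {
      block[i] <- block[i - 1]
    } else {
      block[i] <- block[i - 1] + 1L
    }
    run_end <- max(run_end, tiles$mature_end[i])
  }
  tiles$block <- block
  out <- tiles %>%
    group_by(.data$block) %>%
    summarise(n_tiles = dplyr::n(),
              intersection_start = max(.data$mature_start),
              intersection_end = min(.data$mature_end),
              union_start = min(.data$mature_start),
              union_end = max(.data$mature_end), .groups = "drop")
  if (any(out$intersection_start > out$intersection_end)) {
    warn("a block of chained tiles has an empty common intersection")
  }
  attr(out, "multi_site") <- nrow(out) > 1
  out
}

#' Build an evidence record
#'
#' @param source one of `"chimera"`, `"patch"`, `"point_mutant"`,
#'   `"peptide_overlap"`, `"reverse_chimera"`.
#' @param direction `"loss"`, `"retention"` or `"gain"`.
#' @param start,end mature interval (interval-type evidence).
#' @param positions integer vector of mature positions (set-type evidence:
#'   patch substitutions, point mutants).
#' @return one-row tibble usable with [integrate_evidence()].
#' @export
evidence <- function(source, direction, start = NA_integer_, end = NA_integer_,
                     positions = NULL) {
  source <- match.arg(source, c("chimera", "patch", "point_mutant",
                                "peptide_overlap", "reverse_chimera"))
  direction <- match.arg(direction, c("loss", "retention", "gain"))
  tibble(source = source, direction = direction,
         start = as.integer(start), end = as.integer(end),
         positions = list(as.integer(positions %||% integer(0))))
}

#' Integrate chimera, patch, point-mutant and peptide evidence
#'
#' The epitope interval is the intersection of all interval-type loss/gain
#' evidence (chimera loss, reverse-chimera gain, peptide overlap). Pivotal
#' residues are point-mutant loss positions plus positions shared between
#' patch-loss substitution sets and chimera-loss intervals, restricted to
#' the final interval. Retention evidence annotates residue grades but
#' never shrinks the interval. The result is order-independent.
#'
#' `boundary_rule = "gain"` privileges gain-direction boundaries (reverse
#' chimeras, peptide overlap): the interval is then the intersection of
#' gain and peptide evidence only, with loss intervals required to overlap
#' it.
#'
#' @param ev tibble of [evidence()] rows.
#' @param boundary_rule `"intersection"` (default) or `"gain"`.
#' @return object of class `epitope_call`: `interval`, `pivotal`,
#'   `retained` (annotation positions), `evidence`.
#' @export
integrate_evidence <- function(ev, boundary_rule = c("intersection", "gain")) {
  boundary_rule <- match.arg(boundary_rule)
  ev <- as_tibble(ev)
  ev <- arrange(ev, .data$source, .data$direction, .data$start)  # order independence
  is_interval <- !is.na(ev$start) & !is.na(ev$end)
  core <- ev[is_interval & ev$direction %in% c("loss", "gain"), , drop = FALSE]
  if (nrow(core) == 0 && !any(ev$direction %in% c("loss", "gain"))) {
    abort("need at least one loss- or gain-direction evidence item")
  }
  pick <- if (boundary_rule == "gain") core[core$direction == "gain" |
                                              core$source == "peptide_overlap", , drop = FALSE] else core
  if (nrow(pick) == 0) pick <- core
  if (nrow(pick) > 0) {
    lo <- max(pick$start); hi <- min(pick$end)
    if (lo > hi) {
      pair <- "unknown pair"
      for (i in seq_len(nrow(pick) - 1)) for (j in (i + 1):nrow(pick)) {
        if (pick$start[i] > pick$end[j] || pick$start[j] > pick$end[i]) {
          pair <- paste0(pick$source[i], " [", pick$start[i], ",", pick$end[i], "] vs ",
                         pick$source[j], " [", pick$start[j], ",", pick$end[j], "]")
          break
        }
      }
      abort(paste0("conflicting evidence: empty interval intersection (", pair, ")"))
    }
    if (boundary_rule == "gain") {
      loss_iv <- core[core$direction == "loss" & core$source != "peptide_overlap", , drop = FALSE]
      bad <- loss_iv$start > hi | loss_iv$end < lo
      if (any(bad)) {
        abort(paste0("conflicting evidence: loss interval [", loss_iv$start[which(bad)[1]], ",",
                     loss_iv$end[which(bad)[1]], "] does not overlap gain interval [", lo, ",", hi, "]"))
      }
    }
    interval <- c(lo, hi)
  } else {
    interval <- c(NA_integer_, NA_integer_)
  }
  chim_loss <- ev[is_interval & ev$source == "chimera" & ev$direction == "loss", , drop = FALSE]
  patch_loss_pos <- sort(unique(unlist(ev$positions[ev$source == "patch" & ev$direction == "loss"])))
  point_loss_pos <- sort(unique(unlist(ev$positions[ev$source == "point_mutant" & ev$direction == "loss"])))
  in_chimera <- function(p) {
    nrow(chim_loss) > 0 && any(p >= chim_loss$start & p <= chim_loss$end)
  }
  pivotal <- sort(unique(c(point_loss_pos,
                           patch_loss_pos[vapply(patch_loss_pos, in_chimera, logical(1))])))
  if (!anyNA(interval)) {
    dropped <- pivotal[pivotal < interval[1] | pivotal > interval[2]]
    if (length(dropped) > 0) {
      warn(paste0("pivotal candidate(s) outside the final interval dropped: ",
                  paste(dropped, collapse = ", ")))
    }
    pivotal <- pivotal[pivotal >= interval[1] & pivotal <= interval[2]]
  }
  retained <- sort(unique(unlist(ev$positions[ev$direction == "retention"])))
  out <- list(interval = interval, pivotal = pivotal, retained = retained,
              evidence = ev, boundary_rule = boundary_rule)
  class(out) <- "epitope_call"
  out
}

#' @export
print.epitope_call <- function(x, ...) {
  cat("<epitope_call> interval [", x$interval[1], ", ", x$interval[2], "]",
      if (length(x$pivotal) > 0) paste0("; pivotal: ", paste(x$pivotal, collapse = ", ")) else "",
      if (length(x$retained) > 0) paste0("; retention-annotated: ", paste(x$retained, collapse = ", ")) else "",
      "\n", sep = "")
  invisible(x)
}

#' Percent competition and monotonicity of a competition curve
#'
#' Percent competition is `(control - signal) / (control - blank) * 100`,
#' clipped to `[-10, 110]`; the trend verdict comes from a Spearman test of
#' signal against concentration.
#'
#' @param curve tibble with `concentration` and `signal` (>= 2 rows).
#' @param control positive-control signal (no competitor).
#' @param blank blank signal.
#' @param alpha significance level for the trend verdict.
#' @return list: `curve` with `pct_competition`, `verdict`
#'   (`"decreasing"`, `"increasing"`, `"flat"`), `rho`, `p_value`.
#' @export
competition_metrics <- function(curve, control, blank, alpha = 0.05) {
  curve <- as_tibble(curve)
  if (nrow(curve) < 2) abort("need at least 2 concentrations")
  if (control <= blank) abort("positive control must exceed blank")
  curve$pct_competition <- pmin(110, pmax(-10, 100 * (control - curve$signal) / (control - blank)))
  ct <- suppressWarnings(cor.test(curve$signal, curve$concentration,
                                  method = "spearman", exact = FALSE))
  verdict <- if (!is.na(ct$p.value) && ct$p.value < alpha) {
    if (ct$estimate < 0) "decreasing" else "increasing"
  } else "flat"
  list(curve = curve, verdict = verdict,
       rho = unname(ct$estimate), p_value = ct$p.value)
}
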