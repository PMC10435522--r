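# Seeded synthetic-data generators. Each emulates the statistical or
# geometric structure one pipeline stage assumes and returns the planted
# ground truth alongside the data, so recovery can be asserted exactly.

#' Generate a labelled ortholog panel with a planted divergent epitope
#'
#' Binders (and weak binders) share one consensus sequence. Non-binders
#' differ from the consensus at every site of `planted_interval` and
#' mutate elsewhere with probability `within_binder_divergence`; columns
#' outside the planted interval where by chance every non-binder mutated
#' are repaired (one non-binder reverted) so that the differential-position
#' ground truth is exactly the planted columns.
#'
#' @param n_binders,n_weak,n_nonbinders species counts per label.
#' @param seq_length ungapped sequence length (mature residues).
#' @param planted_interval integer length-2, 1-based inclusive mature
#'   interval of planted divergence.
#' @param within_binder_divergence per-site substitution probability for
#'   non-binders outside the planted interval.
#' @param seed integer seed; identical seeds give identical panels.
#' @return list: `panel` tibble (`species`, `label`, `offset`, `aligned`),
#'   `truth` (integer vector of divergent mature positions), `seed`.
#' @export
gen_ortholog_panel <- function(n_binders = 3, n_weak = 0, n_nonbinders = 3,
                               seq_length = 100, planted_interval = c(40, 55),
                               within_binder_divergence = 0.05, seed = 1) {
  stopifnot(n_binders >= 1, n_nonbinders >= 0, seq_length >= 1)
  if (planted_interval[1] < 1 || planted_interval[2] > seq_length ||
      planted_interval[1] > planted_interval[2]) {
    abort("planted_interval must lie within [1, seq_length]")
  }
  if (within_binder_divergence < 0 || within_binder_divergence > 1) {
    abort("within_binder_divergence must be in [0, 1]")
  }
  withr::with_seed(seed, {
    consensus <- sample(AA1, seq_length, replace = TRUE)
    planted <- seq(planted_interval[1], planted_interval[2])
    mutate_site <- function(res) sample(setdiff(AA1, res), 1)
    nb_seqs <- replicate(n_nonbinders, {
      s <- consensus
      for (p in planted) s[p] <- mutate_site(s[p])
      outside <- setdiff(seq_len(seq_length), planted)
      hits <- outside[stats::runif(length(outside)) < within_binder_divergence]
      for (p in hits) s[p] <- mutate_site(s[p])
      s
    }, simplify = FALSE)
    # repair accidental fully-divergent columns outside the planted interval
    if (n_nonbinders > 0) {
      for (p in setdiff(seq_len(seq_length), planted)) {
        if (all(vapply(nb_seqs, function(s) s[p] != consensus[p], logical(1)))) {
          nb_seqs[[1]][p] <- consensus[p]
        }
      }
    }
    panel <- bind_rows(
      tibble(species = paste0("binder_", seq_len(n_binders)), label = "binder",
             offset = 0, aligned = paste(consensus, collapse = "")),
      if (n_weak > 0) tibble(species = paste0("weak_", seq_len(n_weak)),
                             label = "weak_binder", offset = 0,
                             aligned = paste(consensus, collapse = "")),
      if (n_nonbinders > 0) tibble(
        species = paste0("nonbinder_", seq_len(n_nonbinders)), label = "non_binder",
        offset = 0, aligned = vapply(nb_seqs, paste, character(1), collapse = ""))
    )
    list(panel = panel, truth = if (n_nonbinders > 0) planted else integer(0), seed = seed)
  })
}

#' Generate a toy helical antigen with a pseudo-paratope probe chain
#'
#' The antigen chain is an ideal alpha-helix (1.5 A rise and 100 degree
#' twist per residue) carrying a C-alpha and one side-chain centroid
#' pseudo-atom per residue; probe-chain atoms sit at `probe_distance` from
#' randomly designated centroid atoms, pointing radially outward. Ground
#' truth contacts come from exhaustive pair enumeration and ground-truth
#' buried area from high-resolution numeric SASA.
#'
#' @param helix_sequence amino-acid string for the antigen (length >= 4).
#' @param n_probe_atoms number of probe atoms.
#' @param probe_distance center-center distance (A) from designated
#'   centroids to their probe atoms.
#' @param contact_cutoff cutoff used for the ground-truth contact list.
#' @param seed integer seed (selects designated residues).
#' @return list: `model` ([structure_model()], chains A = antigen,
#'   B = probe), `contacts` (ground-truth residue pairs), `bsa`
#'   (ground-truth buried area, A^2), `designated` (antigen resno).
#' @export
gen_helix_complex <- function(helix_sequence = "ASLDKEQRTVNGILSMFYWH",
                              n_probe_atoms = 5, probe_distance = 3.5,
                              contact_cutoff = 3.8, seed = 1) {
  res1 <- strsplit(helix_sequence, "")[[1]]
  n <- length(res1)
  if (n < 4) abort("helix_sequence must have at least 4 residues")
  if (probe_distance <= 0) abort("probe_distance must be positive")
  if (n_probe_atoms < 1 || n_probe_atoms > n - 2) {
    abort("n_probe_atoms must be between 1 and length(helix) - 2")
  }
  theta <- (seq_len(n) - 1) * 100 * pi / 180
  ca_r <- 2.3; cen_r <- 5.0
  ca <- tibble(chain = "A", resno = seq_len(n), resid = aa_one_to_three(res1),
               atom = "CA", element = "C",
               x = ca_r * cos(theta), y = ca_r * sin(theta), z = 1.5 * seq_len(n))
  cen <- tibble(chain = "A", resno = seq_len(n), resid = aa_one_to_three(res1),
                atom = "CEN", element = "C",
                x = cen_r * cos(theta), y = cen_r * sin(theta), z = 1.5 * seq_len(n))
  designated <- withr::with_seed(seed, sort(sample(2:(n - 1), n_probe_atoms)))
  dir_xy <- cbind(cos(theta[designated]), sin(theta[designated]))
  probe <- tibble(chain = "B", resno = seq_len(n_probe_atoms), resid = "PRB",
                  atom = "PB", element = "C",
                  x = cen_r * dir_xy[, 1] + probe_distance * dir_xy[, 1],
                  y = cen_r * dir_xy[, 2] + probe_distance * dir_xy[, 2],
                  z = 1.5 * designated)
  model <- structure_model(bind_rows(ca, cen, probe))
  # exhaustive ground-truth contact enumeration
  ag <- bind_rows(ca, cen); pr <- probe
  truth <- NULL
  for (i in seq_len(nrow(ag))) for (j in seq_len(nrow(pr))) {
    d <- sqrt((ag$x[i] - pr$x[j])^2 + (ag$y[i] - pr$y[j])^2 + (ag$z[i] - pr$z[j])^2)
    if (d <= contact_cutoff) {
      truth <- bind_rows(truth, tibble(resno_ag = ag$resno[i], atom_ag = ag$atom[i],
                                       resno_probe = pr$resno[j], distance = d))
    }
  }
  truth <- truth %||% tibble(resno_ag = integer(), atom_ag = character(),
                             resno_probe = integer(), distance = numeric())
  bsa_truth <- if (nrow(truth) == 0 && probe_distance > 2 * (1.7 + 1.4) + 3) 0 else {
    b <- buried_surface_area(model, "A", "B", n_points = 4000)
    b$total_bsa
  }
  list(model = model, contacts = truth, bsa = bsa_truth,
       designated = designated, seed = seed)
}

#' Generate two-channel flow-cytometry-like event intensities
#'
#' Log-normal intensities for a binding channel and a display channel, both
#' scaled by a common multiplicative instrument gain (which therefore
#' cancels in the normalized MFI ratio).
#'
#' @param n_events number of events (>= 1).
#' @param log_mean_binding,log_sd_binding,log_mean_display,log_sd_display
#'   log-scale parameters of the two channels.
#' @param gain multiplicative instrument factor applied to both channels.
#' @param seed integer seed.
#' @return tibble with `event`, `binding`, `display`.
#' @export
gen_flow_events <- function(n_events = 10000,
                            log_mean_binding = 7, log_sd_binding = 0.6,
                            log_mean_display = 6, log_sd_display = 0.5,
                            gain = 1, seed = 1) {
  stopifnot(n_events >= 1, log_sd_binding > 0, log_sd_display > 0, gain > 0)
  withr::with_seed(seed, tibble(
    event = seq_len(n_events),
    binding = gain * stats::rlnorm(n_events, log_mean_binding, log_sd_binding),
    display = gain * stats::rlnorm(n_events, log_mean_display, log_sd_display)
  ))
}

#' Generate tiling-peptide binding signals with planted positives
#'
#' Tiles whose mature interval overlaps `planted_interval` by at least
#' `min_overlap` residues receive mean signal
#' `positive_fold * background_mean`; all others the background mean.
#' Gaussian noise with `background_sd` on top, seeded.
#'
#' @param tiles tibble from [tile_peptides()] (needs `tile`,
#'   `mature_start`, `mature_end`).
#' @param planted_interval mature interval (length-2 integer) or `NULL`
#'   for no positives.
#' @param background_mean,background_sd background signal parameters.
#' @param positive_fold fold-over-background of epitope tiles (> 1).
#' @param min_overlap minimum overlapping residues for a tile to be
#'   positive; default the planted-interval length capped at 15.
#' @param seed integer seed.
#' @return list: `signals` tibble (`tile`, `signal`), `truth` (positive
#'   tile indices).
#' @export
gen_peptide_signals <- function(tiles, planted_interval,
                                background_mean = 50, background_sd = 5,
                                positive_fold = 10, min_overlap = NULL, seed = 1) {
  if (nrow(tiles) == 0) abort("tiles must be non-empty")
  stopifnot(positive_fold > 1, background_sd >= 0)
  if (is.null(planted_interval) || length(planted_interval) == 0) {
    truth <- integer(0)
  } else {
    if (is.null(min_overlap)) {
      min_overlap <- min(15, planted_interval[2] - planted_interval[1] + 1)
    }
    ov <- pmax(0, pmin(tiles$mature_end, planted_interval[2]) -
                 pmax(tiles$mature_start, planted_interval[1]) + 1)
    truth <- tiles$tile[ov >= min_overlap]
  }
  mu <- ifelse(tiles$tile %in% truth, positive_fold * background_mean, background_mean)
  signals <- withr::with_seed(seed, tibble(
    tile = tiles$tile,
    signal = stats::rnorm(nrow(tiles), mu, background_sd)
  ))
  list(signals = signals, truth = truth, seed = seed)
}
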