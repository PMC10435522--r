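# Windowed B-cell antigenicity profiles and their consensus.

ANTIGENICITY_WINDOWS <- c(emini = 6L, kolaskar_tongaonkar = 7L, hydrophilicity = 7L)

#' Windowed antigenicity profile of a protein sequence
#'
#' Three predictors over a sliding window (positions are window starts,
#' 1-based; positions without a full window carry no score):
#'
#' * `emini`: product of surface-accessibility propensities over a
#'   6-residue window, normalized by `mean(scale)^6` so a uniformly random
#'   sequence has expected score 1; threshold 1.0.
#' * `kolaskar_tongaonkar`: 7-residue moving average of antigenic
#'   propensity; if the whole-protein mean window score exceeds 1.0 the
#'   threshold is 1.0, otherwise the mean itself (the published rule).
#' * `hydrophilicity`: 7-residue moving average of Parker hydrophilicity
#'   (a stand-in third predictor for HMM-based linear-epitope tools);
#'   threshold = whole-protein mean window score.
#'
#' Non-standard residues score with a scale-neutral value (1.0 for the two
#' propensity scales, 0 for hydrophilicity) and are flagged.
#'
#' @param sequence amino-acid string (no gaps).
#' @param method one of `"emini"`, `"kolaskar_tongaonkar"`,
#'   `"hydrophilicity"`.
#' @return tibble with `position` (window start), `score`, `positive`,
#'   `nonstandard`; attributes `method`, `window`, `threshold`, `sequence`.
#' @export
antigenicity_profile <- function(sequence,
                                 method = c("emini", "kolaskar_tongaonkar", "hydrophilicity")) {
  method <- match.arg(method)
  w <- ANTIGENICITY_WINDOWS[[method]]
  res <- strsplit(toupper(sequence), "")[[1]]
  L <- length(res)
  if (L < w) abort(paste0("sequence shorter than the ", w, "-residue window"))
  scale <- switch(method, emini = EMINI_SCALE,
                  kolaskar_tongaonkar = KOLASKAR_SCALE,
                  hydrophilicity = PARKER_SCALE)
  neutral <- if (method == "hydrophilicity") 0 else 1
  v <- unname(scale[res])
  ns <- is.na(v)
  if (any(ns)) {
    warn(paste0(sum(ns), " non-standard residue(s) scored with neutral value ", neutral))
    v[ns] <- neutral
  }
  starts <- seq_len(L - w + 1)
  if (method == "emini") {
    score <- vapply(starts, function(i) prod(v[i:(i + w - 1)]), numeric(1)) / mean(EMINI_SCALE)^w
    threshold <- 1.0
  } else {
    score <- vapply(starts, function(i) mean(v[i:(i + w - 1)]), numeric(1))
    threshold <- if (method == "kolaskar_tongaonkar") {
      if (mean(score) > 1.0) 1.0 else mean(score)
    } else {
      mean(score)
    }
  }
  window_ns <- vapply(starts, function(i) any(ns[i:(i + w - 1)]), logical(1))
  out <- tibble(position = starts, score = score,
                positive = score > threshold, nonstandard = window_ns)
  attr(out, "method") <- method
  attr(out, "window") <- w
  attr(out, "threshold") <- threshold
  attr(out, "sequence") <- paste(res, collapse = "")
  out
}

#' Consensus antigenic regions across several profiles
#'
#' Maximal runs of at least `min_run` consecutive window-start positions
#' (scored by every profile) where every profile exceeds its threshold,
#' ranked by the mean normalized excess over threshold.
#'
#' @param profiles list of [antigenicity_profile()] outputs over the same
#'   sequence.
#' @param min_run minimum run length (default 4).
#' @return tibble with `start`, `end`, `length`, `excess`, `rank`.
#' @export
consensus_regions <- function(profiles, min_run = 4) {
  if (length(profiles) < 2) abort("need at least two profiles")
  seqs <- unique(vapply(profiles, function(p) attr(p, "sequence"), character(1)))
  if (length(seqs) != 1) abort("profiles cover different sequences")
  common <- Reduce(intersect, lapply(profiles, function(p) p$position))
  pos_ok <- vapply(common, function(i) {
    all(vapply(profiles, function(p) p$positive[p$position == i], logical(1)))
  }, logical(1))
  hits <- sort(common[pos_ok])
  empty <- tibble(start = integer(), end = integer(), length = integer(),
                  excess = numeric(), rank = integer())
  if (length(hits) == 0) return(empty)
  brk <- c(0, which(diff(hits) > 1), length(hits))
  runs <- purrr::map2(brk[-length(brk)] + 1, brk[-1], ~ hits[.x:.y])
  runs <- runs[vapply(runs, length, integer(1)) >= min_run]
  if (length(runs) == 0) return(empty)
  excess_of <- function(run) {
    mean(vapply(profiles, function(p) {
      thr <- attr(p, "threshold")
      sc <- p$score[p$position %in% run]
      denom <- if (abs(thr) > 1e-12) abs(thr) else 1
      mean((sc - thr) / denom)
    }, numeric(1)))
  }
  out <- bind_rows(purrr::map(runs, function(run) {
    tibble(start = min(run), end = max(run), length = length(run),
           excess = excess_of(run))
  })) %>% arrange(dplyr::desc(.data$excess))
  out$rank <- seq_len(nrow(out))
  out
}
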