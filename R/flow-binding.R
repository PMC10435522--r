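# Flow-binding normalization and many-to-one comparison: MFI, display-
# normalized binding ratios, variant classification against a control
# antibody, and a seeded max-T permutation realization of Dunnett-style
# many-to-one testing.

#' Median fluorescence intensity
#'
#' Exact median (mean of the central pair for even event counts).
#'
#' @param intensities numeric vector of per-event intensities (> 0).
#' @return the MFI.
#' @export
median_fluorescence <- function(intensities) {
  if (length(intensities) == 0) abort("no events")
  median(intensities)
}

#' Display-normalized binding ratio
#'
#' Ratio of the binding-channel MFI to the display-channel MFI; a common
#' multiplicative instrument gain cancels exactly. A display MFI at or
#' below `display_floor` marks a display failure and yields no ratio.
#'
#' @param binding,display numeric vectors of per-event intensities.
#' @param display_floor minimal acceptable display MFI (default 0;
#'   typically the negative-control display MFI).
#' @return tibble with `mfi_binding`, `mfi_display`, `ratio`,
#'   `display_failure`.
#' @export
normalized_ratio <- function(binding, display, display_floor = 0) {
  mfi_b <- median_fluorescence(binding)
  mfi_d <- median_fluorescence(display)
  fail <- mfi_d <= max(0, display_floor)
  tibble(mfi_binding = mfi_b, mfi_display = mfi_d,
         ratio = if (fail) NA_real_ else mfi_b / mfi_d,
         display_failure = fail)
}

#' Many-to-one comparison against a reference construct (max-T permutation)
#'
#' Family-wise-error-controlled comparison of every construct's
#' display-normalized ratio against a reference (wild type), realized as a
#' max-T permutation test: group labels are permuted, the maximum absolute
#' t statistic (pooled-variance) across comparisons is recorded, and each
#' construct's adjusted p is the tail probability of its observed |t|
#' under that max-T null. Seeded and reproducible.
#'
#' @param data tibble with `construct` and `ratio` (one row per replicate).
#' @param reference reference construct name.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return tibble per non-reference construct: `construct`, `n`, `mean`,
#'   `effect` (mean difference vs reference), `t`, `p_adj`.
#' @export
compare_to_reference <- function(data, reference, n_perm = 10000, seed = 1) {
  data <- as_tibble(data)
  if (!reference %in% data$construct) abort(paste0("reference '", reference, "' absent from data"))
  counts <- table(data$construct)
  single <- names(counts)[counts < 2]
  if (length(single) > 0) {
    abort(paste0("construct(s) with a single replicate: ", paste(single, collapse = ", ")))
  }
  g <- factor(data$construct)
  y <- data$ratio
  N <- length(y)
  k <- nlevels(g)
  M <- stats::model.matrix(~ g - 1)  # N x k indicator
  n_g <- colSums(M)
  ref_col <- which(levels(g) == reference)
  tstats <- function(sums, sqsums) {
    means <- sums / n_g
    ss_within <- sum(sqsums - sums^2 / n_g)
    vp <- ss_within / (N - k)
    vp <- pmax(vp, .Machine$double.eps)
    se <- sqrt(vp * (1 / n_g + 1 / n_g[ref_col]))
    (means - means[ref_col]) / se
  }
  obs_sums <- as.numeric(t(M) %*% y)
  obs_sq <- as.numeric(t(M) %*% y^2)
  t_obs <- tstats(obs_sums, obs_sq)
  maxT <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      yp <- y[sample.int(N)]
      s <- as.numeric(crossprod(M, yp))
      s2 <- as.numeric(crossprod(M, yp^2))
      tb <- tstats(s, s2)
      max(abs(tb[-ref_col]))
    }, numeric(1))
  })
  keep <- setdiff(seq_len(k), ref_col)
  tibble(
    construct = levels(g)[keep],
    n = as.integer(n_g[keep]),
    mean = obs_sums[keep] / n_g[keep],
    effect = obs_sums[keep] / n_g[keep] - obs_sums[ref_col] / n_g[ref_col],
    t = t_obs[keep],
    p_adj = vapply(t_obs[keep], function(t0) (1 + sum(maxT >= abs(t0))) / (n_perm + 1),
                   numeric(1))
  )
}

#' Classify variants as epitope- versus fold-disrupted
#'
#' Binding to a variant counts as lost for an antibody when its mean ratio
#' falls below `loss_fraction` of the wild-type ratio AND the many-to-one
#' comparison is significant at `alpha`. The truth table then reads:
#' test lost + control retained = `epitope_disrupted`; both lost =
#' `fold_disrupted`; both retained = `retained`; test retained + control
#' lost = `ambiguous`; constructs flagged as display failures are
#' `display_failure`.
#'
#' @param ratios tibble with `construct`, `antibody` (`"test"` or
#'   `"control"`), `replicate`, `ratio`; optionally `display_failure`.
#' @param reference wild-type construct name.
#' @param loss_fraction fraction of the wild-type ratio below which binding
#'   counts as lost (default 0.5).
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param n_perm,seed passed to [compare_to_reference()].
#' @return tibble per construct: verdicts per antibody and the
#'   `classification`.
#' @export
classify_variant <- function(ratios, reference, loss_fraction = 0.5, alpha = 0.05,
                             n_perm = 2000, seed = 1) {
  ratios <- as_tibble(ratios)
  stopifnot(all(c("construct", "antibody", "ratio") %in% names(ratios)))
  fails <- if ("display_failure" %in% names(ratios)) {
    unique(ratios$construct[ratios$display_failure])
  } else character(0)
  ok <- ratios[!ratios$construct %in% fails, , drop = FALSE]
  verdict_one <- function(ab, seed_ab) {
    d <- ok[ok$antibody == ab, c("construct", "ratio")]
    cmp <- compare_to_reference(d, reference, n_perm = n_perm, seed = seed_ab)
    wt <- mean(d$ratio[d$construct == reference])
    cmp %>% mutate(lost = .data$mean < loss_fraction * wt & .data$p_adj < alpha &
                     .data$effect < 0) %>%
      select("construct", "lost")
  }
  test_v <- verdict_one("test", seed)
  ctrl_v <- verdict_one("control", seed + 1)
  out <- test_v %>%
    rename(test_lost = "lost") %>%
    left_join(rename(ctrl_v, control_lost = "lost"), by = "construct") %>%
    mutate(classification = dplyr::case_when(
      .data$test_lost & !.data$control_lost ~ "epitope_disrupted",
      .data$test_lost & .data$control_lost ~ "fold_disrupted",
      !.data$test_lost & !.data$control_lost ~ "retained",
      TRUE ~ "ambiguous"
    ))
  if (length(fails) > 0) {
    out <- bind_rows(out, tibble(construct = fails, test_lost = NA, control_lost = NA,
                                 classification = "display_failure"))
  }
  arrange(out, .data$construct)
}
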