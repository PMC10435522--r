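# End-to-end orchestration of the design and epitope-mapping stages, with
# the resolved parameter set echoed into every result for provenance.

#' Run the chimera/patch design pipeline
#'
#' Differential conservation scan, optional structural surface filtering,
#' patch clustering and chimera proposal, and antigenicity-consensus
#' annotation of the reference sequence. When no structure is supplied the
#' surface filter is skipped with a warning recorded in the report.
#'
#' @param panel ortholog panel tibble (see [ingest_alignment()]).
#' @param donor_species donor (non-binder) species for substitutions.
#' @param model optional [structure_model()] of the reference antigen.
#' @param reference reference species (default: panel attribute or first
#'   binder).
#' @param rsa_threshold surface-filter RSA fraction (default 0.25).
#' @param patch_distance single-linkage cutoff (A, default 10).
#' @param size_range substitutions per patch (default 2-4).
#' @param min_span,max_span,max_gap chimera interval parameters.
#' @param min_run consensus-region minimum run length.
#' @param chain antigen chain in the model.
#' @return list of class `design_run`: `differential`, `surface`,
#'   `patches`, `chimeras`, `consensus`, `report`.
#' @export
run_design_pipeline <- function(panel, donor_species, model = NULL,
                                reference = NULL, rsa_threshold = 0.25,
                                patch_distance = 10, size_range = c(2, 4),
                                min_span = 6, max_span = 20, max_gap = 3,
                                min_run = 4, chain = NULL) {
  params <- list(donor_species = donor_species, reference = reference,
                 rsa_threshold = rsa_threshold, patch_distance = patch_distance,
                 size_range = size_range, min_span = min_span, max_span = max_span,
                 max_gap = max_gap, min_run = min_run)
  warnings <- character(0)
  reference <- panel_reference(panel, reference)

  diff_tab <- tryCatch(differential_positions(panel, reference = reference),
                       error = function(e) abort(paste0("[differential] ", conditionMessage(e))))
  positions <- diff_tab$mature[diff_tab$differential]
  positions <- positions[!is.na(positions)]

  if (is.null(model)) {
    warnings <- c(warnings, "surface filter skipped: no structure supplied")
    surface <- NULL
    exposed <- positions
  } else {
    surface <- tryCatch(
      surface_filter(positions, model, rsa_threshold = rsa_threshold, chain = chain),
      error = function(e) abort(paste0("[surface_filter] ", conditionMessage(e))))
    exposed <- surface$exposed$mature
  }

  patches <- if (length(exposed) > 0 && !is.null(model)) {
    tryCatch(cluster_patches(exposed, model, panel, donor_species,
                             distance_cutoff = patch_distance, size_range = size_range,
                             chain = chain, reference = reference),
             error = function(e) abort(paste0("[cluster_patches] ", conditionMessage(e))))
  } else NULL

  chimeras <- tryCatch(
    propose_chimeras(exposed, panel, donor_species, min_span = min_span,
                     max_span = max_span, max_gap = max_gap, reference = reference),
    error = function(e) abort(paste0("[propose_chimeras] ", conditionMessage(e))))

  ref_seq <- gsub("-", "", panel$aligned[panel$species == reference])
  consensus <- tryCatch({
    profs <- lapply(c("emini", "kolaskar_tongaonkar", "hydrophilicity"),
                    function(m) antigenicity_profile(ref_seq, m))
    consensus_regions(profs, min_run = min_run)
  }, error = function(e) {
    warnings <<- c(warnings, paste0("antigenicity consensus skipped: ", conditionMessage(e)))
    NULL
  })

  out <- list(differential = diff_tab, surface = surface, patches = patches,
              chimeras = chimeras, consensus = consensus,
              report = list(params = params, reference = reference,
                            n_differential = length(positions), warnings = warnings))
  class(out) <- "design_run"
  out
}

#' Run the peptide-mapping and evidence-integration pipeline
#'
#' Tiling positivity calls, interval localization, and integration with
#' construct-level evidence into a single epitope call.
#'
#' @param tiles tibble from [tile_peptides()].
#' @param signals tibble with `tile` and `signal`.
#' @param background_mean,background_sd,background_n plate background.
#' @param extra_evidence optional tibble of [evidence()] rows (chimera,
#'   patch, point-mutant, reverse-chimera results).
#' @param fold,z positivity thresholds (defaults 3 and 5).
#' @param boundary_rule passed to [integrate_evidence()].
#' @return list of class `epitope_run`: `calls`, `localization`,
#'   `epitope` ([integrate_evidence()] output), `report`.
#' @export
run_epitope_pipeline <- function(tiles, signals, background_mean, background_sd,
                                 background_n = 2, extra_evidence = NULL,
                                 fold = 3, z = 5,
                                 boundary_rule = c("intersection", "gain")) {
  boundary_rule <- match.arg(boundary_rule)
  if (is.null(signals) || nrow(signals) == 0) abort("[classify] empty signals table")
  params <- list(fold = fold, z = z, background_mean = background_mean,
                 background_sd = background_sd, boundary_rule = boundary_rule)
  calls <- tryCatch(
    classify_peptide_binding(signals, background_mean, background_sd,
                             background_n = background_n, fold = fold, z = z),
    error = function(e) abort(paste0("[classify] ", conditionMessage(e))))
  pos <- calls %>% filter(.data$positive) %>% left_join(tiles, by = "tile")
  loc <- if (nrow(pos) > 0) localize_from_tiles(pos) else NULL
  ev <- extra_evidence
  if (!is.null(loc)) {
    pep_ev <- bind_rows(purrr::pmap(
      list(loc$intersection_start, loc$intersection_end),
      function(s, e) evidence("peptide_overlap", "loss", s, e)))
    # peptide positives are loss-of-signal localizers in the same sense as
    # chimera losses: they bound the interval from the binding side
    ev <- bind_rows(ev, pep_ev)
  }
  call <- if (!is.null(ev) && nrow(ev) > 0) {
    tryCatch(integrate_evidence(ev, boundary_rule = boundary_rule),
             error = function(e) abort(paste0("[integrate] ", conditionMessage(e))))
  } else NULL
  out <- list(calls = calls, localization = loc, epitope = call,
              report = list(params = params,
                            n_positive = sum(calls$positive)))
  class(out) <- "epitope_run"
  out
}
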