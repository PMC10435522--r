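# broom-style accessors for the fitted/report objects.

#' @describeIn interface_report tidy per-residue interface table.
#' @param x an `interface_report`.
#' @param ... unused.
#' @export
tidy.interface_report <- function(x, ...) {
  ep <- x$epitope$resno
  pa <- x$paratope$resno
  x$residues %>%
    mutate(in_contact_set = (.data$side == "antigen" & .data$resno %in% ep) |
             (.data$side == "antibody" & .data$resno %in% pa))
}

#' @describeIn interface_report one-row interface summary.
#' @export
glance.interface_report <- function(x, ...) {
  tibble(total_bsa = x$total_bsa,
         n_epitope = nrow(x$epitope),
         n_paratope = nrow(x$paratope),
         n_contacts = nrow(x$contacts),
         n_hbonds = nrow(x$hbonds),
         n_disulfides = nrow(x$disulfides),
         contact_cutoff = x$config$contact_cutoff,
         probe = x$config$probe)
}

#' @describeIn superpose per-pair deviations of the final fit.
#' @param x a `superposition`.
#' @param ... unused.
#' @export
tidy.superposition <- function(x, ...) {
  tibble(pair = seq_along(x$deviations), deviation = x$deviations)
}

#' @describeIn superpose one-row superposition summary.
#' @export
glance.superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, n_pairs = x$n_pairs, n_initial = x$n_initial,
         cycles = x$cycles)
}

#' @describeIn integrate_evidence evidence table with the final call.
#' @param x an `epitope_call`.
#' @param ... unused.
#' @export
tidy.epitope_call <- function(x, ...) {
  x$evidence %>%
    mutate(positions = purrr::map_chr(.data$positions, paste, collapse = ","))
}

#' @describeIn integrate_evidence one-row epitope-call summary.
#' @export
glance.epitope_call <- function(x, ...) {
  tibble(interval_start = x$interval[1], interval_end = x$interval[2],
         n_pivotal = length(x$pivotal),
         pivotal = paste(x$pivotal, collapse = ","),
         boundary_rule = x$boundary_rule)
}
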