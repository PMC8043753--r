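#' Rank species by quasi-extinction integral within a scenario
#'
#' Ascending ranks (1 = smallest integral = most resilient); ties receive
#' the average rank.
#'
#' @param integrals_by_species named numeric vector of per-species
#'   quasi-extinction integrals for one scenario.
#' @return named numeric vector of ranks.
#' @export
rank_species <- function(integrals_by_species) {
  if (length(integrals_by_species) < 2)
    stop("ranking needs at least 2 species")
  if (is.null(names(integrals_by_species)) ||
      any(!nzchar(names(integrals_by_species))))
    stop("integrals must be named by species")
  if (any(!is.finite(integrals_by_species)))
    stop("missing or non-finite integral for species: ",
         paste(names(integrals_by_species)[!is.finite(integrals_by_species)],
               collapse = ", "))
  rank(integrals_by_species, ties.method = "average")
}

#' Median susceptibility rank across the six core scenarios
#'
#' @param ranks_across_scenarios named numeric vector of one species' ranks,
#'   names covering all of [core_scenarios()].
#' @return the median rank (scalar).
#' @export
median_rank <- function(ranks_across_scenarios) {
  need <- core_scenarios()
  missing <- setdiff(need, names(ranks_across_scenarios))
  if (length(missing))
    stop("missing core scenario rank(s): ", paste(missing, collapse = ", "))
  median(as.numeric(ranks_across_scenarios[need]))
}

#' Summarise per-species risk across scenarios
#'
#' Takes a species x scenario table of quasi-extinction integrals, ranks the
#' species within each scenario (ties averaged), sums the six core-scenario
#' integrals into a total risk, and takes the median core-scenario rank as
#' the single susceptibility index per species. Sub-scenario columns (e.g.
#' juvenile-only offtake, egg harvest) are carried through but excluded from
#' the total and the median rank.
#'
#' @param integral_table data frame with a `species` column and one numeric
#'   column per scenario kind.
#' @return data frame, one row per species, with the original integrals,
#'   `rank_<scenario>` columns, `total_risk` and `median_rank`.
#' @export
risk_summary <- function(integral_table) {
  stopifnot(is.data.frame(integral_table), "species" %in% names(integral_table))
  core <- core_scenarios()
  have <- intersect(core, names(integral_table))
  if (length(have) < length(core))
    stop("integral table is missing core scenario column(s): ",
         paste(setdiff(core, have), collapse = ", "))
  out <- integral_table
  scen_cols <- setdiff(names(integral_table), "species")
  for (sc in scen_cols) {
    v <- setNames(integral_table[[sc]], integral_table$species)
    out[[paste0("rank_", sc)]] <- as.numeric(rank_species(v))
  }
  out$total_risk <- rowSums(integral_table[core])
  rank_mat <- as.matrix(out[paste0("rank_", core)])
  out$median_rank <- apply(rank_mat, 1, median)
  out
}
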