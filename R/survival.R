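#' Simulate clonogenic colony-count tables
#'
#' Colony counts are drawn binomially: each of the `cells_plated` cells
#' forms a colony with probability `plating_efficiency * p(dose)`, where
#' the surviving-fraction model is log-linear, `p(d) = exp(-lambda * d)`
#' (so `p(0) = 1`). The plating range follows standard clonogenic
#' practice (250 to 4,000 cells per well). With `stochastic = FALSE` the
#' binomial expectation is returned instead of a draw (useful as an
#' oracle).
#'
#' @param doses numeric vector of doses (agent-specific units or an
#'   ordered dose index); must include 0.
#' @param lambda log-linear kill rate (per dose unit), >= 0.
#' @param plating_efficiency probability that an untreated plated cell
#'   forms a colony, in (0, 1].
#' @param cells_plated cells seeded per well (integer in \[250, 4000\]).
#' @param n_replicates independent replicate wells per dose.
#' @param condition condition label carried into the table.
#' @param stochastic draw binomial counts (`TRUE`) or return expectations.
#' @param seed RNG seed.
#' @return data.frame with columns `condition`, `dose`, `replicate`,
#'   `plated`, `colonies`.
#' @export
simulate_survival_counts <- function(doses, lambda = 0.25,
                                     plating_efficiency = 0.5,
                                     cells_plated = 1000L,
                                     n_replicates = 3L,
                                     condition = "simulated",
                                     stochastic = TRUE,
                                     seed = 1L) {
  stopifnot(length(doses) >= 1L, all(doses >= 0), 0 %in% doses, lambda >= 0)
  if (!(plating_efficiency > 0 && plating_efficiency <= 1))
    stopf("plating efficiency must be in (0, 1]")
  if (cells_plated < 250L || cells_plated > 4000L)
    stopf("cells_plated must be in [250, 4000]")
  p <- exp(-lambda * doses)
  if (any(p <= 0 | p > 1)) stopf("surviving fraction p(dose) must be in (0, 1]")
  grid <- expand.grid(replicate = seq_len(n_replicates), dose = doses)
  prob <- plating_efficiency * exp(-lambda * grid$dose)
  colonies <- if (stochastic) {
    with_seed(subseed(seed, 2L),
              stats::rbinom(nrow(grid), cells_plated, prob))
  } else round(cells_plated * prob)
  data.frame(condition = condition, dose = grid$dose,
             replicate = grid$replicate, plated = as.integer(cells_plated),
             colonies = as.integer(colonies), stringsAsFactors = FALSE)
}

#' Surviving fraction dose-response curve
#'
#' Per replicate, the plating efficiency `PE = colonies / plated` at dose
#' 0 normalizes all doses: `SF(d) = (colonies / plated) / PE`, so SF(0) is
#' exactly 1. Replicates are then aggregated per condition and dose as
#' mean +/- SEM (or SD, selectable, since published panels mix both
#' conventions).
#'
#' @param table data.frame with columns `condition`, `dose`, `replicate`,
#'   `plated`, `colonies`; a dose-0 row is required per
#'   condition/replicate.
#' @param dispersion `"sem"` (default) or `"sd"`.
#' @return a data.frame of class `survival_curve` with columns
#'   `condition`, `dose`, `mean_sf`, `err`, `n_replicates`; per-replicate
#'   fractions in the `per_replicate` attribute.
#' @export
surviving_fraction <- function(table, dispersion = c("sem", "sd")) {
  dispersion <- match.arg(dispersion)
  stopifnot(all(c("condition", "dose", "replicate", "plated", "colonies") %in%
                  names(table)))
  if (any(table$colonies < 0) || any(table$colonies > table$plated))
    stopf("colony counts must be in [0, cells plated]")
  per_rep <- do.call(rbind, lapply(
    split(table, interaction(table$condition, table$replicate, drop = TRUE)),
    function(g) {
      z <- g[g$dose == 0, , drop = FALSE]
      if (nrow(z) == 0L)
        stopf("missing dose-0 row for condition %s replicate %s",
              g$condition[1], g$replicate[1])
      pe <- z$colonies[1] / z$plated[1]
      if (pe == 0) stopf("no colonies in untreated control (condition %s, replicate %s)",
                         g$condition[1], g$replicate[1])
      data.frame(condition = g$condition, dose = g$dose,
                 replicate = g$replicate, pe = pe,
                 sf = (g$colonies / g$plated) / pe, stringsAsFactors = FALSE)
    }))
  row.names(per_rep) <- NULL
  out <- do.call(rbind, lapply(
    split(per_rep, interaction(per_rep$condition, per_rep$dose, drop = TRUE)),
    function(g) {
      data.frame(condition = g$condition[1], dose = g$dose[1],
                 mean_sf = mean(g$sf),
                 err = if (nrow(g) > 1) {
                   if (dispersion == "sem") sem(g$sf) else stats::sd(g$sf)
                 } else NA_real_,
                 n_replicates = nrow(g), stringsAsFactors = FALSE)
    }))
  out <- out[order(out$condition, out$dose), ]
  row.names(out) <- NULL
  structure(out, per_replicate = per_rep, dispersion = dispersion,
            class = c("survival_curve", "data.frame"))
}
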