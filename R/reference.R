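# Published reference values used for cross-checks.

#' SDS micelle aggregation numbers: simulation vs experiment
#'
#' Room-temperature mean aggregation numbers for SDS micelles at two weight
#' percentages: the small-angle neutron scattering experimental values and
#' the coarse-grained simulation values they are compared against. The
#' `ratio` column (simulation / experiment) is computed at call time; the
#' under-prediction narrows with concentration.
#'
#' @return data frame with `concentration` (wt %), `n_agg_exp`,
#'   `n_agg_dpd`, `ratio`.
#' @export
sds_aggregation_reference <- function() {
  df <- data.frame(
    concentration = c(10, 20),
    n_agg_exp = c(104, 112),
    n_agg_dpd = c(54, 80)
  )
  df$ratio <- df$n_agg_dpd / df$n_agg_exp
  df
}
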