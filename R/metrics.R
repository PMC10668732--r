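#' Scaled genetic-gain trajectory
#'
#' Genetic gain per cycle as `(mean TBV(cycle) - mean TBV(reference)) / SD`,
#' where the SD is the genetic standard deviation at the reference cycle —
#' gain is zero at the reference and expressed in genetic standard
#' deviations. For the TMI, true breeding values are aggregated with the
#' index weights before averaging; the reference SD is taken from the
#' breeding population (rams + ewes) as in routine reporting. Cycles are
#' relabelled 0 (reference) to `n` post-reference.
#'
#' @param metrics Long metrics tibble of one replicate ([sim_metrics()]).
#' @param cohort Cohort whose mean is tracked (default `"breeding_rams"`).
#' @param trait `"TMI"` or a trait name.
#' @param reference_cycle Reference (raw) cycle, default 10.
#' @param sd_cohort Cohort providing the reference SD (default
#'   `"breeding_pop"`).
#' @return Tibble `cycle` (0 = reference), `raw_cycle`, `gain`.
#' @export
genetic_gain_trajectory <- function(metrics, cohort = "breeding_rams",
                                    trait = "TMI", reference_cycle = 10,
                                    sd_cohort = "breeding_pop") {
  mm <- metrics[metrics$metric == "mean_tbv" & metrics$cohort == cohort &
                  metrics$trait == trait & metrics$cycle >= reference_cycle, ]
  mm <- mm[order(mm$cycle), ]
  if (nrow(mm) == 0 || mm$cycle[1] != reference_cycle)
    stop("metrics do not cover the reference cycle", call. = FALSE)
  if (trait == "TMI") {
    sdr <- metrics$value[metrics$metric == "sd_tbv" &
                           metrics$cohort == sd_cohort &
                           metrics$trait == "TMI" &
                           metrics$cycle == reference_cycle]
  } else {
    sdr <- sqrt(metrics$value[metrics$metric == "var_tbv" &
                                metrics$cohort == "breeding_pop" &
                                metrics$trait == trait &
                                metrics$cycle == reference_cycle])
  }
  if (length(sdr) != 1 || !is.finite(sdr) || sdr <= 0)
    stop("zero or missing reference-cycle genetic SD", call. = FALSE)
  tibble(cycle = mm$cycle - reference_cycle, raw_cycle = mm$cycle,
         gain = (mm$value - mm$value[1]) / sdr)
}

#' EBV accuracy as a correlation
#'
#' Pearson correlation between true and estimated breeding values within a
#' cohort; for the TMI, correlate the index aggregated over TBVs with the
#' index aggregated over EBVs.
#'
#' @param true,estimated Numeric vectors (length >= 3).
#' @return Correlation, or `NA` when either vector has zero variance.
#' @export
#' @examples
#' ebv_accuracy(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8))
ebv_accuracy <- function(true, estimated) {
  if (length(true) != length(estimated) || length(true) < 3)
    stop("need paired vectors of length >= 3", call. = FALSE)
  safe_cor(true, estimated)
}

#' Genetic variance within a cohort
#'
#' Unbiased (n - 1) empirical variance of true breeding values per trait.
#'
#' @param tbv Matrix animals x traits (or a vector for one trait).
#' @return Named per-trait variances (or a scalar).
#' @export
genetic_variance <- function(tbv) {
  if (is.matrix(tbv)) apply(tbv, 2, var) else var(tbv)
}

#' Paired two-sample t test over replicates
#'
#' Standard paired Student's t test (two-sided), with replicates matched by
#' position — scenario runs share replicate seeds, so pairing by replicate
#' removes the common founder/burn-in noise.
#'
#' @param values_a,values_b Per-replicate values, equal length >= 2.
#' @return Tibble `estimate` (mean difference), `t`, `df`, `p`.
#' @export
paired_t_test <- function(values_a, values_b) {
  if (length(values_a) != length(values_b) || length(values_a) < 2)
    stop("need paired samples of length >= 2", call. = FALSE)
  d <- values_a - values_b
  if (sd(d) == 0) {
    if (all(d == 0))
      return(tibble(estimate = 0, t = 0, df = length(d) - 1, p = 1))
    stop("degenerate: differences have zero variance", call. = FALSE)
  }
  tt <- t.test(values_a, values_b, paired = TRUE)
  tibble(estimate = unname(tt$estimate), t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value)
}
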