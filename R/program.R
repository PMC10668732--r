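#' Breeding-program configuration
#'
#' Demographic and selection parameters of the simulated herdbook program.
#' Defaults describe the German Merino population: 469 breeding rams and
#' 7,185 breeding ewes, litter-size probabilities 0.56/0.40/0.04 for
#' singles/twins/triplets, 10% lamb mortality before day 42, licensing of
#' the best 2% of male lambs (with a further 10% of presented males not
#' licensed) and herdbook registration of the best 20% of female lambs.
#' `scale_factor` scales all cohort sizes proportionally (rounding up) so
#' the selected fractions — and with them selection intensity — are
#' preserved at desk scale.
#'
#' @param n_breeding_rams,n_breeding_ewes Breeding cohort sizes (full scale).
#' @param litter_probs Probabilities of 1/2/3 lambs per lambing (sum to 1).
#' @param lamb_mortality Probability a lamb dies before postnatal day 42.
#' @param male_selected_fraction Fraction of surviving male lambs licensed.
#' @param female_selected_fraction Fraction of female lambs registered.
#' @param licensing_rejection_fraction Fraction of presented males not
#'   licensed, removed at random.
#' @param survival_schedule Per-age, per-sex retention probabilities, a
#'   tibble `sex`, `age`, `retention` (see [default_survival_schedule()]).
#' @param scale_factor Population scaling multiplier in (0, 1].
#' @param n_founders Founder panel size (full scale; scaled like cohorts).
#' @return A `program_config` list; scaled cohort sizes are in `$n_rams`,
#'   `$n_ewes`, `$n_founders_scaled`.
#' @export
program_config <- function(n_breeding_rams = 469, n_breeding_ewes = 7185,
                           litter_probs = c(0.56, 0.40, 0.04),
                           lamb_mortality = 0.1,
                           male_selected_fraction = 0.02,
                           female_selected_fraction = 0.20,
                           licensing_rejection_fraction = 0.1,
                           survival_schedule = default_survival_schedule(),
                           scale_factor = 1,
                           n_founders = 785) {
  stopifnot(abs(sum(litter_probs) - 1) < 1e-8, all(litter_probs >= 0),
            lamb_mortality >= 0, lamb_mortality < 1,
            male_selected_fraction > 0, male_selected_fraction <= 1,
            female_selected_fraction > 0, female_selected_fraction <= 1,
            licensing_rejection_fraction >= 0,
            licensing_rejection_fraction < 1,
            scale_factor > 0, scale_factor <= 1,
            all(c("sex", "age", "retention") %in% names(survival_schedule)))
  structure(list(
    n_breeding_rams = n_breeding_rams, n_breeding_ewes = n_breeding_ewes,
    litter_probs = litter_probs, lamb_mortality = lamb_mortality,
    male_selected_fraction = male_selected_fraction,
    female_selected_fraction = female_selected_fraction,
    licensing_rejection_fraction = licensing_rejection_fraction,
    survival_schedule = survival_schedule,
    scale_factor = scale_factor,
    n_founders = n_founders,
    n_rams = as.integer(ceiling(scale_factor * n_breeding_rams)),
    n_ewes = as.integer(ceiling(scale_factor * n_breeding_ewes)),
    n_founders_scaled = as.integer(ceiling(scale_factor * n_founders))
  ), class = "program_config")
}

#' Default age- and sex-specific retention schedule
#'
#' Probability that a breeding animal of a given age and sex stays in the
#' program for another cycle: rams are retained with probability 0.65 per
#' year through age 6 (exit at 7), ewes with 0.80 per year through age 8
#' (exit at 9) — geometric-style culling that yields a realistic overlapping
#' age structure with ram turnover of roughly a third per year. Note that
#' with the fixed selection gates (2% of male lambs licensed, 20% of female
#' lambs registered) this outflow exceeds the inflow of new breeding
#' animals, so cohorts settle below their nominal sizes; shortfalls are
#' logged each cycle. The schedule is a calibration knob: override it to
#' match an observed culling pattern.
#'
#' @return Tibble with columns `sex`, `age`, `retention`.
#' @export
default_survival_schedule <- function() {
  dplyr::bind_rows(
    tibble(sex = "M", age = 1:7, retention = c(rep(0.65, 6), 0)),
    tibble(sex = "F", age = 1:9, retention = c(rep(0.80, 8), 0))
  )
}

#' Truncation selection on a merit index
#'
#' Selects the `ceiling(fraction * n)` candidates with the highest index
#' value; ties at the cutoff are broken by a seeded uniform draw.
#'
#' @param candidates Vector of candidate ids.
#' @param index Numeric index values, same length/order as `candidates`.
#' @param fraction Selected fraction in (0, 1].
#' @return Selected ids.
#' @export
select_top <- function(candidates, index, fraction) {
  stopifnot(fraction > 0, fraction <= 1,
            length(candidates) == length(index))
  if (anyNA(index)) stop("missing index values", call. = FALSE)
  k <- ceiling(fraction * length(candidates))
  ord <- order(-index, runif(length(index)))
  candidates[ord[seq_len(k)]]
}

#' Age- and sex-dependent exits
#'
#' Each animal is independently retained with the probability its (sex, age)
#' row in the schedule specifies; ages not covered are an error.
#'
#' @param cohort Tibble with columns `id`, `sex`, `age`.
#' @param schedule Retention schedule (see [default_survival_schedule()]).
#' @return Ids of retained animals.
#' @export
apply_exits <- function(cohort, schedule) {
  key <- paste(cohort$sex, cohort$age)
  skey <- paste(schedule$sex, schedule$age)
  pos <- match(key, skey)
  if (anyNA(pos))
    stop("survival schedule missing entries for: ",
         paste(unique(key[is.na(pos)]), collapse = ", "), call. = FALSE)
  p <- schedule$retention[pos]
  cohort$id[runif(nrow(cohort)) < p]
}

#' Mate the breeding cohorts
#'
#' Ewes are partitioned randomly into near-equal harems, one per ram (no
#' assortative mating); every ewe lambs once. Litter size is categorical
#' with the configured probabilities, lamb sex is Bernoulli(1/2), and each
#' lamb independently dies before day 42 with the configured probability
#' (dead lambs are not instantiated). Lamb genomes arise by meiosis from
#' both parents.
#'
#' @param rams,ewes Id vectors of the parent cohorts.
#' @param haplo Haplotype pool (list `mat`, `ids`) holding both cohorts.
#' @param map Genome map.
#' @param config A [program_config()].
#' @return List: `lambs` (tibble `sire`, `dam`, `sex`), `haplotypes`
#'   (matrix, loci x haplotypes, two columns per lamb), `n_born` (before
#'   mortality).
#' @export
mate_cohorts <- function(rams, ewes, haplo, map, config) {
  if (length(rams) < 1 || length(ewes) < 1)
    stop("empty parent cohort", call. = FALSE)
  ewes_shuffled <- if (length(ewes) > 1) sample(ewes) else ewes
  rams_shuffled <- if (length(rams) > 1) sample(rams) else rams
  sire_of_ewe <- rams_shuffled[rep_len(seq_along(rams_shuffled),
                                       length(ewes_shuffled))]
  litter <- sample.int(3, length(ewes_shuffled), replace = TRUE,
                       prob = config$litter_probs)
  n_born <- sum(litter)
  lamb_sire <- rep(sire_of_ewe, litter)
  lamb_dam <- rep(ewes_shuffled, litter)
  alive <- runif(n_born) >= config$lamb_mortality
  lamb_sire <- lamb_sire[alive]; lamb_dam <- lamb_dam[alive]
  n <- length(lamb_sire)
  sex <- ifelse(rbinom(n, 1, 0.5) == 1, "M", "F")

  spos <- match(lamb_sire, haplo$ids)
  dpos <- match(lamb_dam, haplo$ids)
  if (anyNA(spos) || anyNA(dpos))
    stop("parent haplotypes missing from pool", call. = FALSE)
  pat <- gametes_from_cols(haplo$mat, 2 * spos - 1, 2 * spos, map)
  mat <- gametes_from_cols(haplo$mat, 2 * dpos - 1, 2 * dpos, map)
  H <- matrix(0L, nrow(haplo$mat), 2 * n)
  H[, seq(1, 2 * n, 2)] <- pat
  H[, seq(2, 2 * n, 2)] <- mat

  list(lambs = tibble(sire = lamb_sire, dam = lamb_dam, sex = sex),
       haplotypes = H, n_born = n_born)
}
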