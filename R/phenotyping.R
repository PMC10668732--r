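#' Scenario recording rules
#'
#' The three progeny-testing scenarios: `ST` (station testing only, 8 male
#' lambs per sire recorded for the station fattening, carcass and feed
#' conversion traits), `FT` (field testing only, 20 male lambs per sire
#' recorded for the four field fattening traits), and `ST_FT` (both). In
#' every scenario all
#' surviving lambs are scored for WL, MC and BC, ewes get an NL record at
#' first lambing, and a random 25% of the lamb cohort is scored for nursing
#' ability.
#'
#' When both schemes run, the station and field groups are drawn
#' independently by default and may overlap: the default group sizes exceed
#' the male progeny a sire typically has, so the combined scheme records
#' essentially every son in both environments. Set `ft_disjoint = TRUE` to
#' force disjoint groups (field lambs drawn only from sons not station
#' tested).
#'
#' @param scenario One of `"ST"`, `"FT"`, `"ST_FT"`.
#' @param st_progeny_per_sire,ft_progeny_per_sire Progeny-test group sizes.
#' @param na_fraction Fraction of surviving lambs scored for `NA`.
#' @param ft_disjoint Force disjoint station/field groups per sire.
#' @return A `recording_rules` list.
#' @export
recording_rules <- function(scenario = c("ST", "FT", "ST_FT"),
                            st_progeny_per_sire = 8,
                            ft_progeny_per_sire = 20,
                            na_fraction = 0.25,
                            ft_disjoint = FALSE) {
  scenario <- match.arg(scenario)
  stopifnot(st_progeny_per_sire >= 0, ft_progeny_per_sire >= 0,
            na_fraction >= 0, na_fraction <= 1)
  structure(list(scenario = scenario,
                 st = scenario %in% c("ST", "ST_FT"),
                 ft = scenario %in% c("FT", "ST_FT"),
                 st_progeny_per_sire = st_progeny_per_sire,
                 ft_progeny_per_sire = ft_progeny_per_sire,
                 na_fraction = na_fraction,
                 ft_disjoint = ft_disjoint),
            class = "recording_rules")
}

station_traits <- function() c("ADG_S", "FLN_S", "UMD_S", "UFD_S", "SW_S",
                               "BMA_S", "WC_S", "SFA_S", "PKF_S", "FC_S")
field_traits <- function() c("ADG_F", "FLN_F", "UMD_F", "UFD_F")

#' Record one cycle's phenotypes
#'
#' Applies the scenario recording rules to the current lamb crop: (a) `NL`
#' on every ewe at her first lambing; (b) `NA` on a random `na_fraction` of
#' surviving lambs; (c) `WL`, `MC`, `BC` on all surviving lambs (available
#' before selection); (d) progeny testing per sire — station and/or field
#' groups of male lambs, each sampled without replacement (overlapping by
#' default, disjoint under `ft_disjoint`); sires with fewer eligible sons
#' contribute all of them.
#' Phenotypes are the animal's true breeding value plus an independent
#' residual set by the trait heritability.
#'
#' @param lambs Tibble of the surviving lamb crop: `id`, `sex`, `sire`.
#' @param ewes_lambed Ids of ewes that lambed this cycle.
#' @param tbv True-breeding-value matrix indexed by animal id (rows) and
#'   trait (columns).
#' @param traits Trait table ([merino_traits()]).
#' @param rules A [recording_rules()].
#' @param cycle Current cycle index.
#' @param nl_recorded Ids of ewes that already carry an NL record.
#' @return List: `records` (tibble `animal`, `trait`, `cycle`, `value`),
#'   `shortfall` (named counts of sires with fewer sons than the test-group
#'   size).
#' @export
record_phenotypes <- function(lambs, ewes_lambed, tbv, traits, rules, cycle,
                              nl_recorded = integer()) {
  h2 <- setNames(traits$h2, traits$trait)
  pairs_animal <- integer(); pairs_trait <- character()

  add <- function(animals, trts) {
    if (length(animals) == 0) return()
    pairs_animal <<- c(pairs_animal, rep(animals, times = length(trts)))
    pairs_trait <<- c(pairs_trait, rep(trts, each = length(animals)))
  }

  # (a) NL at first lambing
  add(setdiff(ewes_lambed, nl_recorded), "NL")
  # (b) nursing ability on a random share of the lamb crop
  n_na <- round(rules$na_fraction * nrow(lambs))
  if (n_na > 0) add(sample(lambs$id, n_na), "NA")
  # (c) conformation traits on all surviving lambs, before selection
  add(lambs$id, c("WL", "MC", "BC"))

  # (d) progeny testing on male lambs, grouped by sire
  shortfall <- c(st = 0L, ft = 0L)
  if (rules$st || rules$ft) {
    males <- lambs[lambs$sex == "M", ]
    by_sire <- split(males$id, males$sire)
    for (sons in by_sire) {
      avail <- sons
      if (rules$st) {
        k <- min(rules$st_progeny_per_sire, length(avail))
        if (k < rules$st_progeny_per_sire) shortfall["st"] <- shortfall["st"] + 1L
        st_set <- if (k > 0) sample_ids(avail, k) else integer()
        add(st_set, station_traits())
        if (isTRUE(rules$ft_disjoint)) avail <- setdiff(avail, st_set)
      }
      if (rules$ft) {
        k <- min(rules$ft_progeny_per_sire, length(avail))
        if (k < rules$ft_progeny_per_sire) shortfall["ft"] <- shortfall["ft"] + 1L
        ft_set <- if (k > 0) sample_ids(avail, k) else integer()
        add(ft_set, field_traits())
      }
    }
  }

  if (length(pairs_animal) == 0) {
    return(list(records = tibble(animal = integer(), trait = character(),
                                 cycle = integer(), value = numeric()),
                shortfall = shortfall))
  }
  base <- tbv[cbind(pairs_animal, match(pairs_trait, colnames(tbv)))]
  value <- base + rnorm(length(base)) *
    sqrt(residual_variance(h2[pairs_trait]))
  list(records = tibble(animal = pairs_animal, trait = pairs_trait,
                        cycle = cycle, value = unname(value)),
       shortfall = shortfall)
}

# sample() without its scalar-x surprise
sample_ids <- function(x, k) x[sample.int(length(x), k)]
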