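#' Initialise a breeding-program simulation
#'
#' Builds the starting state: synthetic founders in linkage equilibrium,
#' `burn_in_generations` of random mating to create relatedness and a
#' pedigree, an initial breeding population with the configured cohort
#' sizes, and a pleiotropic QTL architecture standardized (mean 100,
#' genetic variance 10 per trait) on that initial breeding population.
#'
#' @param config A [program_config()].
#' @param traits Trait table ([merino_traits()]).
#' @param C True genetic correlation matrix of the simulated traits;
#'   projected to the PSD cone if needed.
#' @param C_eval Correlation matrix the BLUP evaluation assumes; defaults
#'   to [evaluation_correlations()] of `C` (no cross-environment
#'   parameters, as in routine evaluations).
#' @param map Genome map ([genome_map()]).
#' @param n_qtl Number of QTL underlying all traits.
#' @param burn_in_generations Random-mating generations before the program.
#' @param maf Founder allele-frequency bounds `c(low, high)`.
#' @param blup_tol PCG tolerance used for the per-cycle evaluations.
#' @param reference_cycle Cycle whose breeding population anchors the
#'   genetic-gain scale (gain zero, SD unit) and from which kinship is
#'   tracked.
#' @return A `merino_sim` state object.
#' @export
new_simulation <- function(config = program_config(),
                           traits = merino_traits(),
                           C = trait_correlations(),
                           C_eval = NULL,
                           map = genome_map(),
                           n_qtl = 1000,
                           burn_in_generations = 5,
                           maf = c(0.05, 0.5),
                           blup_tol = 1e-6,
                           reference_cycle = 10) {
  stopifnot(burn_in_generations >= 1)
  C <- project_to_psd(C)
  C_eval <- C_eval %||% evaluation_correlations(C)
  stopifnot(identical(dimnames(C_eval), dimnames(C)))
  nf <- config$n_founders_scaled
  founders <- sim_founder_haplotypes(nf, map, maf[1], maf[2])
  burn <- burn_in_random_mating(
    founders, map, burn_in_generations,
    final_sex_counts = c(M = config$n_rams, F = config$n_ewes))

  bg <- burn_in_generations
  n_burn <- nrow(burn$pedigree)
  N <- nf + n_burn
  sire <- c(integer(nf), burn$pedigree$sire)
  dam <- c(integer(nf), burn$pedigree$dam)
  sex <- c(burn$founder_sexes, burn$pedigree$sex)
  birth <- c(rep(-bg, nf), burn$pedigree$generation - bg)

  arch <- build_architecture(burn$haplotypes, traits, C, n_qtl)
  inb <- cpp_inbreeding_ml(sire, dam, numeric(0), numeric(0))
  tbv <- matrix(NA_real_, N, nrow(traits),
                dimnames = list(NULL, traits$trait))
  base_ids <- which(birth == 0)
  tbv[base_ids, ] <- true_breeding_values(burn$haplotypes, arch)

  alive <- logical(N)
  alive[base_ids] <- TRUE

  structure(list(
    config = config, traits = traits, C = C, C_eval = C_eval,
    G0 = 10 * C_eval,
    R0 = setNames(residual_variance(traits$h2), traits$trait),
    weights = merino_tmi_weights(traits),
    map = map, arch = arch,
    sire = sire, dam = dam, sex = sex, birth = birth,
    alive = alive, exit = rep(NA_integer_, N),
    F = inb$F, D = inb$D,
    tbv = tbv,
    haplo = list(mat = unclass(burn$haplotypes), ids = base_ids),
    rams = base_ids[sex[base_ids] == "M"],
    ewes = base_ids[sex[base_ids] == "F"],
    cycle = 0L,
    phenotypes = tibble(animal = integer(), trait = character(),
                        cycle = integer(), value = numeric()),
    nl_recorded = integer(),
    last_eval = NULL,
    metrics = list(),
    log = character(),
    blup_tol = blup_tol,
    reference_cycle = reference_cycle
  ), class = "merino_sim")
}

#' @export
print.merino_sim <- function(x, ...) {
  cat("<merino_sim> cycle ", x$cycle, ": ", length(x$rams),
      " breeding rams, ", length(x$ewes), " breeding ewes, ",
      length(x$sire), " animals in pedigree\n", sep = "")
  invisible(x)
}

#' Pedigree of a simulation state
#'
#' @param sim A `merino_sim`.
#' @return Tibble `id`, `sire`, `dam`, `sex`, `birth_cycle`, `alive`,
#'   `exit_cycle`.
#' @export
sim_pedigree <- function(sim) {
  tibble(id = seq_along(sim$sire), sire = sim$sire, dam = sim$dam,
         sex = sim$sex, birth_cycle = sim$birth, alive = sim$alive,
         exit_cycle = sim$exit)
}

#' Advance the breeding program by one cycle
#'
#' Runs one annual cycle in the fixed within-cycle order: (1) mate the
#' breeding cohorts and generate the lamb crop; (2) record phenotypes under
#' the scenario rules; (3) run the multi-trait BLUP evaluation once and
#' compute the total merit index; (4) timepoint-1 selection — the best males
#' amounting to 2% of the surviving lamb crop are presented at licensing (a
#' random share of them rejected) and the best females amounting to 20% of
#' the crop are registered; (5)
#' timepoint-2 — age/sex exits are applied to the breeding cohorts and the
#' highest-TMI survivors are retained; (6) cohorts are refilled to their
#' configured sizes with the new entrants, truncating by TMI if oversupplied
#' (shortfalls are logged and the cohort runs short).
#'
#' @param sim A `merino_sim`.
#' @param rules A [recording_rules()].
#' @param selection `"tmi"` for index selection; `"random"` replaces the
#'   index by uniform noise and skips the evaluation (no-selection null).
#' @return The advanced `merino_sim` (metrics for the cycle appended).
#' @export
advance_cycle <- function(sim, rules, selection = c("tmi", "random")) {
  selection <- match.arg(selection)
  cfg <- sim$config
  cyc <- sim$cycle + 1L

  ## (1) mating
  mt <- mate_cohorts(sim$rams, sim$ewes, sim$haplo, sim$map, cfg)
  n_lambs <- nrow(mt$lambs)
  lamb_ids <- seq.int(length(sim$sire) + 1L, length.out = n_lambs)
  sim$sire <- c(sim$sire, mt$lambs$sire)
  sim$dam <- c(sim$dam, mt$lambs$dam)
  sim$sex <- c(sim$sex, mt$lambs$sex)
  sim$birth <- c(sim$birth, rep(cyc, n_lambs))
  sim$alive <- c(sim$alive, rep(TRUE, n_lambs))
  sim$exit <- c(sim$exit, rep(NA_integer_, n_lambs))
  inb <- cpp_inbreeding_ml(sim$sire, sim$dam, sim$F, sim$D)
  sim$F <- inb$F; sim$D <- inb$D
  sim$haplo$mat <- cbind(sim$haplo$mat, mt$haplotypes)
  sim$haplo$ids <- c(sim$haplo$ids, lamb_ids)
  lamb_tbv <- true_breeding_values(new_haplo_set(mt$haplotypes), sim$arch)
  sim$tbv <- rbind(sim$tbv, lamb_tbv)

  lambs <- tibble(id = lamb_ids, sex = mt$lambs$sex, sire = mt$lambs$sire)

  ## (2) phenotype recording (before the evaluation, so conformation traits
  ##     are available at selection)
  rec <- record_phenotypes(lambs, sim$ewes, sim$tbv, sim$traits, rules, cyc,
                           sim$nl_recorded)
  sim$phenotypes <- dplyr::bind_rows(sim$phenotypes, rec$records)
  sim$nl_recorded <- union(sim$nl_recorded, sim$ewes)
  if (any(rec$shortfall > 0))
    sim$log <- c(sim$log, sprintf(
      "cycle %d: %d sires short of ST group size, %d short of FT",
      cyc, rec$shortfall["st"], rec$shortfall["ft"]))

  ## (3) evaluation
  if (selection == "tmi") {
    ev <- build_evaluation_pedigree(
      sim_pedigree(sim), sim$phenotypes, cyc,
      extra_animals = c(sim$rams, sim$ewes, lamb_ids))
    fit <- solve_blup(ev$records, ev$pedigree, sim$G0, sim$R0,
                      method = "pcg", tol = sim$blup_tol,
                      F = sim$F[ev$pedigree$orig_id])
    ebv <- fit$ebv
    rownames(ebv) <- ev$pedigree$orig_id
    tmi_all <- rep(NA_real_, length(sim$sire))
    tmi_all[ev$pedigree$orig_id] <- total_merit_index(ebv, sim$weights)
    sim$last_eval <- list(ids = ev$pedigree$orig_id, ebv = ebv,
                          tmi = tmi_all, iterations = fit$iterations)
  } else {
    ebv <- NULL
    tmi_all <- runif(length(sim$sire))
  }

  ## (4) timepoint 1: entry selection among the lamb crop. The selected
  ## fractions refer to the whole surviving crop (all lambs are eligible
  ## candidates), taken from the respective sex.
  male_lambs <- lambs$id[lambs$sex == "M"]
  female_lambs <- lambs$id[lambs$sex == "F"]
  n_lic <- min(ceiling(cfg$male_selected_fraction * n_lambs),
               length(male_lambs))
  licensing <- select_top(male_lambs, tmi_all[male_lambs],
                          n_lic / length(male_lambs))
  n_rej <- round(cfg$licensing_rejection_fraction * length(licensing))
  rejected <- if (n_rej > 0) sample_ids(licensing, n_rej) else integer()
  new_rams <- setdiff(licensing, rejected)
  n_reg <- min(ceiling(cfg$female_selected_fraction * n_lambs),
               length(female_lambs))
  new_ewes <- select_top(female_lambs, tmi_all[female_lambs],
                         n_reg / length(female_lambs))

  ## cycle metrics: cohorts as they bred/were selected this cycle
  sim$metrics[[cyc]] <- collect_metrics(sim, cyc, ebv, tmi_all, licensing)

  ## (5) timepoint 2: stochastic age/sex exits, then TMI retention among the
  ##     survivors (binds only when survivors exceed the open slots)
  keep_old <- function(cohort, target) {
    surv <- apply_exits(tibble(id = cohort, sex = sim$sex[cohort],
                               age = cyc - sim$birth[cohort]),
                        cfg$survival_schedule)
    if (length(surv) > target)
      surv <- select_top(surv, tmi_all[surv], target / length(surv))
    surv
  }
  old_rams <- keep_old(sim$rams, cfg$n_rams)
  old_ewes <- keep_old(sim$ewes, cfg$n_ewes)

  ## (6) refill to configured cohort sizes
  refill <- function(old, new, target, label) {
    slots <- target - length(old)
    if (slots < length(new)) {
      new <- select_top(new, tmi_all[new], max(slots, 1) / length(new))
      new <- new[seq_len(max(slots, 0))]
    } else if (slots > length(new)) {
      sim$log <<- c(sim$log, sprintf(
        "cycle %d: %s cohort short by %d", cyc, label,
        slots - length(new)))
    }
    c(old, new)
  }
  rams_next <- refill(old_rams, new_rams, cfg$n_rams, "ram")
  ewes_next <- refill(old_ewes, new_ewes, cfg$n_ewes, "ewe")

  ## bookkeeping: exits and haplotype pool
  gone <- setdiff(c(sim$rams, sim$ewes, lamb_ids), c(rams_next, ewes_next))
  sim$alive[gone] <- FALSE
  sim$exit[gone] <- cyc
  keep <- c(rams_next, ewes_next)
  pos <- match(keep, sim$haplo$ids)
  cols <- as.vector(rbind(2 * pos - 1, 2 * pos))
  sim$haplo <- list(mat = sim$haplo$mat[, cols, drop = FALSE], ids = keep)

  sim$rams <- rams_next
  sim$ewes <- ewes_next
  sim$cycle <- cyc
  sim
}

# per-cycle metric rows (long format)
collect_metrics <- function(sim, cyc, ebv, tmi_all, licensing) {
  traits <- colnames(sim$tbv)
  rows <- list()
  push <- function(cohort, metric, trait, value) {
    rows[[length(rows) + 1L]] <<- tibble(
      cycle = cyc, cohort = cohort, metric = metric, trait = trait,
      value = value)
  }

  cohorts <- list(breeding_rams = sim$rams,
                  breeding_pop = c(sim$rams, sim$ewes),
                  licensing = licensing)
  for (nm in names(cohorts)) {
    ids <- cohorts[[nm]]
    tb <- sim$tbv[ids, , drop = FALSE]
    tmi_tbv <- total_merit_index(tb, sim$weights)
    push(nm, "mean_tbv", "TMI", mean(tmi_tbv))
    push(nm, "sd_tbv", "TMI", sd(tmi_tbv))
    push(nm, "mean_tbv", traits, colMeans(tb))
    if (nm == "breeding_pop")
      push(nm, "var_tbv", traits, apply(tb, 2, var))
    if (!is.null(ebv) && nm %in% c("breeding_rams", "licensing")) {
      eb <- ebv[as.character(ids), , drop = FALSE]
      push(nm, "accuracy", "TMI",
           safe_cor(tmi_tbv, total_merit_index(eb, sim$weights)))
      push(nm, "accuracy", traits,
           vapply(traits, function(tr) safe_cor(tb[, tr], eb[, tr]),
                  numeric(1)))
    }
  }
  if (cyc >= sim$reference_cycle) {
    ped <- tibble(id = seq_along(sim$sire), sire = sim$sire, dam = sim$dam)
    push("breeding_pop", "kinship", "ALL",
         mean_kinship(ped, c(sim$rams, sim$ewes), F = sim$F))
  }
  dplyr::bind_rows(rows)
}

safe_cor <- function(a, b) {
  if (length(a) < 3 || sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Per-cycle metrics of a simulation
#'
#' @param sim A `merino_sim` that has been advanced at least one cycle.
#' @return Long tibble `cycle`, `cohort`, `metric`, `trait`, `value`:
#'   cohort mean/SD of true breeding values (TMI-aggregated and per trait),
#'   EBV accuracy (Pearson correlation of true and estimated values), TBV
#'   variance per trait, and mean kinship of the breeding population from
#'   the reference cycle onward.
#' @export
sim_metrics <- function(sim) {
  dplyr::bind_rows(sim$metrics)
}
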