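#' Study configuration
#'
#' Bundles everything a scenario sweep needs. The `"desk"` profile (default)
#' runs the program at one tenth of the real population size with 10
#' replicates; selection intensities are preserved because all cohort sizes
#' scale together, so gain and accuracy are comparable to the full-scale
#' study while a three-scenario sweep stays a desk job. The `"full"` profile
#' is the real-size study (scale 1, 50 replicates).
#'
#' @param profile `"desk"` or `"full"`; sets `scale_factor`/`n_replicates`
#'   defaults (explicit arguments always win).
#' @param program A [program_config()]; default built from the profile.
#' @param traits,C,map Trait table, true genetic correlation matrix,
#'   genome map.
#' @param C_eval Correlation matrix assumed by the evaluation (default: `C`
#'   without cross-environment entries, see [evaluation_correlations()]).
#' @param ft_disjoint Force disjoint station/field progeny-test groups (see
#'   [recording_rules()]).
#' @param n_cycles Breeding cycles per replicate (default 20; cycles before
#'   `reference_cycle` are the demographic burn-in and are discarded from
#'   gain reporting).
#' @param reference_cycle Gain/kinship reference (default 10).
#' @param n_replicates Independent runs per scenario.
#' @param seed Master seed; per-replicate streams are derived from it and
#'   shared across scenarios (common random numbers) so paired tests are
#'   well defined.
#' @param n_qtl,burn_in_generations,maf Genome/architecture parameters.
#' @param st_progeny_per_sire,ft_progeny_per_sire,na_fraction Recording
#'   parameters passed to [recording_rules()].
#' @param blup_tol PCG tolerance for per-cycle evaluations.
#' @return A `study_config` list.
#' @export
study_config <- function(profile = c("desk", "full"),
                         program = NULL,
                         traits = merino_traits(),
                         C = trait_correlations(),
                         C_eval = NULL,
                         map = genome_map(),
                         n_cycles = 20, reference_cycle = 10,
                         n_replicates = NULL, seed = 1,
                         n_qtl = 1000, burn_in_generations = 5,
                         maf = c(0.05, 0.5),
                         st_progeny_per_sire = 8, ft_progeny_per_sire = 20,
                         na_fraction = 0.25, ft_disjoint = FALSE,
                         blup_tol = 1e-6) {
  profile <- match.arg(profile)
  if (is.null(program))
    program <- program_config(scale_factor = if (profile == "desk") 0.1 else 1)
  if (is.null(n_replicates))
    n_replicates <- if (profile == "desk") 10L else 50L
  cfg <- structure(list(
    profile = profile, program = program, traits = traits, C = C,
    C_eval = C_eval, map = map,
    n_cycles = as.integer(n_cycles),
    reference_cycle = as.integer(reference_cycle),
    n_replicates = as.integer(n_replicates), seed = as.integer(seed),
    n_qtl = as.integer(n_qtl),
    burn_in_generations = as.integer(burn_in_generations), maf = maf,
    st_progeny_per_sire = st_progeny_per_sire,
    ft_progeny_per_sire = ft_progeny_per_sire,
    na_fraction = na_fraction, ft_disjoint = ft_disjoint,
    blup_tol = blup_tol
  ), class = "study_config")
  validate_study_config(cfg)
}

#' Validate a study configuration
#'
#' @param config A `study_config` (or a plain list with the same fields).
#' @return The validated config, invisibly usable in a pipe; errors describe
#'   the offending field.
#' @export
validate_study_config <- function(config) {
  with(config, {
    if (n_cycles <= reference_cycle)
      stop("n_cycles must exceed reference_cycle", call. = FALSE)
    if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
    if (!inherits(program, "program_config"))
      stop("program must be a program_config()", call. = FALSE)
    if (nrow(traits) < 1) stop("empty trait table", call. = FALSE)
    check_correlation_matrix(C, tol = 1e-6)
    if (!identical(rownames(C), traits$trait))
      stop("correlation matrix dimnames must match the trait table",
           call. = FALSE)
  })
  invisible(config)
}

# per-replicate RNG streams: phase 1 (founders/burn-in/architecture) is
# shared across scenarios, phase 2 (breeding cycles) is scenario-divergent
replicate_seed <- function(master, replicate, phase) {
  as.integer((as.numeric(master) * 100003 + replicate * 10007 +
                phase * 101) %% 2147483629)
}

run_replicate <- function(config, rules, replicate) {
  set.seed(replicate_seed(config$seed, replicate, 1L))
  sim <- new_simulation(config$program, config$traits, config$C,
                        C_eval = config$C_eval, map = config$map,
                        n_qtl = config$n_qtl,
                        burn_in_generations = config$burn_in_generations,
                        maf = config$maf, blup_tol = config$blup_tol,
                        reference_cycle = config$reference_cycle)
  set.seed(replicate_seed(config$seed, replicate, 2L))
  for (i in seq_len(config$n_cycles)) sim <- advance_cycle(sim, rules)
  list(metrics = sim_metrics(sim), log = sim$log)
}

#' Run one scenario of the breeding-program study
#'
#' Simulates `n_replicates` independent runs of `n_cycles` breeding cycles
#' under one progeny-testing scenario. Founder genomes, burn-in and QTL
#' architecture are seeded identically across scenarios for a given
#' replicate (common random numbers); the cycle phase then diverges with the
#' recording scheme.
#'
#' @param config A [study_config()].
#' @param scenario `"ST"`, `"FT"`, or `"ST_FT"`.
#' @param out_dir Optional directory; per-replicate metrics are written as
#'   CSV together with a small YAML run log (seed, scenario, shortfalls).
#' @param progress Print a line per replicate.
#' @return A `merino_run`: long tibble of per-cycle metrics with columns
#'   `scenario`, `replicate`, `cycle`, `cohort`, `metric`, `trait`, `value`.
#' @export
run_scenario <- function(config, scenario = c("ST", "FT", "ST_FT"),
                         out_dir = NULL, progress = FALSE) {
  scenario <- match.arg(scenario)
  validate_study_config(config)
  rules <- recording_rules(scenario, config$st_progeny_per_sire,
                           config$ft_progeny_per_sire, config$na_fraction,
                           ft_disjoint = isTRUE(config$ft_disjoint))
  out <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    res <- run_replicate(config, rules, r)
    out[[r]] <- dplyr::mutate(res$metrics, scenario = scenario,
                              replicate = r, .before = 1)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write.csv(out[[r]], file.path(out_dir, sprintf(
        "metrics_%s_rep%02d.csv", scenario, r)), row.names = FALSE)
      yaml::write_yaml(
        list(scenario = scenario, replicate = r,
             seed_phase1 = replicate_seed(config$seed, r, 1L),
             seed_phase2 = replicate_seed(config$seed, r, 2L),
             shortfalls = res$log),
        file.path(out_dir, sprintf("log_%s_rep%02d.yaml", scenario, r)))
    }
    if (progress)
      message(sprintf("%s replicate %d/%d done", scenario, r,
                      config$n_replicates))
  }
  structure(dplyr::bind_rows(out), class = c("merino_run", "tbl_df", "tbl",
                                             "data.frame"),
            config = config, scenario = scenario)
}

#' Run the full scenario sweep
#'
#' @inheritParams run_scenario
#' @param scenarios Scenarios to run (default all three).
#' @return A `merino_study` tibble (stacked [run_scenario()] outputs) with
#'   the config attached.
#' @export
run_study <- function(config = study_config(),
                      scenarios = c("ST", "ST_FT", "FT"),
                      out_dir = NULL, progress = FALSE) {
  runs <- lapply(scenarios, function(sc)
    run_scenario(config, sc, out_dir = out_dir, progress = progress))
  structure(dplyr::bind_rows(runs),
            class = c("merino_study", "tbl_df", "tbl", "data.frame"),
            config = config)
}

#' Per-replicate headline statistics of a study
#'
#' For each scenario and replicate: the scaled TMI gain of the breeding ram
#' cohort at the final evaluated cycle, the TMI and field-trait EBV
#' accuracies averaged over the evaluated cycles for the licensing and
#' breeding ram cohorts, and the maximum mean kinship of the breeding
#' population over the evaluated cycles.
#'
#' @param study A `merino_study` (or `merino_run`).
#' @return Tibble `scenario`, `replicate`, `stat`, `value`.
#' @export
replicate_stats <- function(study) {
  config <- attr(study, "config")
  ref <- config$reference_cycle
  traits4 <- field_traits()
  per_rep <- function(df) {
    g <- genetic_gain_trajectory(df, "breeding_rams", "TMI", ref)
    rows <- list(tibble(stat = "gain_TMI_rams_c10",
                        value = g$gain[nrow(g)]))
    acc <- df[df$metric == "accuracy" & df$cycle > ref, ]
    for (coh in c("breeding_rams", "licensing")) {
      for (tr in c("TMI", traits4)) {
        v <- acc$value[acc$cohort == coh & acc$trait == tr]
        rows[[length(rows) + 1L]] <- tibble(
          stat = paste0("acc_", tr, "_", coh),
          value = mean(v, na.rm = TRUE))
      }
    }
    kin <- df$value[df$metric == "kinship"]
    rows[[length(rows) + 1L]] <- tibble(stat = "kinship_max",
                                        value = max(kin))
    dplyr::bind_rows(rows)
  }
  dplyr::reframe(dplyr::group_by(as_tibble(study), .data$scenario,
                                 .data$replicate),
                 per_rep(dplyr::pick(dplyr::everything())))
}

#' Genetic-gain table (per scenario and evaluated cycle)
#'
#' Mean and SD over replicates of the scaled TMI gain of a cohort, cycles
#' relabelled 1..n after the reference.
#'
#' @param study A `merino_study`.
#' @param cohort Reported cohort (default breeding rams).
#' @param trait `"TMI"` or a trait name.
#' @return Tibble `scenario`, `cycle`, `mean_gain`, `sd_gain`.
#' @export
gain_table <- function(study, cohort = "breeding_rams", trait = "TMI") {
  config <- attr(study, "config")
  ref <- config$reference_cycle
  parts <- split(as_tibble(study),
                 list(study$scenario, study$replicate), drop = TRUE)
  per <- dplyr::bind_rows(lapply(parts, function(df)
    dplyr::mutate(genetic_gain_trajectory(df, cohort, trait, ref),
                  scenario = df$scenario[1], replicate = df$replicate[1])))
  out <- dplyr::summarise(
    dplyr::group_by(per, .data$scenario, .data$cycle),
    mean_gain = mean(.data$gain), sd_gain = sd(.data$gain),
    .groups = "drop")
  out[out$cycle > 0, ]
}

#' EBV-accuracy table (per scenario, cohort and trait)
#'
#' Accuracies averaged over the evaluated cycles within each replicate;
#' mean and SD are then taken across replicates.
#'
#' @param study A `merino_study`.
#' @param traits Traits to report (default TMI plus the field fattening
#'   traits).
#' @return Tibble `scenario`, `cohort`, `trait`, `mean_accuracy`, `sd_accuracy`.
#' @export
accuracy_table <- function(study, traits = c("TMI", field_traits())) {
  stats <- replicate_stats(study)
  stats <- stats[grepl("^acc_", stats$stat), ]
  parts <- sub("^acc_", "", stats$stat)
  stats$trait <- sub("_(breeding_rams|licensing)$", "", parts)
  stats$cohort <- sub("^.*_(breeding_rams|licensing)$", "\\1", parts)
  stats <- stats[stats$trait %in% traits, ]
  dplyr::summarise(
    dplyr::group_by(stats, .data$scenario, .data$cohort, .data$trait),
    mean_accuracy = mean(.data$value), sd_accuracy = sd(.data$value),
    .groups = "drop")
}

#' Compare scenarios with paired t tests
#'
#' For each headline statistic ([replicate_stats()]): scenario means and
#' SDs, all pairwise paired t tests (replicates matched by seed),
#' significance letters at `p < alpha` (scenarios sharing a letter do not
#' differ significantly), and the percentage change relative to the
#' reference scenario.
#'
#' @param study A `merino_study` with at least two scenarios.
#' @param reference Reference scenario name (default `"ST"`).
#' @param alpha Significance level (default 0.05).
#' @return A `merino_comparison`: tibble `stat`, `scenario`, `mean`, `sd`,
#'   `letter`, `rel_change_pct`; pairwise tests in `attr(, "tests")`.
#' @export
compare_scenarios <- function(study, reference = "ST", alpha = 0.05) {
  stats <- replicate_stats(study)
  scens <- unique(stats$scenario)
  if (length(scens) < 2) stop("need at least two scenarios", call. = FALSE)
  stopifnot(reference %in% scens)

  tests <- list()
  rows <- list()
  skipped <- character()
  for (st in unique(stats$stat)) {
    s <- stats[stats$stat == st, ]
    wide <- tidyr::pivot_wider(s, names_from = "scenario",
                               values_from = "value")
    if (!all(vapply(scens, function(sc) all(is.finite(wide[[sc]])),
                    logical(1)))) {
      skipped <- c(skipped, st)   # e.g. undefined accuracies (zero-EBV trait)
      next
    }
    p <- matrix(1, length(scens), length(scens),
                dimnames = list(scens, scens))
    for (i in seq_along(scens)) for (j in seq_along(scens)) {
      if (i < j) {
        tt <- paired_t_test(wide[[scens[i]]], wide[[scens[j]]])
        p[i, j] <- p[j, i] <- tt$p
        tests[[length(tests) + 1L]] <- dplyr::mutate(
          tt, stat = st, pair = paste(scens[i], "vs", scens[j]),
          .before = 1)
      }
    }
    m <- vapply(scens, function(sc) mean(wide[[sc]]), numeric(1))
    sdv <- vapply(scens, function(sc) sd(wide[[sc]]), numeric(1))
    letters <- significance_letters(m, p, alpha)
    rows[[length(rows) + 1L]] <- tibble(
      stat = st, scenario = scens, mean = unname(m), sd = unname(sdv),
      letter = unname(letters),
      rel_change_pct = unname(100 * (m - m[reference]) / abs(m[reference])))
  }
  structure(dplyr::bind_rows(rows),
            class = c("merino_comparison", "tbl_df", "tbl", "data.frame"),
            tests = dplyr::bind_rows(tests), alpha = alpha,
            reference = reference, skipped = skipped)
}

# compact-letter display: maximal groups of mutually non-significant
# scenarios, lettered in order of decreasing group best mean
significance_letters <- function(means, pmat, alpha = 0.05) {
  k <- length(means)
  nm <- names(means)
  nonsig <- pmat >= alpha
  diag(nonsig) <- TRUE
  subsets <- list()
  for (size in k:1) {
    for (idx in utils::combn(k, size, simplify = FALSE)) {
      if (all(nonsig[idx, idx])) subsets[[length(subsets) + 1L]] <- idx
    }
  }
  groups <- list()
  for (s in subsets) {
    if (!any(vapply(groups, function(g) all(s %in% g), logical(1))))
      groups[[length(groups) + 1L]] <- s
  }
  best <- vapply(groups, function(g) max(means[g]), numeric(1))
  groups <- groups[order(-best)]
  out <- setNames(rep("", k), nm)
  for (i in seq_along(groups))
    out[groups[[i]]] <- paste0(out[groups[[i]]], letters[i])
  out
}

#' @export
print.merino_comparison <- function(x, ...) {
  NextMethod()
  cat("\nPairwise paired t tests in attr(x, \"tests\")\n")
  invisible(x)
}

#' @rdname run_study
#' @param x A `merino_study`.
#' @param ... Unused.
#' @export
tidy.merino_study <- function(x, ...) as_tibble(x)

#' @rdname run_study
#' @export
glance.merino_study <- function(x, ...) {
  stats <- replicate_stats(x)
  keep <- c("gain_TMI_rams_c10", "acc_TMI_breeding_rams", "kinship_max")
  s <- stats[stats$stat %in% keep, ]
  out <- dplyr::summarise(dplyr::group_by(s, .data$scenario, .data$stat),
                          value = mean(.data$value), .groups = "drop")
  tidyr::pivot_wider(out, names_from = "stat", values_from = "value")
}
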