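#' Read a study configuration from YAML
#'
#' Structured-text configuration for a full study. All keys are optional
#' and fall back to the package defaults; recognised sections are
#' `program` (cohort sizes, litter probabilities, mortality, selection
#' fractions, scale factor, survival schedule), `traits` (named `h2` and
#' `tmi_weights` overrides), `correlations` (`gxe` scalar or `csv` path to
#' a full matrix, optionally `project: true` to PSD-project it),
#' `genome` (`n_chromosomes`, `loci_per_chromosome`, `map_length`) and
#' `study` (`n_cycles`, `reference_cycle`, `n_replicates`, `seed`,
#' `n_qtl`, `burn_in_generations`, `blup_tol`, `st_progeny_per_sire`,
#' `ft_progeny_per_sire`, `na_fraction`, `profile`).
#'
#' @param path YAML file.
#' @return A validated [study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  traits <- merino_traits(h2 = unlist(y$traits$h2),
                          tmi_weights = unlist(y$traits$tmi_weights))

  if (!is.null(y$correlations$csv)) {
    C <- read_correlation_csv(y$correlations$csv)
    C <- C[traits$trait, traits$trait]
    if (isTRUE(y$correlations$project)) C <- project_to_psd(C)
  } else {
    C <- trait_correlations(gxe = y$correlations$gxe %||% 0.8,
                            traits = traits)
  }

  gy <- y$genome %||% list()
  map <- genome_map(n_chromosomes = gy$n_chromosomes %||% 26,
                    loci_per_chromosome = gy$loci_per_chromosome %||% 200,
                    map_length = gy$map_length %||% 1)

  py <- y$program %||% list()
  sched <- if (!is.null(py$survival_schedule))
    as_tibble(do.call(rbind.data.frame, py$survival_schedule))
  else default_survival_schedule()
  prog_args <- py[setdiff(names(py), "survival_schedule")]
  prog_args$litter_probs <- unlist(prog_args$litter_probs) %||%
    c(0.56, 0.40, 0.04)
  program <- do.call(program_config,
                     c(prog_args, list(survival_schedule = sched)))

  sy <- y$study %||% list()
  args <- list(profile = sy$profile %||% "desk", program = program,
               traits = traits, C = C, map = map)
  for (k in c("n_cycles", "reference_cycle", "n_replicates", "seed",
              "n_qtl", "burn_in_generations", "st_progeny_per_sire",
              "ft_progeny_per_sire", "na_fraction", "ft_disjoint",
              "blup_tol"))
    if (!is.null(sy[[k]])) args[[k]] <- sy[[k]]
  do.call(study_config, args)
}

#' Write a study configuration to YAML
#'
#' Serialises the scalar parameters of a [study_config()] (trait table and
#' correlation overrides included); a config written here round-trips
#' through [read_study_config()].
#'
#' @param config A `study_config`.
#' @param path Output YAML file.
#' @export
write_study_config <- function(config, path) {
  p <- config$program
  y <- list(
    study = list(profile = config$profile, n_cycles = config$n_cycles,
                 reference_cycle = config$reference_cycle,
                 n_replicates = config$n_replicates, seed = config$seed,
                 n_qtl = config$n_qtl,
                 burn_in_generations = config$burn_in_generations,
                 st_progeny_per_sire = config$st_progeny_per_sire,
                 ft_progeny_per_sire = config$ft_progeny_per_sire,
                 na_fraction = config$na_fraction,
                 ft_disjoint = isTRUE(config$ft_disjoint),
                 blup_tol = config$blup_tol),
    program = list(n_breeding_rams = p$n_breeding_rams,
                   n_breeding_ewes = p$n_breeding_ewes,
                   litter_probs = as.list(p$litter_probs),
                   lamb_mortality = p$lamb_mortality,
                   male_selected_fraction = p$male_selected_fraction,
                   female_selected_fraction = p$female_selected_fraction,
                   licensing_rejection_fraction =
                     p$licensing_rejection_fraction,
                   scale_factor = p$scale_factor,
                   n_founders = p$n_founders,
                   survival_schedule = lapply(
                     seq_len(nrow(p$survival_schedule)), function(i)
                       as.list(p$survival_schedule[i, ]))),
    traits = list(h2 = as.list(setNames(config$traits$h2,
                                        config$traits$trait)),
                  tmi_weights = as.list(setNames(config$traits$tmi_weight,
                                                 config$traits$trait))),
    correlations = list(gxe = unname(config$C["ADG_F", "ADG_S"])),
    genome = list(
      n_chromosomes = max(config$map$chrom),
      loci_per_chromosome = sum(config$map$chrom == 1),
      map_length = unname(attr(config$map, "chr_len")[1]))
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Export phenotypes as long-format CSV
#'
#' @param phenotypes Tibble `animal`, `trait`, `cycle`, `value` (e.g.
#'   `sim$phenotypes`).
#' @param path Output file.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.csv(phenotypes[c("animal", "trait", "cycle", "value")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Import phenotypes from long-format CSV
#'
#' @param path CSV with columns `animal`, `trait`, `cycle`, `value`.
#' @return Phenotype tibble.
#' @export
read_phenotypes <- function(path) {
  x <- read.csv(path, colClasses = c(animal = "integer",
                                     trait = "character",
                                     cycle = "integer",
                                     value = "numeric"))
  x$trait[is.na(x$trait)] <- "NA"     # nursing ability vs. R missing
  as_tibble(x)
}
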