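test_that("population scaling preserves selected fractions", {
  cfg <- program_config(scale_factor = 0.1)
  expect_equal(cfg$n_rams, 47L)        # ceiling(0.1 * 469)
  expect_equal(cfg$n_ewes, 719L)       # ceiling(0.1 * 7185)
  expect_equal(cfg$male_selected_fraction, 0.02)
  expect_equal(cfg$female_selected_fraction, 0.20)
  expect_error(program_config(litter_probs = c(0.5, 0.4, 0.2)))
  expect_error(program_config(scale_factor = 0))
})

test_that("truncation selection keeps the highest index values", {
  set.seed(41)
  tmi <- rnorm(5000)
  ids <- seq_len(5000)
  sel <- select_top(ids, tmi, 0.02)
  expect_length(sel, 100)
  expect_gte(min(tmi[sel]), max(tmi[-sel]))

  expect_setequal(select_top(ids, tmi, 1), ids)
  expect_error(select_top(ids, c(tmi[-1], NA), 0.02), "missing")

  # all-equal indices: selection is uniform over candidates
  counts <- integer(50)
  for (r in 1:2000) {
    s <- select_top(1:50, rep(0, 50), 0.2)
    counts[s] <- counts[s] + 1
  }
  expected <- 2000 * 10 / 50
  chisq <- sum((counts - expected)^2 / expected)
  expect_lt(chisq, qchisq(0.999, df = 49))
})

test_that("exits follow the age- and sex-specific schedule", {
  sched <- tibble::tibble(sex = rep(c("M", "F"), each = 3),
                          age = rep(1:3, 2),
                          retention = c(1, 0.6, 0, 1, 0.8, 0))
  cohort <- tibble::tibble(id = 1:9000,
                           sex = rep(c("M", "F", "M"), each = 3000),
                           age = rep(1:3, 3000))
  set.seed(42)
  surv <- apply_exits(cohort, sched)
  by_age <- table(cohort$age[cohort$id %in% surv], cohort$sex[cohort$id %in% surv])
  # retention 1 keeps everyone, retention 0 removes everyone
  expect_equal(sum(cohort$age == 1), sum(by_age["1", ]))
  expect_false("3" %in% rownames(by_age)[rowSums(by_age) > 0])
  # binomial expectation at age 2 within 3 SE
  n2m <- sum(cohort$age == 2 & cohort$sex == "M")
  expect_lt(abs(by_age["2", "M"] - 0.6 * n2m), 3 * sqrt(n2m * 0.6 * 0.4))

  expect_error(apply_exits(tibble::tibble(id = 1, sex = "M", age = 9), sched),
               "missing")
})

test_that("mating produces the configured litter and sex distributions", {
  map <- genome_map(2, 50, 1)
  set.seed(43)
  cfg <- program_config(scale_factor = 0.02)
  h <- sim_founder_haplotypes(60, map)
  haplo <- list(mat = unclass(h), ids = 1:60)
  rams <- 1:10; ewes <- 11:60

  tot_born <- 0; tot_lambs <- 0; tot_male <- 0; n_ewes_tot <- 0
  for (r in 1:40) {
    mt <- mate_cohorts(rams, ewes, haplo, map, cfg)
    tot_born <- tot_born + mt$n_born
    tot_lambs <- tot_lambs + nrow(mt$lambs)
    tot_male <- tot_male + sum(mt$lambs$sex == "M")
    n_ewes_tot <- n_ewes_tot + length(ewes)
  }
  # expected lambs born per ewe = 0.56 + 2*0.40 + 3*0.04 = 1.48
  se_born <- sqrt(0.3696 * n_ewes_tot)     # var of litter size = 0.3696
  expect_lt(abs(tot_born - 1.48 * n_ewes_tot), 3 * se_born)
  # surviving lambs per ewe = 1.48 * 0.9 = 1.332
  expect_lt(abs(tot_lambs - 1.332 * n_ewes_tot), 4 * se_born)
  # sex ratio 1:1
  expect_lt(abs(tot_male - tot_lambs / 2), 3 * sqrt(tot_lambs / 4))

  expect_error(mate_cohorts(integer(), ewes, haplo, map, cfg), "empty")

  # gamete alleles are parental: offspring dosage bounded by parents'
  mt <- mate_cohorts(rams, ewes, haplo, map, cfg)
  H <- mt$haplotypes
  pat <- H[, 1]; l <- which(pat == 1)[1]
  sp <- match(mt$lambs$sire[1], haplo$ids)
  expect_true(pat[l] %in% haplo$mat[l, c(2 * sp - 1, 2 * sp)])
})

test_that("a cycle is reproducible and keeps the pedigree consistent", {
  rules <- recording_rules("ST")
  cfg <- program_config(scale_factor = 0.02)
  set.seed(44); sim1 <- new_simulation(cfg)
  set.seed(44); sim2 <- new_simulation(cfg)
  set.seed(45); sim1 <- advance_cycle(sim1, rules)
  set.seed(45); sim2 <- advance_cycle(sim2, rules)
  expect_identical(sim1[setdiff(names(sim1), "last_eval")],
                   sim2[setdiff(names(sim2), "last_eval")])
  expect_identical(sim1$last_eval$tmi, sim2$last_eval$tmi)

  # pedigree time consistency after several cycles
  for (i in 1:3) sim1 <- advance_cycle(sim1, rules)
  ped <- sim_pedigree(sim1)
  has_s <- ped$sire > 0
  expect_true(all(ped$birth_cycle[has_s] > ped$birth_cycle[ped$sire[has_s]]))
  expect_true(all(ped$sex[ped$sire[has_s]] == "M"))
  has_d <- ped$dam > 0
  expect_true(all(ped$sex[ped$dam[has_d]] == "F"))

  # overlapping generations: breeding rams from >= 2 birth cycles
  expect_gte(length(unique(ped$birth_cycle[sim1$rams])), 2)
})

test_that("without selection pressure the genetic trend is flat", {
  cfg <- program_config(scale_factor = 0.02)
  rules <- recording_rules("ST")
  set.seed(46)
  sim <- new_simulation(cfg)
  for (i in 1:10) sim <- advance_cycle(sim, rules, selection = "random")
  m <- sim_metrics(sim)
  mm <- m[m$metric == "mean_tbv" & m$trait == "TMI" &
            m$cohort == "breeding_pop", ]
  sdv <- m$value[m$metric == "sd_tbv" & m$trait == "TMI" &
                   m$cohort == "breeding_pop" & m$cycle == 1]
  drift <- (mm$value[nrow(mm)] - mm$value[1]) / sdv
  # pure drift: change stays a fraction of one genetic SD (selection runs
  # move several SDs over the same horizon)
  expect_lt(abs(drift), 0.75)
})
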