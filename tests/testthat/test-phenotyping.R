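make_crop <- function(n_lambs = 60, n_sires = 3, seed = 51) {
  set.seed(seed)
  traits <- merino_traits()
  tbv <- matrix(rnorm(200 * 19, 100, sqrt(10)), 200,
                dimnames = list(NULL, traits$trait))
  lambs <- tibble::tibble(
    id = 1:n_lambs,
    sex = rep(c("M", "F"), length.out = n_lambs),
    sire = rep(seq(101, by = 1, length.out = n_sires),
               length.out = n_lambs))
  list(lambs = lambs, tbv = tbv, traits = traits)
}

test_that("scenario rules gate which traits ever get records", {
  cr <- make_crop()
  ewes <- 150:170

  st <- record_phenotypes(cr$lambs, ewes, cr$tbv, cr$traits,
                          recording_rules("ST"), cycle = 1)$records
  expect_equal(sum(st$trait %in% c("ADG_F", "FLN_F", "UMD_F", "UFD_F")), 0)
  expect_gt(sum(st$trait == "ADG_S"), 0)

  ft <- record_phenotypes(cr$lambs, ewes, cr$tbv, cr$traits,
                          recording_rules("FT"), cycle = 1)$records
  expect_equal(sum(ft$trait %in% c("ADG_S", "FLN_S", "UMD_S", "UFD_S",
                                   "SW_S", "BMA_S", "WC_S", "SFA_S",
                                   "PKF_S", "FC_S")), 0)
  expect_gt(sum(ft$trait == "ADG_F"), 0)

  # conformation traits on every surviving lamb in all scenarios
  for (rec in list(st, ft)) {
    for (tr in c("WL", "MC", "BC"))
      expect_setequal(rec$animal[rec$trait == tr], cr$lambs$id)
  }
  # NL on every ewe that lambed, once
  expect_setequal(st$animal[st$trait == "NL"], ewes)
  # at most one record per animal-trait pair
  expect_equal(anyDuplicated(st[c("animal", "trait")]), 0)
})

test_that("progeny-test groups are sized per sire; disjoint mode honoured", {
  # one sire with 40 sons, disjoint mode: 8 station + 20 distinct field
  lambs <- tibble::tibble(id = 1:40, sex = "M", sire = 7L)
  tbv <- matrix(100, 50, 19, dimnames = list(NULL, merino_traits()$trait))
  set.seed(52)
  rec <- record_phenotypes(lambs, integer(), tbv, merino_traits(),
                           recording_rules("ST_FT", ft_disjoint = TRUE),
                           cycle = 1)$records
  st_ids <- unique(rec$animal[rec$trait == "ADG_S"])
  ft_ids <- unique(rec$animal[rec$trait == "ADG_F"])
  expect_length(st_ids, 8)
  expect_length(ft_ids, 20)
  expect_length(intersect(st_ids, ft_ids), 0)
  # every station-tested lamb gets the full station trait block
  expect_equal(sum(rec$trait == "FC_S"), 8)

  # default (overlapping) mode: a sire with 10 sons still fields all of
  # them while 8 go to station, so groups overlap
  lambs10 <- tibble::tibble(id = 1:10, sex = "M", sire = 7L)
  rec10 <- record_phenotypes(lambs10, integer(), tbv, merino_traits(),
                             recording_rules("ST_FT"), cycle = 1)$records
  expect_length(unique(rec10$animal[rec10$trait == "ADG_S"]), 8)
  expect_length(unique(rec10$animal[rec10$trait == "ADG_F"]), 10)

  # sires with fewer sons contribute all of them (logged as shortfall)
  lambs2 <- tibble::tibble(id = 1:5, sex = "M", sire = 7L)
  out <- record_phenotypes(lambs2, integer(), tbv, merino_traits(),
                           recording_rules("ST_FT", ft_disjoint = TRUE),
                           cycle = 1)
  expect_equal(sum(out$records$trait == "ADG_S"), 5)
  expect_equal(sum(out$records$trait == "ADG_F"), 0)
  expect_true(all(out$shortfall > 0))
})

test_that("nursing-ability sampling follows na_fraction", {
  cr <- make_crop()
  set.seed(53)
  r0 <- record_phenotypes(cr$lambs, integer(), cr$tbv, cr$traits,
                          recording_rules("ST", na_fraction = 0),
                          cycle = 1)$records
  expect_equal(sum(r0$trait == "NA"), 0)
  r25 <- record_phenotypes(cr$lambs, integer(), cr$tbv, cr$traits,
                           recording_rules("ST", na_fraction = 0.25),
                           cycle = 1)$records
  expect_equal(sum(r25$trait == "NA"), round(0.25 * nrow(cr$lambs)))
})

test_that("NL is recorded at first lambing only", {
  cr <- make_crop()
  ewes <- 150:160
  r1 <- record_phenotypes(cr$lambs, ewes, cr$tbv, cr$traits,
                          recording_rules("ST"), cycle = 1)$records
  expect_setequal(r1$animal[r1$trait == "NL"], ewes)
  r2 <- record_phenotypes(cr$lambs, ewes, cr$tbv, cr$traits,
                          recording_rules("ST"), cycle = 2,
                          nl_recorded = ewes)$records
  expect_equal(sum(r2$trait == "NL"), 0)
})

test_that("phenotypes equal TBV plus trait-variance residuals", {
  cr <- make_crop()
  set.seed(54)
  rec <- record_phenotypes(cr$lambs, integer(), cr$tbv, cr$traits,
                           recording_rules("ST"), cycle = 1)$records
  wl <- rec[rec$trait == "WL", ]
  resid <- wl$value - cr$tbv[wl$animal, "WL"]
  s2 <- residual_variance(cr$traits$h2[cr$traits$trait == "WL"])
  expect_lt(abs(var(resid) / s2 - 1), 0.8)  # 60 records, crude F-bound
})

test_that("fattening records only arise from the birth-cycle progeny test", {
  # in a short run, every station/field record is on a male lamb of the
  # recording cycle - never an own-performance record of an older animal
  cfg <- program_config(scale_factor = 0.02)
  set.seed(55)
  sim <- new_simulation(cfg)
  for (i in 1:3) sim <- advance_cycle(sim, recording_rules("ST_FT"))
  ped <- sim_pedigree(sim)
  fat <- sim$phenotypes[sim$phenotypes$trait %in%
                          c("ADG_F", "FLN_F", "UMD_F", "UFD_F",
                            "ADG_S", "FLN_S", "UMD_S", "UFD_S",
                            "SW_S", "BMA_S", "WC_S", "SFA_S",
                            "PKF_S", "FC_S"), ]
  expect_gt(nrow(fat), 0)
  expect_true(all(ped$birth_cycle[fat$animal] == fat$cycle))
  expect_true(all(ped$sex[fat$animal] == "M"))
})
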