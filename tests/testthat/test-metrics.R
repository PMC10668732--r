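# minimal synthetic study object (metrics already computed) for testing the
# reporting layer without running simulations
make_fake_study <- function(gain_rates = c(ST = 0.36, ST_FT = 0.39, FT = 0.36),
                            acc = c(ST = 0.72, ST_FT = 0.80, FT = 0.72),
                            n_rep = 6, noise = 0.02, seed = 61) {
  set.seed(seed)
  cfg <- list(reference_cycle = 10L)
  rows <- list()
  for (sc in names(gain_rates)) for (r in seq_len(n_rep)) {
    cycles <- 10:20
    base <- 100 + gain_rates[sc] * sqrt(10) * (cycles - 10) +
      rnorm(1, 0, noise)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      scenario = sc, replicate = r, cycle = cycles,
      cohort = "breeding_rams", metric = "mean_tbv", trait = "TMI",
      value = base + rnorm(length(cycles), 0, noise))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      scenario = sc, replicate = r, cycle = 10, cohort = "breeding_pop",
      metric = "sd_tbv", trait = "TMI", value = sqrt(10))
    for (coh in c("breeding_rams", "licensing"))
      for (tr in c("TMI", "ADG_F", "FLN_F", "UMD_F", "UFD_F"))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          scenario = sc, replicate = r, cycle = 11:20, cohort = coh,
          metric = "accuracy", trait = tr,
          value = acc[sc] + rnorm(10, 0, noise))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      scenario = sc, replicate = r, cycle = 10:20, cohort = "breeding_pop",
      metric = "kinship", trait = "ALL",
      value = 0.005 + 0.001 * (0:10))
  }
  structure(dplyr::bind_rows(rows),
            class = c("merino_study", "tbl_df", "tbl", "data.frame"),
            config = cfg)
}

test_that("scaled gain is zero at the reference and in SD units", {
  m <- tibble::tibble(
    cycle = c(10, 11), cohort = "breeding_rams", metric = "mean_tbv",
    trait = "TMI", value = c(100, 101))
  m <- dplyr::bind_rows(m, tibble::tibble(
    cycle = 10, cohort = "breeding_pop", metric = "sd_tbv", trait = "TMI",
    value = sqrt(10)))
  g <- genetic_gain_trajectory(m, reference_cycle = 10)
  expect_equal(g$gain[g$cycle == 0], 0)
  expect_equal(g$gain[g$cycle == 1], 1 / sqrt(10), tolerance = 1e-12)

  # constant TBVs: all-zero trajectory
  m2 <- m; m2$value[m2$metric == "mean_tbv"] <- 100
  expect_true(all(genetic_gain_trajectory(m2, reference_cycle = 10)$gain == 0))

  # zero reference SD is an error
  m3 <- m; m3$value[m3$metric == "sd_tbv"] <- 0
  expect_error(genetic_gain_trajectory(m3, reference_cycle = 10), "SD")
})

test_that("EBV accuracy is the Pearson correlation with guard rails", {
  expect_equal(ebv_accuracy(1:5, 1:5), 1)
  expect_equal(ebv_accuracy(1:5, -(1:5)), -1)
  # frozen value from the hand covariance formula
  expect_equal(ebv_accuracy(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.8)),
               0.9908470002, tolerance = 1e-9)
  expect_true(is.na(ebv_accuracy(rep(1, 4), 1:4)))  # degenerate -> missing
  expect_error(ebv_accuracy(1:2, 1:2), "length")
})

test_that("genetic variance is the unbiased empirical variance", {
  expect_equal(genetic_variance(c(0, 2)), 2)
  expect_equal(unname(genetic_variance(matrix(c(0, 2, 5, 5), 2))), c(2, 0))
})

test_that("paired t test matches hand arithmetic", {
  a <- c(5, 6, 7); b <- a - c(1, 2, 3)   # differences 1, 2, 3
  tt <- paired_t_test(a, b)
  expect_equal(tt$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(tt$df, 2)
  expect_equal(tt$p, 0.0741799002, tolerance = 1e-9)

  t0 <- paired_t_test(a, a)
  expect_equal(t0$t, 0)
  expect_equal(t0$p, 1)

  expect_error(paired_t_test(1, 2), "length")
  expect_error(paired_t_test(c(1, 2), c(0, 1)), "degenerate")
})

test_that("scenario comparison: letters, pairing and relative gain", {
  study <- make_fake_study()
  cmp <- compare_scenarios(study)
  g <- cmp[cmp$stat == "gain_TMI_rams_c10", ]
  lt <- setNames(g$letter, g$scenario)
  # ST and FT share a letter; ST_FT stands alone (a/b/a pattern)
  expect_equal(lt[["ST"]], lt[["FT"]])
  expect_false(lt[["ST_FT"]] == lt[["ST"]])
  # relative gain of ST_FT vs ST in percent
  rel <- g$rel_change_pct[g$scenario == "ST_FT"]
  expect_equal(rel, 100 * (g$mean[g$scenario == "ST_FT"] -
                             g$mean[g$scenario == "ST"]) /
                 g$mean[g$scenario == "ST"])
  expect_gt(rel, 2)

  tests <- attr(cmp, "tests")
  expect_true(all(c("t", "p", "pair") %in% names(tests)))
  pst <- tests$p[tests$stat == "gain_TMI_rams_c10" &
                   grepl("ST vs ST_FT|ST_FT vs ST", tests$pair)]
  expect_lt(pst, 0.05)

  # identical result sets: all p = 1, shared letters
  same <- make_fake_study(gain_rates = c(ST = 0.3, ST_FT = 0.3, FT = 0.3),
                          acc = c(ST = 0.7, ST_FT = 0.7, FT = 0.7),
                          noise = 1e-6, seed = 62)
  # make scenarios byte-identical per replicate
  base <- same[same$scenario == "ST", ]
  for (sc in c("ST_FT", "FT")) {
    same[same$scenario == sc, "value"] <- base$value
  }
  cmp2 <- compare_scenarios(same)
  expect_true(all(attr(cmp2, "tests")$p == 1))
  expect_equal(length(unique(cmp2$letter[cmp2$stat == "gain_TMI_rams_c10"])), 1)
})

test_that("tables aggregate mean and SD across replicates", {
  study <- make_fake_study()
  gt <- gain_table(study)
  expect_setequal(unique(gt$cycle), 1:10)
  expect_true(all(gt$sd_gain >= 0))
  at <- accuracy_table(study)
  expect_setequal(unique(at$trait),
                  c("TMI", "ADG_F", "FLN_F", "UMD_F", "UFD_F"))
  a <- at$mean_accuracy[at$scenario == "ST_FT" & at$cohort == "breeding_rams" &
                          at$trait == "TMI"]
  expect_lt(abs(a - 0.80), 0.05)

  gl <- glance(study)
  expect_equal(nrow(gl), 3)
  expect_true("gain_TMI_rams_c10" %in% names(gl))
})
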