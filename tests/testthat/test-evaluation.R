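test_that("evaluation pedigree keeps recent records and 7 ancestor generations", {
  # chain pedigree: one animal per "cycle", each the child of the previous
  n <- 15
  ped <- tibble::tibble(id = 1:n, sire = c(0L, seq_len(n - 1)),
                        dam = 0L, birth_cycle = 1:n)
  phen <- tibble::tibble(animal = 1:n, trait = "X", cycle = 1:n,
                         value = rnorm(n))
  ev <- build_evaluation_pedigree(ped, phen, current_cycle = n,
                                  record_generations = 3,
                                  pedigree_generations = 7)
  # records only for animals born in the last 3 cycles
  expect_setequal(ev$pedigree$orig_id[ev$records$animal], 13:15)
  # ancestors traced 7 generations up from animal 13 -> id 6 included, 5 not
  expect_true(6 %in% ev$pedigree$orig_id)
  expect_false(5 %in% ev$pedigree$orig_id)
  # truncated parent coded unknown
  expect_equal(ev$pedigree$sire[ev$pedigree$orig_id == 6], 0L)

  # a record from an animal born 4 cycles ago is excluded
  expect_false(11 %in% ev$pedigree$orig_id[ev$records$animal])

  # record_generations = 0: no data, all EBVs zero
  ev0 <- build_evaluation_pedigree(ped, phen, n, record_generations = 0,
                                   extra_animals = n)
  expect_equal(nrow(ev0$records), 0)
  G0 <- matrix(10, 1, 1, dimnames = list("X", "X"))
  f0 <- solve_blup(ev0$records, ev0$pedigree, G0, c(X = 10))
  expect_true(all(f0$ebv == 0))
})

test_that("BLUP reduces to the shrinkage closed form for unrelated animals", {
  set.seed(31)
  n <- 80
  ped <- tibble::tibble(id = 1:n, sire = 0L, dam = 0L)
  y <- rnorm(n, 50, 4)
  G0 <- matrix(10, 1, 1, dimnames = list("X", "X"))
  # h2 = 0.5: EBV_i = 0.5 * (y_i - mean estimate)
  fit <- solve_blup(one_trait_records(1:n, y), ped, G0, c(X = 10),
                    method = "dense")
  expect_equal(as.numeric(fit$ebv),
               0.5 * (y - fit$means), tolerance = 1e-6)

  # residual variance -> 0: EBV -> y - mean
  fit1 <- solve_blup(one_trait_records(1:n, y), ped, G0, c(X = 1e-8),
                     method = "dense")
  expect_equal(as.numeric(fit1$ebv), y - fit1$means, tolerance = 1e-5)
})

test_that("PCG agrees with the dense MME solve on related multi-trait data", {
  set.seed(32)
  ped <- random_pedigree(250, n_founders = 12)[c("id", "sire", "dam")]
  tr <- c("A", "B", "C")
  C <- diag(3); C[1, 2] <- C[2, 1] <- 0.8; C[2, 3] <- C[3, 2] <- 0.3
  dimnames(C) <- list(tr, tr)
  G0 <- 10 * C
  R0 <- c(A = 15, B = 40, C = 25)
  rec <- tibble::tibble(
    animal = c(sample(50:250, 150), sample(100:250, 80)),
    trait = c(rep("A", 150), rep("B", 80)),
    value = rnorm(230, 100, 5))
  rec <- rec[!duplicated(rec[c("animal", "trait")]), ]
  fd <- solve_blup(rec, ped, G0, R0, method = "dense")
  fp <- solve_blup(rec, ped, G0, R0, method = "pcg", tol = 1e-12)
  expect_lt(max(abs(fd$ebv - fp$ebv)), 1e-6)
  expect_lt(max(abs(fd$means - fp$means)), 1e-6)
  expect_true(fp$converged)

  # tidiers
  td <- tidy(fp)
  expect_equal(nrow(td), 250 * 3)
  expect_equal(glance(fp)$method, "pcg")
})

test_that("a diagonal G0 decouples into single-trait solves", {
  set.seed(33)
  ped <- random_pedigree(120, n_founders = 10)[c("id", "sire", "dam")]
  tr <- c("A", "B")
  G0 <- diag(c(10, 10)); dimnames(G0) <- list(tr, tr)
  R0 <- c(A = 30, B = 10)
  recA <- tibble::tibble(animal = 20:100, trait = "A",
                         value = rnorm(81, 10, 3))
  recB <- tibble::tibble(animal = 40:120, trait = "B",
                         value = rnorm(81, -5, 2))
  multi <- solve_blup(dplyr::bind_rows(recA, recB), ped, G0, R0,
                      method = "dense")
  sA <- solve_blup(recA, ped, G0[1, 1, drop = FALSE], R0["A"],
                   method = "dense")
  sB <- solve_blup(recB, ped, G0[2, 2, drop = FALSE], R0["B"],
                   method = "dense")
  expect_lt(max(abs(multi$ebv[, "A"] - sA$ebv[, "A"])), 1e-6)
  expect_lt(max(abs(multi$ebv[, "B"] - sB$ebv[, "B"])), 1e-6)
})

test_that("solver validates its inputs", {
  ped <- tibble::tibble(id = 1:3, sire = c(0L, 0L, 1L), dam = c(0L, 0L, 2L))
  G0 <- matrix(10, 1, 1, dimnames = list("X", "X"))
  expect_error(solve_blup(one_trait_records(1:2, c(1, 2), "Y"), ped, G0,
                          c(X = 10)), "not in G0")
  expect_error(solve_blup(one_trait_records(c(1, 1), c(1, 2)), ped, G0,
                          c(X = 10)), "more than one record")
})

test_that("total merit index applies the routine weights", {
  tr <- merino_traits()$trait
  e0 <- matrix(0, 2, 19, dimnames = list(c("a", "b"), tr))
  expect_equal(unname(total_merit_index(e0)), c(0, 0))
  e1 <- matrix(1, 1, 19, dimnames = list("a", tr))
  expect_equal(unname(total_merit_index(e1)), 100)
  eA <- e0[1, , drop = FALSE]; eA[, "ADG_F"] <- 1
  expect_equal(unname(total_merit_index(eA)), 10)
  # station fattening EBVs do not move the index
  eS <- e0[1, , drop = FALSE]; eS[, c("ADG_S", "FLN_S")] <- 5
  expect_equal(unname(total_merit_index(eS)), 0)
  expect_error(total_merit_index(e1[, 1:5, drop = FALSE]), "missing")
})

test_that("EBV accuracy grows with progeny-group size", {
  # sires evaluated from half-sib progeny records on one trait; more tested
  # progeny means more information per sire
  set.seed(34)
  n_sires <- 40
  h2 <- 0.4
  G0 <- matrix(10, 1, 1, dimnames = list("X", "X"))
  R0 <- c(X = residual_variance(h2))
  acc <- vapply(c(8, 20, 28), function(n_prog) {
    accs <- vapply(1:4, function(rep) {
      tbv_s <- rnorm(n_sires, 0, sqrt(10))
      n <- n_sires + n_sires * n_prog
      ped <- tibble::tibble(
        id = 1:n,
        sire = c(rep(0L, n_sires), rep(1:n_sires, each = n_prog)),
        dam = 0L)
      tbv_o <- 0.5 * tbv_s[ped$sire[-(1:n_sires)]] +
        rnorm(n_sires * n_prog, 0, sqrt(10 * 0.75))
      y <- tbv_o + rnorm(length(tbv_o), 0, sqrt(R0))
      fit <- solve_blup(one_trait_records((n_sires + 1):n, y), ped, G0, R0,
                        method = "pcg", tol = 1e-8)
      cor(tbv_s, fit$ebv[1:n_sires, 1])
    }, numeric(1))
    mean(accs)
  }, numeric(1))
  expect_true(all(diff(acc) > 0))
})

test_that("a correlated recorded trait lifts an unrecorded trait's accuracy", {
  set.seed(35)
  n <- 600
  ped <- tibble::tibble(id = 1:n, sire = 0L, dam = 0L)
  tr <- c("A", "B")
  C <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(tr, tr))
  G0 <- 10 * C
  R0 <- c(A = 20, B = 20)
  tbv <- matrix(rnorm(2 * n), n) %*% chol(G0)
  colnames(tbv) <- tr
  y <- tbv[, "B"] + rnorm(n, 0, sqrt(R0["B"]))
  fit <- solve_blup(one_trait_records(1:n, y, "B"), ped, G0, R0,
                    method = "pcg", tol = 1e-10)
  accA <- cor(tbv[, "A"], fit$ebv[, "A"])
  accB <- cor(tbv[, "B"], fit$ebv[, "B"])
  expect_gt(accA, 0.3)     # strictly positive, information via correlation
  expect_gt(accB, accA)    # but below the recorded trait
})
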