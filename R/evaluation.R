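#' Restrict records and pedigree for one evaluation round
#'
#' Mirrors routine genetic evaluations that keep the data recent and the
#' pedigree shallow: phenotypes are kept only for animals born in the last
#' `record_generations` cycles, and the pedigree is traced ancestor-wise
#' `pedigree_generations` generations up from those animals. Parents outside
#' the traced set are coded unknown.
#'
#' @param pedigree Full pedigree tibble (`id`, `sire`, `dam`, `birth_cycle`,
#'   ids `1..n` chronological).
#' @param phenotypes Long phenotype tibble (`animal`, `trait`, `cycle`,
#'   `value`).
#' @param current_cycle Cycle being evaluated.
#' @param record_generations Record window in cycles (default 3).
#' @param pedigree_generations Ancestor depth (default 7).
#' @param extra_animals Ids that must be in the evaluation (e.g. selection
#'   candidates without records); their ancestors are traced too.
#' @return List: `pedigree` (renumbered tibble with `id`, `sire`, `dam`,
#'   `orig_id`), `records` (tibble `animal` (renumbered), `trait`, `value`),
#'   `id_map` (orig id -> new id named vector).
#' @export
build_evaluation_pedigree <- function(pedigree, phenotypes, current_cycle,
                                      record_generations = 3,
                                      pedigree_generations = 7,
                                      extra_animals = integer()) {
  window <- pedigree$birth_cycle > current_cycle - record_generations
  rec_keep <- phenotypes[window[phenotypes$animal], , drop = FALSE]
  base <- unique(c(rec_keep$animal, extra_animals))

  sire <- pedigree$sire; dam <- pedigree$dam
  in_set <- logical(nrow(pedigree))
  frontier <- base
  in_set[frontier] <- TRUE
  depth <- 0
  while (length(frontier) > 0 && depth < pedigree_generations) {
    par <- unique(c(sire[frontier], dam[frontier]))
    par <- par[par > 0]
    frontier <- par[!in_set[par]]
    in_set[frontier] <- TRUE
    depth <- depth + 1
  }

  keep <- which(in_set)               # ascending = chronological
  id_map <- integer(nrow(pedigree))
  id_map[keep] <- seq_along(keep)
  remap <- function(p) ifelse(p > 0 & in_set[pmax(p, 1)], id_map[pmax(p, 1)], 0L)
  ped <- tibble(
    id = seq_along(keep),
    sire = as.integer(remap(sire[keep])),
    dam = as.integer(remap(dam[keep])),
    orig_id = keep
  )
  records <- tibble(
    animal = id_map[rec_keep$animal],
    trait = rec_keep$trait,
    value = rec_keep$value
  )
  list(pedigree = ped, records = records,
       id_map = setNames(seq_along(keep), keep))
}

#' Multi-trait pedigree BLUP
#'
#' Solves Henderson's mixed-model equations for the animal model with one
#' overall mean per trait as the only fixed effect, animal effects with
#' covariance `A (x) G0`, and diagonal residual covariance `R0` (no residual
#' correlations). Variance components are treated as known. The default
#' solver is preconditioned conjugate gradients with a block-Jacobi
#' (per-animal) preconditioner on the sparse `A^-1`-based equations; small
#' systems are solved directly.
#'
#' @param records Tibble with `animal` (1..n pedigree ids), `trait`
#'   (names matching `rownames(G0)`), `value`. At most one record per
#'   animal-trait pair.
#' @param pedigree Pedigree tibble (`id` = 1..n, `sire`, `dam`).
#' @param G0 Genetic covariance matrix with trait dimnames (for the default
#'   architecture, `10 * C`).
#' @param R0 Named vector of residual variances per trait.
#' @param method `"auto"` (dense if `n_animals * n_traits <= 4000`),
#'   `"pcg"`, or `"dense"`.
#' @param tol Relative-residual convergence tolerance for PCG.
#' @param max_iter PCG iteration cap; non-convergence is a warning carrying
#'   the residual norm.
#' @param F Optional precomputed inbreeding coefficients for the pedigree
#'   (passed to [a_inverse()]).
#' @return A `blup_fit`: `ebv` (animals x traits matrix), `means` (fixed
#'   trait means), `iterations`, `relres`, `converged`, `method`.
#' @export
solve_blup <- function(records, pedigree, G0, R0,
                       method = c("auto", "pcg", "dense"),
                       tol = 1e-8, max_iter = 5000, F = NULL) {
  method <- match.arg(method)
  n <- nrow(pedigree)
  traits <- rownames(G0)
  T <- length(traits)
  stopifnot(!is.null(traits), identical(colnames(G0), traits),
            all(traits %in% names(R0)))
  if (nrow(records) > 0) {
    stopifnot(all(records$animal >= 1), all(records$animal <= n))
    if (!all(records$trait %in% traits))
      stop("record trait not in G0", call. = FALSE)
    if (anyDuplicated(paste(records$animal, records$trait)))
      stop("more than one record per animal-trait pair", call. = FALSE)
  }
  if (method == "auto") method <- if (n * T <= 4000) "dense" else "pcg"

  G0i <- tryCatch(solve(G0), error = function(e) solve(G0 + diag(1e-8, T)))
  Ainv <- a_inverse(pedigree, F = F)
  rec_t <- match(records$trait, traits)
  rec_w <- 1 / unname(R0[traits])[rec_t]

  if (method == "pcg") {
    Ag <- as(as(Ainv, "generalMatrix"), "CsparseMatrix")
    fit <- cpp_blup_pcg(Ag, G0i,
                        as.integer(records$animal), as.integer(rec_t),
                        as.numeric(rec_w), as.numeric(records$value),
                        tol, as.integer(max_iter))
    if (!fit$converged)
      warning(sprintf("PCG not converged in %d iterations (relres %.2e)",
                      max_iter, fit$relres))
    ebv <- t(fit$u)
  } else {
    fit <- blup_dense(records, Ainv, G0i, rec_t, rec_w, n, T)
    ebv <- fit$ebv
  }
  dimnames(ebv) <- list(pedigree$id, traits)
  structure(list(ebv = ebv, means = setNames(as.numeric(fit$beta), traits),
                 iterations = fit$iterations %||% NA_integer_,
                 relres = fit$relres %||% 0,
                 converged = fit$converged %||% TRUE, method = method),
            class = "blup_fit")
}

# direct dense solve of the same MME; also the small-system reference
blup_dense <- function(records, Ainv, G0i, rec_t, rec_w, n, T) {
  K <- kronecker(as.matrix(Ainv), G0i)      # animal-major blocks of T
  p <- T + n * T
  C <- matrix(0, p, p)
  C[(T + 1):p, (T + 1):p] <- K
  rhs <- numeric(p)
  if (nrow(records) > 0) {
    for (r in seq_len(nrow(records))) {
      t <- rec_t[r]; i <- records$animal[r]; w <- rec_w[r]
      y <- records$value[r]
      ui <- T + (i - 1) * T + t
      C[t, t] <- C[t, t] + w
      C[ui, ui] <- C[ui, ui] + w
      C[t, ui] <- C[t, ui] + w
      C[ui, t] <- C[ui, t] + w
      rhs[t] <- rhs[t] + w * y
      rhs[ui] <- rhs[ui] + w * y
    }
  }
  # traits without records leave a zero row in the fixed block
  empty <- which(diag(C)[seq_len(T)] == 0)
  for (t in empty) C[t, t] <- 1
  sol <- solve(C, rhs)
  list(beta = sol[seq_len(T)],
       ebv = matrix(sol[-seq_len(T)], n, T, byrow = TRUE),
       iterations = NA_integer_, relres = 0, converged = TRUE)
}

#' @export
print.blup_fit <- function(x, ...) {
  cat("<blup_fit> ", nrow(x$ebv), " animals x ", ncol(x$ebv),
      " traits (", x$method,
      if (x$method == "pcg") sprintf(", %d iterations, relres %.1e",
                                     x$iterations, x$relres) else "",
      ")\n", sep = "")
  invisible(x)
}

#' @rdname solve_blup
#' @param x A `blup_fit`.
#' @param ... Unused.
#' @export
tidy.blup_fit <- function(x, ...) {
  tibble(
    animal = rep(as.integer(rownames(x$ebv)), ncol(x$ebv)),
    trait = rep(colnames(x$ebv), each = nrow(x$ebv)),
    ebv = as.numeric(x$ebv)
  )
}

#' @rdname solve_blup
#' @export
glance.blup_fit <- function(x, ...) {
  tibble(n_animals = nrow(x$ebv), n_traits = ncol(x$ebv),
         method = x$method, iterations = x$iterations,
         relres = x$relres, converged = x$converged)
}

#' Total merit index
#'
#' Weighted sum of per-trait (estimated or true) breeding values with the
#' routine-evaluation index weights. Traits with zero weight (the station
#' fattening traits) contribute nothing to the index but still sharpen the
#' evaluation of their weighted field counterparts.
#'
#' @param bv Matrix animals x traits with trait colnames (EBVs or TBVs), or
#'   a `blup_fit`.
#' @param weights Named weight vector; defaults to [merino_tmi_weights()].
#' @return Named numeric vector of index values per animal.
#' @export
#' @examples
#' ebv <- matrix(1, 1, 19, dimnames = list("a", merino_traits()$trait))
#' total_merit_index(ebv) # 100
total_merit_index <- function(bv, weights = merino_tmi_weights()) {
  if (inherits(bv, "blup_fit")) bv <- bv$ebv
  w <- weights[weights != 0]
  if (!all(names(w) %in% colnames(bv)))
    stop("missing breeding value for weighted trait(s): ",
         paste(setdiff(names(w), colnames(bv)), collapse = ", "),
         call. = FALSE)
  drop(bv[, names(w), drop = FALSE] %*% w)
}
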