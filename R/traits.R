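#' Trait panel of the simulated Merino breeding goal
#'
#' Returns the 19-trait panel used throughout the simulator: reproduction and
#' rearing traits (number of lambs born `NL`, nursing ability `NA`),
#' conformation traits scored at licensing/herdbook registration (`WL`, `MC`,
#' `BC`), fattening traits recordable in field (`_F`) and station (`_S`)
#' progeny testing, station-only carcass traits, and feed conversion (`FC_S`).
#' Heritabilities are the routine-evaluation values for German Merino; the
#' total-merit-index (TMI) weights sum to 100, with the station fattening
#' traits (`ADG_S` ... `UFD_S`) carrying zero weight — they enter the
#' evaluation only to support their field counterparts through the genetic
#' correlation.
#'
#' @param h2 Optional named numeric vector overriding heritabilities.
#' @param tmi_weights Optional named numeric vector overriding TMI weights.
#' @return A tibble with columns `trait`, `h2`, `timepoint`, `tmi_weight`,
#'   and `group`.
#' @export
#' @examples
#' merino_traits()
merino_traits <- function(h2 = NULL, tmi_weights = NULL) {
  tr <- tibble(
    trait = c("NL", "NA", "WL", "MC", "BC",
              "ADG_F", "FLN_F", "UMD_F", "UFD_F",
              "ADG_S", "FLN_S", "UMD_S", "UFD_S",
              "SW_S", "BMA_S", "WC_S", "SFA_S", "PKF_S", "FC_S"),
    h2 = c(0.10, 0.25, 0.20, 0.25, 0.30,
           0.26, 0.13, 0.22, 0.17,
           0.40, 0.50, 0.26, 0.20,
           0.33, 0.36, 0.14, 0.12, 0.19, 0.40),
    timepoint = c("lambing", "day42", rep("licensing_registration", 3),
                  rep("FT", 4), rep("ST", 10)),
    tmi_weight = c(10, 5, 7.5, 7.5, 20,
                   10, 2.5, 2.5, 3.125,
                   0, 0, 0, 0,
                   2.5, 2.5, 2.5, 6.25, 3.125, 15),
    group = c(rep("reproduction", 2), rep("conformation", 3),
              rep("fattening_field", 4), rep("fattening_station", 4),
              rep("carcass", 5), "efficiency")
  )
  if (!is.null(h2)) {
    stopifnot(all(names(h2) %in% tr$trait))
    tr$h2[match(names(h2), tr$trait)] <- unname(h2)
  }
  if (!is.null(tmi_weights)) {
    stopifnot(all(names(tmi_weights) %in% tr$trait))
    tr$tmi_weight[match(names(tmi_weights), tr$trait)] <- unname(tmi_weights)
  }
  stopifnot(all(tr$h2 > 0), all(tr$h2 <= 1))
  tr
}

#' TMI weights as a named vector
#'
#' The total merit index is `TMI = 10 NL + 7.5 WL + 7.5 MC + 20 BC + 5 NA +
#' 10 ADG_F + 2.5 FLN_F + 2.5 UMD_F + 3.125 UFD_F + 15 FC_S + 2.5 SW_S +
#' 2.5 BMA_S + 2.5 WC_S + 6.25 SFA_S + 3.125 PKF_S` (weights sum to 100).
#'
#' @param traits Trait table from [merino_traits()].
#' @return Named numeric vector of length 19 (zero for unweighted traits).
#' @export
merino_tmi_weights <- function(traits = merino_traits()) {
  setNames(traits$tmi_weight, traits$trait)
}

#' Genetic correlation matrix of the trait panel
#'
#' Builds the default 19 x 19 genetic correlation matrix: identity except for
#' the genotype-by-environment pairs, where the same fattening trait measured
#' on pasture (`_F`) and on station (`_S`) is given correlation `gxe`
#' (default 0.8, the level at which re-ranking across environments becomes a
#' practical concern). A full custom matrix can be supplied instead, e.g. one
#' read with [read_correlation_csv()].
#'
#' @param gxe Genetic correlation between field and station versions of ADG,
#'   FLN, UMD and UFD.
#' @param traits Trait table from [merino_traits()].
#' @param custom Optional full correlation matrix (with trait dimnames) that
#'   replaces the default; it is validated and returned as-is (project it with
#'   [project_to_psd()] if it is not positive semidefinite).
#' @return A symmetric unit-diagonal matrix with trait dimnames.
#' @export
trait_correlations <- function(gxe = 0.8, traits = merino_traits(),
                               custom = NULL) {
  nm <- traits$trait
  if (!is.null(custom)) {
    stopifnot(is.matrix(custom), nrow(custom) == ncol(custom))
    stopifnot(setequal(rownames(custom), nm))
    custom <- custom[nm, nm]
    check_correlation_matrix(custom)
    return(custom)
  }
  stopifnot(gxe >= -1, gxe <= 1)
  C <- diag(length(nm))
  dimnames(C) <- list(nm, nm)
  for (b in c("ADG", "FLN", "UMD", "UFD")) {
    f <- paste0(b, "_F"); s <- paste0(b, "_S")
    C[f, s] <- C[s, f] <- gxe
  }
  C
}

#' Evaluation parameter matrix for the genetic evaluation
#'
#' Routine genetic evaluations parameterize traits recorded in one
#' environment; a trait's field and station expressions are scored as
#' separate traits without an established cross-environment correlation.
#' This helper derives the BLUP parameter matrix from the simulation's true
#' correlation matrix by zeroing every correlation between the `_F` and
#' `_S` versions of the same base trait, so the evaluation cannot transfer
#' information across environments even though the simulated genetics do
#' (the source of the realized G x E penalty). Supply your own matrix to
#' model an evaluation with (partial) cross-environment knowledge.
#'
#' @param C True (simulation) correlation matrix with trait dimnames.
#' @return Correlation matrix of the same shape with cross-environment
#'   entries set to zero.
#' @export
evaluation_correlations <- function(C) {
  nm <- rownames(C)
  base_f <- sub("_F$", "", nm[grepl("_F$", nm)])
  for (b in base_f) {
    f <- paste0(b, "_F"); s <- paste0(b, "_S")
    if (f %in% nm && s %in% nm) C[f, s] <- C[s, f] <- 0
  }
  C
}

check_correlation_matrix <- function(C, tol = 1e-8) {
  if (!isSymmetric(unname(C), tol = tol))
    stop("correlation matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(C) - 1) > tol))
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  invisible(C)
}

#' Read a trait correlation matrix from CSV
#'
#' Expects a square CSV with a header row and a first column both holding
#' trait names.
#'
#' @param path CSV file path.
#' @return Correlation matrix with dimnames.
#' @export
read_correlation_csv <- function(path) {
  # na.strings emptied so the trait named "NA" survives the round trip
  x <- read.csv(path, check.names = FALSE, na.strings = character(0))
  rn <- as.character(x[[1]])
  C <- as.matrix(x[-1])
  rownames(C) <- rn
  storage.mode(C) <- "double"
  check_correlation_matrix(C)
  C
}

#' Project a correlation matrix onto the positive semidefinite cone
#'
#' Eigendecomposes, clips negative eigenvalues to zero, reconstructs, and
#' rescales to unit diagonal. Literature-compiled correlation matrices are
#' frequently indefinite; this projection makes them usable as a simulation
#' covariance. Idempotent within numerical tolerance.
#'
#' @param C Symmetric matrix with unit diagonal.
#' @return Positive semidefinite correlation matrix (min eigenvalue
#'   `>= -1e-10`).
#' @export
#' @examples
#' C <- matrix(c(1, .9, -.9, .9, 1, .9, -.9, .9, 1), 3, 3)
#' min(eigen(project_to_psd(C))$values) >= -1e-10
project_to_psd <- function(C) {
  check_correlation_matrix(C, tol = 1e-6)
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  if (min(e$values) >= 0) return(C)
  ev <- pmax(e$values, 0)
  M <- e$vectors %*% (ev * t(e$vectors))
  d <- sqrt(diag(M))
  out <- M / tcrossprod(d)
  diag(out) <- 1
  dimnames(out) <- dimnames(C)
  out
}

#' Residual variance implied by a heritability
#'
#' With the genetic variance standardized to `sigma2_g` (default 10), a trait
#' with heritability `h2` carries residual variance
#' `sigma2_g * (1 - h2) / h2`.
#'
#' @param h2 Heritability in (0, 1].
#' @param sigma2_g Genetic variance on the standardized scale.
#' @return Residual variance(s).
#' @export
#' @examples
#' residual_variance(0.4) # 15
residual_variance <- function(h2, sigma2_g = 10) {
  if (any(h2 <= 0) || any(h2 > 1)) stop("h2 must lie in (0, 1]", call. = FALSE)
  sigma2_g * (1 - h2) / h2
}

#' Build a pleiotropic QTL architecture
#'
#' Samples `n_qtl` loci uniformly without replacement from the panel and draws
#' for each locus one allele-substitution effect per trait from a multivariate
#' Gaussian with correlation `C`, so that pleiotropy induces the target
#' genetic correlations under linkage equilibrium. Per-trait standardizers
#' (multiplicative `scale` and additive `shift`) are then fixed so that the
#' supplied cohort has true-breeding-value mean `target_mean` (100) and
#' variance `target_var` (10) on every trait; they are frozen thereafter so
#' genetic trend and variance stay on one scale.
#'
#' @param haplotypes A `haplo_set` for the standardization cohort (two
#'   columns per individual).
#' @param traits Trait table from [merino_traits()].
#' @param C Positive semidefinite genetic correlation matrix.
#' @param n_qtl Number of QTL (default 1000).
#' @param target_mean,target_var Standardization targets.
#' @return A `genetic_architecture` object: `qtl` (locus indices), `effects`
#'   (`n_qtl` x traits raw effects), `scale`, `shift`, `traits`.
#' @export
build_architecture <- function(haplotypes, traits = merino_traits(),
                               C = trait_correlations(), n_qtl = 1000,
                               target_mean = 100, target_var = 10) {
  H <- unclass(haplotypes)
  L <- nrow(H)
  if (n_qtl > L) stop("n_qtl exceeds the number of panel loci", call. = FALSE)
  nm <- traits$trait
  stopifnot(identical(rownames(C), nm))
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8)
    stop("C must be positive semidefinite; apply project_to_psd() first",
         call. = FALSE)
  sq <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  qtl <- sort(sample.int(L, n_qtl))
  effects <- matrix(rnorm(n_qtl * length(nm)), n_qtl) %*% sq
  colnames(effects) <- nm

  arch <- structure(
    list(qtl = qtl, effects = effects,
         scale = setNames(rep(1, length(nm)), nm),
         shift = setNames(rep(0, length(nm)), nm),
         traits = traits),
    class = "genetic_architecture")
  raw <- true_breeding_values(haplotypes, arch)
  v <- apply(raw, 2, var)
  if (any(v < 1e-12))
    stop("degenerate zero founder variance for trait(s): ",
         paste(nm[v < 1e-12], collapse = ", "), call. = FALSE)
  arch$scale <- sqrt(target_var / v)
  arch$shift <- target_mean - arch$scale * colMeans(raw)
  arch
}

#' @export
print.genetic_architecture <- function(x, ...) {
  cat("<genetic_architecture> ", length(x$qtl), " QTL x ",
      ncol(x$effects), " traits\n", sep = "")
  invisible(x)
}

#' True breeding values from haplotypes
#'
#' `TBV_t(i) = scale_t * sum_q x_iq e_qt + shift_t`, with `x_iq` in {0,1,2}
#' the QTL allele dosage (purely additive gene action).
#'
#' @param haplotypes A `haplo_set` (two columns per individual) or a dosage
#'   matrix (individuals x loci, entries 0/1/2) covering all panel loci.
#' @param architecture A `genetic_architecture`.
#' @return Matrix individuals x traits of true breeding values.
#' @export
true_breeding_values <- function(haplotypes, architecture) {
  if (inherits(haplotypes, "haplo_set")) {
    H <- unclass(haplotypes)
    odd <- seq(1, ncol(H), by = 2)
    X <- H[architecture$qtl, odd, drop = FALSE] +
      H[architecture$qtl, odd + 1, drop = FALSE]
    if (anyNA(X)) stop("missing genotypes", call. = FALSE)
    raw <- crossprod(X, architecture$effects)
  } else {
    X <- haplotypes[, architecture$qtl, drop = FALSE]
    if (anyNA(X)) stop("missing genotypes", call. = FALSE)
    raw <- X %*% architecture$effects
  }
  sweep(sweep(raw, 2, architecture$scale, `*`), 2, architecture$shift, `+`)
}

#' Draw phenotypes from true breeding values
#'
#' `phenotype = TBV + e`, `e ~ N(0, sigma2_g (1 - h2) / h2)`, residuals
#' independent across traits and animals (no residual covariance, no
#' permanent-environment effect).
#'
#' @param tbv Numeric vector (one trait) or matrix (columns named by trait).
#' @param h2 Heritability (scalar for a vector `tbv`, or a named vector
#'   covering the columns of a matrix `tbv`).
#' @param sigma2_g Genetic variance on the standardized scale.
#' @return Phenotypes with the shape of `tbv`.
#' @export
draw_phenotypes <- function(tbv, h2, sigma2_g = 10) {
  if (is.matrix(tbv)) {
    stopifnot(!is.null(colnames(tbv)), all(colnames(tbv) %in% names(h2)))
    sdv <- sqrt(residual_variance(h2[colnames(tbv)], sigma2_g))
    tbv + matrix(rnorm(length(tbv)), nrow(tbv)) %*% diag(sdv, ncol(tbv))
  } else {
    tbv + rnorm(length(tbv), sd = sqrt(residual_variance(h2, sigma2_g)))
  }
}
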