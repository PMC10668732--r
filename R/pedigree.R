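#' Pedigree inbreeding coefficients
#'
#' Meuwissen-Luo tabular recursion over a chronologically sorted pedigree.
#'
#' @param pedigree Tibble/data frame with integer columns `id` (must be
#'   `1..n` in order), `sire`, `dam` (0 = unknown; parents precede
#'   offspring).
#' @return Numeric vector of inbreeding coefficients F.
#' @export
inbreeding_coefficients <- function(pedigree) {
  check_pedigree(pedigree)
  cpp_inbreeding_ml(as.integer(pedigree$sire), as.integer(pedigree$dam),
                    numeric(0), numeric(0))$F
}

check_pedigree <- function(pedigree) {
  n <- nrow(pedigree)
  if (!identical(as.integer(pedigree$id), seq_len(n)))
    stop("pedigree ids must be 1..n in chronological order", call. = FALSE)
  s <- pedigree$sire; d <- pedigree$dam
  if (any(s < 0) || any(d < 0) || any(s > n) || any(d > n))
    stop("parent id outside pedigree (use 0 for unknown)", call. = FALSE)
  bad <- s >= pedigree$id & s > 0 | d >= pedigree$id & d > 0
  if (any(bad))
    stop("parents must precede offspring (pedigree not sorted or cyclic)",
         call. = FALSE)
  invisible(pedigree)
}

# Mendelian-sampling variances d_i given parents and inbreeding
mendelian_variances <- function(sire, dam, F) {
  Fs <- ifelse(sire > 0, F[pmax(sire, 1)], 0)
  Fd <- ifelse(dam > 0, F[pmax(dam, 1)], 0)
  both <- sire > 0 & dam > 0
  one <- xor(sire > 0, dam > 0)
  d <- rep(1, length(sire))
  d[both] <- 0.5 - 0.25 * (Fs[both] + Fd[both])
  d[one] <- 0.75 - 0.25 * (Fs[one] + Fd[one])
  d
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with Mendelian-sampling variances from inbreeding
#' coefficients (Meuwissen-Luo recursion), so inbreeding is fully accounted
#' for. The result is the sparse symmetric `A^-1` used in the animal-model
#' mixed-model equations.
#'
#' @inheritParams inbreeding_coefficients
#' @param F Optional precomputed inbreeding coefficients (e.g. cached from a
#'   deeper pedigree than the one evaluated); computed by the Meuwissen-Luo
#'   recursion when omitted.
#' @return A sparse symmetric matrix (`Matrix::dsCMatrix`) of dimension
#'   `n x n`.
#' @export
#' @examples
#' trio <- tibble::tibble(id = 1:3, sire = c(0L, 0L, 1L), dam = c(0L, 0L, 2L))
#' as.matrix(a_inverse(trio)) # [[1.5,.5,-1],[.5,1.5,-1],[-1,-1,2]]
a_inverse <- function(pedigree, F = NULL) {
  check_pedigree(pedigree)
  n <- nrow(pedigree)
  s <- as.integer(pedigree$sire); d <- as.integer(pedigree$dam)
  if (is.null(F)) F <- cpp_inbreeding_ml(s, d, numeric(0), numeric(0))$F
  stopifnot(length(F) == n)
  alpha <- 1 / mendelian_variances(s, d, F)
  i <- seq_len(n)

  ii <- c(i, i[s > 0], i[d > 0], s[s > 0], d[d > 0], pmax(s, d)[s > 0 & d > 0])
  jj <- c(i, s[s > 0], d[d > 0], s[s > 0], d[d > 0], pmin(s, d)[s > 0 & d > 0])
  xx <- c(alpha,
          -alpha[s > 0] / 2, -alpha[d > 0] / 2,
          alpha[s > 0] / 4, alpha[d > 0] / 4,
          alpha[s > 0 & d > 0] / 4)
  # keep lower triangle for a symmetric sparse build
  lo <- pmax(ii, jj); hi <- pmin(ii, jj)
  Matrix::sparseMatrix(i = lo, j = hi, x = xx, dims = c(n, n),
                       symmetric = TRUE)
}

# A %*% v without forming A, via A = T D T' with T = (I - P)^-1
# (P carries 1/2 at parent columns). Used for cohort kinship summaries.
relationship_times <- function(pedigree, v, F = NULL) {
  check_pedigree(pedigree)
  n <- nrow(pedigree)
  s <- pedigree$sire; d <- pedigree$dam
  if (is.null(F)) F <- cpp_inbreeding_ml(as.integer(s), as.integer(d),
                                         numeric(0), numeric(0))$F
  D <- mendelian_variances(s, d, F)
  keep_s <- s > 0; keep_d <- d > 0
  IP <- Matrix::sparseMatrix(
    i = c(seq_len(n), which(keep_s), which(keep_d)),
    j = c(seq_len(n), s[keep_s], d[keep_d]),
    x = c(rep(1, n), rep(-0.5, sum(keep_s)), rep(-0.5, sum(keep_d))),
    dims = c(n, n), triangular = TRUE)
  x <- Matrix::solve(Matrix::t(IP), v)
  Matrix::solve(IP, D * as.numeric(x))
}

#' Mean pairwise kinship within a cohort
#'
#' Average tabular kinship (`A_ij / 2`) over distinct pairs of cohort
#' members, self-pairs excluded; founders of the supplied pedigree are the
#' zero-kinship base. Computed without forming the dense relationship matrix
#' (one pair of sparse triangular solves), so whole-run pedigrees are cheap.
#'
#' @inheritParams inbreeding_coefficients
#' @param cohort Integer ids (rows of `pedigree`) of the cohort (size >= 2).
#' @param F Optional precomputed inbreeding coefficients for the pedigree.
#' @return Mean kinship (scalar).
#' @export
mean_kinship <- function(pedigree, cohort, F = NULL) {
  if (length(cohort) < 2) stop("cohort must have at least 2 animals",
                               call. = FALSE)
  n <- nrow(pedigree)
  stopifnot(all(cohort >= 1), all(cohort <= n))
  if (is.null(F))
    F <- cpp_inbreeding_ml(as.integer(pedigree$sire),
                           as.integer(pedigree$dam),
                           numeric(0), numeric(0))$F
  v <- numeric(n); v[cohort] <- 1
  Av <- as.numeric(relationship_times(pedigree, v, F))
  total <- sum(Av[cohort])              # 1' A_cohort 1
  self <- sum(1 + F[cohort])            # diagonal terms
  m <- length(cohort)
  (total - self) / (m * (m - 1)) / 2
}

#' Export a pedigree as CSV
#'
#' Writes `id, sire, dam, sex, birth_cycle` (columns present in the input)
#' as a plain CSV.
#'
#' @param pedigree Pedigree tibble.
#' @param path Output file.
#' @export
write_pedigree <- function(pedigree, path) {
  keep <- intersect(c("id", "sire", "dam", "sex", "birth_cycle"),
                    names(pedigree))
  write.csv(pedigree[keep], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
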