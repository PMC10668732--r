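#' Genome map for the synthetic SNP panel
#'
#' Defines the chromosome structure the simulator works on. The default —
#' 26 autosomes of 1 Morgan with 200 evenly spaced loci each (5,200 loci) —
#' is a desk-scale stand-in for a 50k ovine SNP chip; a full-density map is
#' just a parameter change. Locus positions are genetic positions in Morgan
#' within their chromosome and must be strictly increasing.
#'
#' @param n_chromosomes Number of autosomes.
#' @param loci_per_chromosome Loci per chromosome (at least 2).
#' @param map_length Map length per chromosome in Morgan (scalar or vector).
#' @param positions Optional list (one numeric vector per chromosome) of
#'   locus positions; defaults to an even grid.
#' @return A `genome_map`: tibble with columns `chrom`, `locus`, `pos`, and
#'   attribute `chr_len`.
#' @export
#' @examples
#' map <- genome_map()
#' nrow(map) # 5200
genome_map <- function(n_chromosomes = 26, loci_per_chromosome = 200,
                       map_length = 1, positions = NULL) {
  stopifnot(n_chromosomes >= 1, loci_per_chromosome >= 2)
  len <- rep_len(map_length, n_chromosomes)
  stopifnot(all(len > 0))
  if (is.null(positions)) {
    positions <- lapply(seq_len(n_chromosomes), function(c)
      len[c] * (seq_len(loci_per_chromosome) - 0.5) / loci_per_chromosome)
  }
  stopifnot(length(positions) == n_chromosomes)
  for (c in seq_len(n_chromosomes)) {
    p <- positions[[c]]
    if (length(p) < 2 || any(diff(p) <= 0) || any(p < 0) || any(p > len[c]))
      stop("locus positions must be strictly increasing within [0, map_length]",
           call. = FALSE)
  }
  out <- tibble(
    chrom = rep(seq_len(n_chromosomes), lengths(positions)),
    locus = seq_len(sum(lengths(positions))),
    pos = unlist(positions)
  )
  attr(out, "chr_len") <- len
  class(out) <- c("genome_map", class(out))
  out
}

# chromosome bounds and positions in the layout cpp_make_gametes expects
map_index <- function(map) {
  chr <- map$chrom
  list(
    pos = map$pos,
    chr_start = as.integer(tapply(map$locus, chr, min)),
    chr_end = as.integer(tapply(map$locus, chr, max)),
    chr_len = attr(map, "chr_len"),
    n_loci = nrow(map)
  )
}

#' Simulate founder haplotypes in linkage equilibrium
#'
#' Draws one allele frequency per locus uniformly in `[maf_low, maf_high]`
#' and samples haplotype alleles independently per locus — linkage
#' equilibrium by construction; relatedness and LD are built afterwards by
#' random mating ([burn_in_random_mating()]). A synthetic stand-in for real
#' chip genotypes.
#'
#' @param n_individuals Number of diploid founders (>= 2).
#' @param map A [genome_map()].
#' @param maf_low,maf_high Allele-frequency bounds, `0 < maf_low <= maf_high
#'   <= 0.5`.
#' @return A `haplo_set`: integer matrix with one row per locus and two
#'   columns per individual (columns `2i-1`, `2i`).
#' @export
sim_founder_haplotypes <- function(n_individuals, map = genome_map(),
                                   maf_low = 0.05, maf_high = 0.5) {
  if (n_individuals < 2) stop("need at least 2 founders", call. = FALSE)
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5))
    stop("need 0 < maf_low <= maf_high <= 0.5", call. = FALSE)
  L <- nrow(map)
  freq <- runif(L, maf_low, maf_high)
  # prob recycles down the columns: every haplotype gets the same per-locus
  # frequencies
  H <- matrix(rbinom(2 * n_individuals * L, 1L, freq), nrow = L)
  new_haplo_set(H)
}

new_haplo_set <- function(H) {
  storage.mode(H) <- "integer"
  structure(H, class = "haplo_set")
}

#' @export
print.haplo_set <- function(x, ...) {
  cat("<haplo_set> ", ncol(x) / 2, " individuals x ", nrow(x), " loci\n",
      sep = "")
  invisible(x)
}

n_individuals <- function(haplotypes) ncol(haplotypes) / 2

#' Generate gametes by meiosis
#'
#' Recombination follows the Haldane model: per chromosome the crossover
#' count is Poisson(map length in Morgan) with uniform crossover positions
#' and no interference; the starting parental haplotype is chosen with
#' probability 1/2. Every transmitted allele is one of the two parental
#' alleles at that locus.
#'
#' @param haplotypes A `haplo_set`.
#' @param parents Integer vector of parent indices (one gamete per entry;
#'   repeat an index for several gametes).
#' @param map The [genome_map()] the haplotypes live on.
#' @return Integer matrix, one gamete per column (loci in rows).
#' @export
make_gametes <- function(haplotypes, parents, map = genome_map()) {
  H <- unclass(haplotypes)
  stopifnot(all(parents >= 1), all(parents <= ncol(H) / 2))
  mi <- map_index(map)
  stopifnot(mi$n_loci == nrow(H))
  cpp_make_gametes(H, as.integer(2 * parents - 1), as.integer(2 * parents),
                   mi$pos, mi$chr_start, mi$chr_end, mi$chr_len)
}

# gametes for a cohort where parents are addressed by column pairs in a pool
gametes_from_cols <- function(H, hap_col1, hap_col2, map) {
  mi <- map_index(map)
  cpp_make_gametes(H, as.integer(hap_col1), as.integer(hap_col2),
                   mi$pos, mi$chr_start, mi$chr_end, mi$chr_len)
}

#' Random mating burn-in
#'
#' Mates the founders randomly for `n_generations` discrete generations to
#' build up relatedness, linkage disequilibrium, and a pedigree before the
#' breeding program starts. Each offspring draws its sire uniformly from the
#' previous generation's males and its dam from its females. The final
#' generation can be given exact sex counts so it can seed the initial
#' breeding cohorts.
#'
#' @param founders A `haplo_set` of founders.
#' @param map The [genome_map()].
#' @param n_generations Number of burn-in generations (>= 0; default 5).
#' @param offspring_per_generation Offspring per generation (default: founder
#'   count).
#' @param founder_sexes Optional character vector ("M"/"F") for founders;
#'   default random 1:1.
#' @param final_sex_counts Optional `c(M = ..., F = ...)` forcing the sex
#'   composition (and size) of the final generation.
#' @return List with `haplotypes` (final generation), `sexes` (final
#'   generation), `pedigree` (tibble `id`, `sire`, `dam`, `sex`,
#'   `generation` covering all burn-in offspring; founders are ids
#'   `1..n_founders` with unknown parents and are not listed), and
#'   `founder_sexes`.
#' @export
burn_in_random_mating <- function(founders, map = genome_map(),
                                  n_generations = 5,
                                  offspring_per_generation = NULL,
                                  founder_sexes = NULL,
                                  final_sex_counts = NULL) {
  stopifnot(n_generations >= 0)
  n0 <- n_individuals(founders)
  sexes <- founder_sexes %||%
    sample(rep_len(c("M", "F"), n0))
  stopifnot(length(sexes) == n0)
  opg <- offspring_per_generation %||% n0
  founder_sexes0 <- sexes

  ped <- list()
  H <- unclass(founders)
  next_id <- n0 + 1L
  gen_ids <- seq_len(n0)

  if (n_generations == 0) {
    return(list(haplotypes = founders, sexes = sexes,
                pedigree = tibble(id = integer(), sire = integer(),
                                  dam = integer(), sex = character(),
                                  generation = integer()),
                founder_sexes = sexes))
  }

  for (g in seq_len(n_generations)) {
    males <- which(sexes == "M")
    females <- which(sexes == "F")
    if (length(males) < 1 || length(females) < 1)
      stop("burn-in generation has fewer than one individual of a sex",
           call. = FALSE)
    last <- g == n_generations
    if (last && !is.null(final_sex_counts)) {
      n_off <- sum(final_sex_counts)
      off_sex <- sample(rep(c("M", "F"), times = final_sex_counts[c("M", "F")]))
    } else {
      n_off <- opg
      off_sex <- ifelse(rbinom(n_off, 1, 0.5) == 1, "M", "F")
    }
    sire_pos <- males[sample.int(length(males), n_off, replace = TRUE)]
    dam_pos <- females[sample.int(length(females), n_off, replace = TRUE)]
    pat <- gametes_from_cols(H, 2 * sire_pos - 1, 2 * sire_pos, map)
    mat <- gametes_from_cols(H, 2 * dam_pos - 1, 2 * dam_pos, map)
    Hn <- matrix(0L, nrow(H), 2 * n_off)
    Hn[, seq(1, 2 * n_off, 2)] <- pat
    Hn[, seq(2, 2 * n_off, 2)] <- mat
    ids <- seq.int(next_id, length.out = n_off)
    ped[[g]] <- tibble(id = ids, sire = gen_ids[sire_pos],
                       dam = gen_ids[dam_pos], sex = off_sex,
                       generation = g)
    next_id <- next_id + n_off
    H <- Hn
    sexes <- off_sex
    gen_ids <- ids
  }

  list(haplotypes = new_haplo_set(H), sexes = sexes,
       pedigree = dplyr::bind_rows(ped), founder_sexes = founder_sexes0)
}

#' Empirical allele frequencies of a haplotype set
#'
#' @param haplotypes A `haplo_set`.
#' @return Numeric vector of per-locus allele-1 frequencies.
#' @export
allele_frequencies <- function(haplotypes) {
  rowMeans(unclass(haplotypes))
}
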