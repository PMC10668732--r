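#' Export haplotypes as a phased VCF
#'
#' Writes the panel as a minimal VCF 4.2 file with phased `GT` fields;
#' physical positions are synthesised from the genetic map (1 Morgan =
#' 100 Mb) since the panel is synthetic. Allele 0 is written as REF `A`,
#' allele 1 as ALT `G`.
#'
#' @param haplotypes A `haplo_set`.
#' @param map The [genome_map()] the haplotypes live on.
#' @param path Output `.vcf` path (plain text).
#' @param ids Sample names; default `ind1..indN`.
#' @export
write_vcf <- function(haplotypes, map, path, ids = NULL) {
  H <- unclass(haplotypes)
  n <- ncol(H) / 2
  ids <- ids %||% paste0("ind", seq_len(n))
  stopifnot(length(ids) == n, nrow(H) == nrow(map))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=merinosim",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", ids), collapse = "\t")),
             con)
  gt <- matrix(paste(H[, seq(1, ncol(H), 2)], H[, seq(2, ncol(H), 2)],
                     sep = "|"), nrow = nrow(H))
  body <- paste(map$chrom, as.integer(round(map$pos * 1e8)),
                paste0("snp", map$locus), "A", "G", ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Import founder haplotypes from a phased VCF
#'
#' Reads biallelic, fully phased genotypes (via the vcfR package) and maps
#' them onto a [genome_map()]: one map locus per VCF record, in file order.
#' Use this to seed the simulator with a real genotype panel instead of the
#' synthetic founders.
#'
#' @param path VCF file (plain or gzipped).
#' @param map Optional genome map to validate against (locus count must
#'   match); if `NULL`, an evenly spaced map with the VCF's chromosome
#'   structure is built (1 Morgan per chromosome).
#' @return List `haplotypes` (a `haplo_set`), `map`, `ids` (sample names).
#' @export
read_founders_vcf <- function(path, map = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("package vcfR is required for VCF import", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl("/", gt)))
    stop("VCF genotypes must be phased (GT with '|')", call. = FALSE)
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
  if (!all(c(a1, a2) %in% c("0", "1")))
    stop("only biallelic 0/1 genotypes are supported", call. = FALSE)
  L <- nrow(gt); n <- ncol(gt)
  H <- matrix(0L, L, 2 * n)
  H[, seq(1, 2 * n, 2)] <- matrix(as.integer(a1), L, n)
  H[, seq(2, 2 * n, 2)] <- matrix(as.integer(a2), L, n)
  chrom <- vcfR::getCHROM(v)
  if (is.null(map)) {
    counts <- table(factor(chrom, levels = unique(chrom)))
    map <- genome_map(n_chromosomes = length(counts),
                      loci_per_chromosome = max(counts), map_length = 1)
    if (length(unique(counts)) > 1)
      stop("chromosomes with unequal locus counts need an explicit map",
           call. = FALSE)
  } else if (nrow(map) != L) {
    stop("map has ", nrow(map), " loci but VCF has ", L, call. = FALSE)
  }
  list(haplotypes = new_haplo_set(H), map = map, ids = colnames(gt))
}
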