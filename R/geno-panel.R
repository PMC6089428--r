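#' Genotype panel: individuals x SNPs with map and sample metadata
#'
#' Container for a biallelic genotype matrix (values 0/1/2 = copies of the
#' focal allele, `NA` = missing), the SNP map (scaffold, 1-based position) and
#' per-individual sample metadata (population, collection year, and optionally
#' an explicit sampling-event label). SNPs are stored sorted by scaffold then
#' position; positions are unique within a scaffold.
#'
#' @param genotypes Integer matrix, individuals in rows (rownames = individual
#'   ids), SNPs in columns (colnames = SNP ids), values in `c(0, 1, 2, NA)`.
#' @param snp_map Data frame with columns `snp_id`, `scaffold`, `pos` matching
#'   the genotype columns.
#' @param sample_meta Data frame with columns `individual`, `population`,
#'   `year` (and optionally `event`) matching the genotype rows. When `event`
#'   is absent each distinct (population, year) is its own sampling event.
#' @return An object of class `geno_panel`.
#' @export
geno_panel <- function(genotypes, snp_map, sample_meta) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  snp_map <- as_tibble(snp_map)
  sample_meta <- as_tibble(sample_meta)
  if ("pos" %in% names(snp_map)) snp_map$pos <- as.integer(snp_map$pos)
  if (!all(c("snp_id", "scaffold", "pos") %in% names(snp_map))) {
    abort("`snp_map` needs columns snp_id, scaffold, pos.")
  }
  if (!all(c("individual", "population", "year") %in% names(sample_meta))) {
    abort("`sample_meta` needs columns individual, population, year.")
  }
  if (ncol(genotypes) != nrow(snp_map)) {
    abort("genotype columns and `snp_map` rows differ in number.")
  }
  if (nrow(genotypes) != nrow(sample_meta)) {
    abort("genotype rows and `sample_meta` rows differ in number.")
  }
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && !all(bad %in% 0:2)) {
    abort("genotypes must be 0, 1, 2 or NA.")
  }
  if (!("event" %in% names(sample_meta))) {
    sample_meta$event <- paste(sample_meta$population, sample_meta$year, sep = ":")
  }
  ord <- order(snp_map$scaffold, snp_map$pos)
  snp_map <- snp_map[ord, ]
  genotypes <- genotypes[, ord, drop = FALSE]
  dup <- duplicated(snp_map[c("scaffold", "pos")])
  if (any(dup)) abort("duplicate (scaffold, pos) in `snp_map`.")
  if (is.null(colnames(genotypes))) colnames(genotypes) <- snp_map$snp_id
  if (is.null(rownames(genotypes))) rownames(genotypes) <- sample_meta$individual
  structure(
    list(genotypes = genotypes, snp_map = snp_map, sample_meta = sample_meta),
    class = "geno_panel"
  )
}

#' @export
print.geno_panel <- function(x, ...) {
  cat("<geno_panel> ", nrow(x$genotypes), " individuals x ",
      ncol(x$genotypes), " SNPs on ", length(unique(x$snp_map$scaffold)),
      " scaffold(s)\n", sep = "")
  cat("  populations: ",
      paste(unique(x$sample_meta$population), collapse = ", "), "\n", sep = "")
  miss <- mean(is.na(x$genotypes))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_panel <- function(x) dim(x$genotypes)

#' Number of SNPs in a panel
#' @param panel A [geno_panel].
#' @return Integer SNP count.
#' @export
n_snps <- function(panel) ncol(panel$genotypes)

#' Long-format view of a genotype panel
#'
#' @param x A [geno_panel].
#' @param ... Unused.
#' @return Tibble with one row per (individual, SNP): `individual`,
#'   `population`, `year`, `event`, `snp_id`, `scaffold`, `pos`, `genotype`.
#' @export
tidy.geno_panel <- function(x, ...) {
  long <- as_tibble(x$genotypes, rownames = "individual") |>
    tidyr::pivot_longer(-"individual", names_to = "snp_id",
                        values_to = "genotype")
  long |>
    left_join(x$sample_meta, by = "individual") |>
    left_join(x$snp_map, by = "snp_id") |>
    select("individual", "population", "year", "event",
           "snp_id", "scaffold", "pos", "genotype")
}

# keep a subset of SNP columns (logical or integer index over current order)
.panel_keep <- function(panel, keep) {
  geno_panel(panel$genotypes[, keep, drop = FALSE],
             panel$snp_map[keep, , drop = FALSE],
             panel$sample_meta)
}

# per-individual sampling-group labels (the "samples" of the filtering rules)
.sample_groups <- function(panel) panel$sample_meta$event
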