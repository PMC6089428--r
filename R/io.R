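#' Read a genotype panel from the TSV genotype dialect
#'
#' The dialect has one row per SNP: columns `scaffold`, `pos`, `snp_id`, then
#' one 0/1/2/NA column per individual (column name = individual id). Sample
#' metadata come from a companion TSV with columns `individual`, `population`,
#' `year` (optionally `event`).
#'
#' @param geno_path Path to the genotype TSV.
#' @param meta_path Path to the sample-metadata TSV.
#' @return A [geno_panel].
#' @export
read_geno_tsv <- function(geno_path, meta_path) {
  geno <- readr::read_tsv(geno_path, show_col_types = FALSE)
  need <- c("scaffold", "pos", "snp_id")
  if (!all(need %in% names(geno))) {
    abort(sprintf("%s: first columns must be scaffold, pos, snp_id.", geno_path))
  }
  meta <- read_sample_meta(meta_path)
  inds <- setdiff(names(geno), need)
  G <- t(as.matrix(geno[inds]))
  colnames(G) <- geno$snp_id
  missing_meta <- setdiff(inds, meta$individual)
  if (length(missing_meta)) {
    abort(sprintf("%s: individuals absent from metadata: %s", geno_path,
                  paste(head(missing_meta, 5), collapse = ", ")))
  }
  meta <- meta[match(inds, meta$individual), ]
  geno_panel(G, geno[c("snp_id", "scaffold", "pos")], meta)
}

#' @rdname read_geno_tsv
#' @param panel A [geno_panel] to write.
#' @param geno_path,meta_path Output paths.
#' @export
write_geno_tsv <- function(panel, geno_path, meta_path = NULL) {
  df <- bind_cols(panel$snp_map[c("scaffold", "pos", "snp_id")],
                  as_tibble(t(panel$genotypes)))
  readr::write_tsv(df, geno_path)
  if (!is.null(meta_path)) write_sample_meta(panel$sample_meta, meta_path)
  invisible(geno_path)
}

#' Read or write the sample-metadata TSV
#' @param path Path to a TSV with columns `individual`, `population`, `year`.
#' @return A tibble.
#' @export
read_sample_meta <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("individual", "population", "year") %in% names(meta))) {
    abort(sprintf("%s: needs columns individual, population, year.", path))
  }
  meta
}

#' @rdname read_sample_meta
#' @param meta Sample-metadata tibble.
#' @export
write_sample_meta <- function(meta, path) {
  readr::write_tsv(meta, path)
  invisible(path)
}

#' Read a genotype panel from a VCF
#'
#' Keeps biallelic SNPs only and codes genotypes as copies of the ALT (focal)
#' allele; half-missing genotypes are treated as missing.
#'
#' @param vcf_path Path to a VCF file (plain or gzipped).
#' @param meta_path Path to the sample-metadata TSV.
#' @return A [geno_panel].
#' @export
read_geno_vcf <- function(vcf_path, meta_path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package.")
  }
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  if (!all(bi)) {
    warn(sprintf("%d non-biallelic site(s) dropped.", sum(!bi)))
    v <- v[bi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  allele_count <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/", fixed = TRUE)
    vapply(a, function(al) {
      if (length(al) != 2L || any(al == ".")) return(NA_integer_)
      sum(al == "1")
    }, integer(1))
  }
  G <- apply(gt, 2, allele_count)          # SNPs x individuals -> per column
  G <- t(matrix(G, nrow = nrow(gt), dimnames = dimnames(gt)))
  fix <- vcfR::getFIX(v)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  snp_map <- tibble(snp_id = ids, scaffold = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]))
  colnames(G) <- snp_map$snp_id
  meta <- read_sample_meta(meta_path)
  inds <- rownames(G)
  meta <- meta[match(inds, meta$individual), ]
  if (anyNA(meta$individual)) abort("VCF samples missing from metadata.")
  geno_panel(G, snp_map, meta)
}

#' Write a genotype panel as a minimal VCF
#'
#' Emits a VCFv4.2 file with GT-only genotypes (`0/0`, `0/1`, `1/1`, `./.`)
#' and placeholder REF/ALT alleles (A/T): the panel tracks dosages of a focal
#' allele, not nucleotides.
#'
#' @param panel A [geno_panel].
#' @param path Output path.
#' @export
write_geno_vcf <- function(panel, path) {
  G <- panel$genotypes
  map <- panel$snp_map
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(c(map$scaffold[j], map$pos[j], map$snp_id[j], "A", "T", ".", "PASS",
            ".", "GT", gt), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=driftscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G)), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a scan result as TSV
#' @param scan A `wf_scan` tibble.
#' @param path Output path.
#' @export
write_scan_tsv <- function(scan, path) {
  readr::write_tsv(as_tibble(scan), path)
  invisible(path)
}

#' Read a scan result written by [write_scan_tsv()]
#' @param path Path to the TSV.
#' @return A `wf_scan` tibble.
#' @export
read_scan_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  class(out) <- c("wf_scan", class(out))
  out
}

#' Write simulation truth as TSV
#'
#' The per-generation population-count trajectory is serialised as a
#' comma-separated string.
#'
#' @param truth Truth tibble from [simulate_panel()].
#' @param path Output path.
#' @export
write_truth_tsv <- function(truth, path) {
  df <- truth |>
    mutate(trajectory = purrr::map_chr(.data$trajectory, paste, collapse = ","))
  readr::write_tsv(df, path)
  invisible(path)
}
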