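#' Call selection-signature regions from a scan
#'
#' Candidate SNPs seed signatures of selection under two rules: a single SNP
#' with `pvalue < p1`, or two SNPs adjacent in the filtered SNP order on the
#' same scaffold both with `pvalue < p2`. Seeded SNPs on one scaffold whose
#' positions are within `merge_bp` of each other are merged into one signature
#' spanning the member positions. A merged signature's criterion is
#' `"single_p1"` when any member passes the single-SNP rule, else `"pair_p2"`.
#'
#' @param scan A `wf_scan` (or any tibble with `snp_id`, `scaffold`, `pos`,
#'   `pvalue`), sorted by scaffold and position.
#' @param p1 Single-SNP p-value threshold (default 1e-4).
#' @param p2 Neighbouring-pair p-value threshold (default 1e-2).
#' @param merge_bp Maximum gap between seeded SNPs merged into one signature
#'   (default 100 kb).
#' @return A `selection_signatures` tibble: `scaffold`, `start`, `end`
#'   (1-based inclusive), `criterion`, `n_snps`, `member_snps` (list-column of
#'   SNP ids), `genes` (list-column, filled by [annotate_genes()]).
#' @examples
#' scan <- tibble::tibble(snp_id = paste0("s", 1:4), scaffold = "scf1",
#'                        pos = c(100L, 200L, 5000L, 900000L),
#'                        pvalue = c(0.005, 0.008, 5e-5, 0.5))
#' call_signatures(scan)
#' @export
call_signatures <- function(scan, p1 = 1e-4, p2 = 1e-2, merge_bp = 100000) {
  df <- as_tibble(scan) |> arrange(.data$scaffold, .data$pos)
  single <- df$pvalue < p1
  adj_same_scf <- df$scaffold[-1] == df$scaffold[-nrow(df)]
  pair_left <- c(df$pvalue[-nrow(df)] < p2 & df$pvalue[-1] < p2 & adj_same_scf,
                 FALSE)
  pair <- pair_left | c(FALSE, pair_left[-length(pair_left)])
  seeded <- single | pair
  if (!any(seeded)) return(.empty_signatures())

  seeds <- df[seeded, ]
  seeds$is_single <- single[seeded]
  sig <- seeds |>
    group_by(.data$scaffold) |>
    mutate(cluster = cumsum(c(1, diff(.data$pos) > merge_bp))) |>
    group_by(.data$scaffold, .data$cluster) |>
    summarise(
      start = min(.data$pos),
      end = max(.data$pos),
      criterion = if (any(.data$is_single)) "single_p1" else "pair_p2",
      n_snps = dplyr::n(),
      member_snps = list(.data$snp_id),
      .groups = "drop"
    ) |>
    select(-"cluster") |>
    arrange(.data$scaffold, .data$start) |>
    mutate(genes = vector("list", dplyr::n()))
  class(sig) <- c("selection_signatures", class(sig))
  sig
}

.empty_signatures <- function() {
  sig <- tibble(scaffold = character(), start = integer(), end = integer(),
                criterion = character(), n_snps = integer(),
                member_snps = list(), genes = list())
  class(sig) <- c("selection_signatures", class(sig))
  sig
}

#' Attach nearby genes to selection signatures
#'
#' A gene is attached to a signature when both lie on the same scaffold and
#' the distance between the gene interval and the signature interval is
#' strictly less than `max_dist` (0 when they overlap). When the gene table
#' carries a logical `has_orthologue` column, genes are first restricted to
#' those with an orthologue.
#'
#' @param signatures A `selection_signatures` tibble from [call_signatures()].
#' @param genes Tibble of gene records: `gene_id`, `scaffold`, `start`, `end`
#'   (1-based inclusive), optionally `strand` and `has_orthologue`. See
#'   [read_gff_genes()].
#' @param max_dist Maximum gene-signature distance in bp, exclusive
#'   (default 100 kb).
#' @return The signatures with the `genes` list-column filled with gene ids.
#' @export
annotate_genes <- function(signatures, genes, max_dist = 100000) {
  genes <- as_tibble(genes)
  if (any(genes$start > genes$end)) abort("gene records need start <= end.")
  if ("has_orthologue" %in% names(genes)) {
    genes <- filter(genes, .data$has_orthologue)
  }
  signatures$genes <- purrr::pmap(
    list(signatures$scaffold, signatures$start, signatures$end),
    function(scf, s0, e0) {
      g <- genes[genes$scaffold == scf, ]
      if (!nrow(g)) return(character(0))
      gap <- pmax(0, pmax(g$start - e0, s0 - g$end))
      g$gene_id[gap < max_dist]
    }
  )
  signatures
}

#' Read gene records from a GFF3 annotation
#'
#' Imports a GFF3 file and keeps features of the given type as a flat gene
#' table suitable for [annotate_genes()]. All GFF attributes are carried
#' through as extra columns; a logical attribute named `has_orthologue` (or an
#' attribute given via `orthologue_attr`) is normalised to the
#' `has_orthologue` column that [annotate_genes()] filters on.
#'
#' @param path Path to a GFF3 file.
#' @param feature Feature type to keep (default `"gene"`).
#' @param orthologue_attr Optional name of the GFF attribute flagging a human
#'   orthologue; values `"1"`, `"true"`, `"yes"` (any case) count as `TRUE`.
#' @return Tibble: `gene_id`, `scaffold`, `start`, `end`, `strand`, plus
#'   attribute columns.
#' @export
read_gff_genes <- function(path, feature = "gene", orthologue_attr = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GFF3 requires the rtracklayer package.")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == feature]
  meta <- as_tibble(as.data.frame(S4Vectors::mcols(gr)))
  out <- tibble(
    gene_id = if ("ID" %in% names(meta)) as.character(meta$ID)
              else as.character(seq_along(gr)),
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  extra <- meta[setdiff(names(meta), c("ID", "type", "score", "phase", "source"))]
  out <- bind_cols(out, as_tibble(extra))
  if (!is.null(orthologue_attr) && orthologue_attr %in% names(out)) {
    out$has_orthologue <- tolower(as.character(out[[orthologue_attr]])) %in%
      c("1", "true", "yes")
  }
  out
}

#' Write signatures as a BED-like TSV
#'
#' Output uses the BED convention: 0-based half-open `start`/`end` (internally
#' signatures are 1-based inclusive). Member SNPs and genes are
#' comma-separated lists.
#'
#' @param signatures A `selection_signatures` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_signatures_bed <- function(signatures, path) {
  df <- as_tibble(signatures) |>
    mutate(start = .data$start - 1L,
           member_snps = purrr::map_chr(.data$member_snps, paste, collapse = ","),
           genes = purrr::map_chr(.data$genes, function(g) {
             if (length(g)) paste(g, collapse = ",") else "."
           })) |>
    select("scaffold", "start", "end", "criterion", "n_snps",
           "member_snps", "genes")
  writeLines(paste0("# selection signatures; start is 0-based half-open (BED)"),
             path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read signatures written by [write_signatures_bed()]
#' @param path Path to the BED-like TSV.
#' @return A `selection_signatures` tibble (1-based inclusive coordinates).
#' @export
read_signatures_bed <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (nrow(df) == 0L) return(.empty_signatures())
  sig <- df |>
    mutate(start = as.integer(.data$start + 1L),
           end = as.integer(.data$end),
           member_snps = strsplit(.data$member_snps, ","),
           genes = purrr::map(.data$genes, function(g) {
             if (is.na(g) || g == ".") character(0) else strsplit(g, ",")[[1]]
           }))
  class(sig) <- c("selection_signatures", class(sig))
  sig
}

#' @export
autoplot.selection_signatures <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(width_kb = (.data$end - .data$start + 1) / 1e3)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scaffold, y = .data$width_kb,
                                   fill = .data$criterion)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "signature width (kb)",
                  title = "Called signatures of selection") +
    ggplot2::theme_minimal()
}
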