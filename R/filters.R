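#' SNP filters for temporal genotype panels
#'
#' The four-step protocol applied to temporal RAD-seq SNP panels before
#' scanning for selection: (i) minor allele frequency over the whole dataset,
#' (ii) observed heterozygosity over the whole dataset, (iii) missingness
#' overall and per sample, (iv) linkage-disequilibrium pruning of near-perfectly
#' correlated neighbours. [run_filters()] chains all four and reports
#' telescoping SNP counts per step.
#'
#' @name snp_filters
NULL

#' Filter SNPs on minor allele frequency
#'
#' MAF is computed over all non-missing genotypes pooled across the whole
#' panel. SNPs with MAF strictly below `threshold` are removed; a SNP with all
#' genotypes missing has undefined MAF and is removed too.
#'
#' @param panel A [geno_panel].
#' @param threshold MAF cutoff in (0, 0.5); SNPs with MAF < threshold go.
#' @return The filtered [geno_panel].
#' @export
filter_maf <- function(panel, threshold = 0.01) {
  if (threshold <= 0 || threshold >= 0.5) abort("`threshold` must be in (0, 0.5).")
  G <- panel$genotypes
  n_chr <- 2L * colSums(!is.na(G))
  freq <- colSums(G, na.rm = TRUE) / n_chr    # NaN when all missing
  maf <- pmin(freq, 1 - freq)
  drop <- is.na(maf) | maf < threshold
  if (any(is.na(maf))) {
    warn(sprintf("%d SNP(s) with all genotypes missing removed at the MAF step.",
                 sum(is.na(maf))))
  }
  .panel_keep(panel, !drop)
}

#' Filter SNPs on observed heterozygosity
#'
#' Observed heterozygosity is the fraction of non-missing genotypes equal to 1
#' (heterozygous), over the whole panel. SNPs strictly above `threshold` are
#' removed — excess heterozygosity at this level flags paralog collapse in
#' RAD-seq assemblies.
#'
#' @inheritParams filter_maf
#' @param threshold Heterozygosity cutoff in (0, 1]; SNPs with H > threshold go.
#' @export
filter_het <- function(panel, threshold = 0.5) {
  if (threshold <= 0 || threshold > 1) abort("`threshold` must be in (0, 1].")
  G <- panel$genotypes
  het <- colMeans(G == 1L, na.rm = TRUE)
  drop <- !is.na(het) & het > threshold
  .panel_keep(panel, !drop)
}

#' Filter SNPs on missing-genotype rates
#'
#' A SNP is removed when its genotype call rate falls below `overall_min`
#' across the whole panel, or below `sample_min` within any sampling event —
#' except that for the `n_strict` smallest sampling events (fewest
#' individuals, ties broken by earlier collection year) the per-sample
#' requirement is the stricter `strict_min` instead of `sample_min`.
#'
#' @inheritParams filter_maf
#' @param overall_min Minimum call rate over the whole panel (default 1/3).
#' @param sample_min Minimum call rate within each ordinary sample (default 1/3).
#' @param strict_min Minimum call rate within the smallest samples (default 1/2).
#' @param n_strict How many of the smallest samples use `strict_min` (default 2).
#' @export
filter_missing <- function(panel, overall_min = 1 / 3, sample_min = 1 / 3,
                           strict_min = 1 / 2, n_strict = 2) {
  G <- panel$genotypes
  groups <- .sample_groups(panel)
  call_overall <- colMeans(!is.na(G))

  meta <- panel$sample_meta |>
    group_by(.data$event) |>
    summarise(n = dplyr::n(), year = min(.data$year), .groups = "drop") |>
    arrange(.data$n, .data$year)
  strict <- head(meta$event, n_strict)

  drop <- call_overall < overall_min
  for (g in meta$event) {
    idx <- groups == g
    rate <- colMeans(!is.na(G[idx, , drop = FALSE]))
    need <- if (g %in% strict) strict_min else sample_min
    drop <- drop | rate < need
  }
  .panel_keep(panel, !drop)
}

#' Prune SNPs in near-perfect linkage disequilibrium
#'
#' Within each scaffold, every pair of SNPs at most `window_snps` apart in SNP
#' order and at most `window_bp` apart in position is examined; the genotype
#' (dosage) correlation R-squared is computed separately within each sampling
#' event using pairwise-complete observations, and if it exceeds
#' `r2_threshold` in any sample the later (right-hand) SNP of the pair is
#' removed. The sweep is deterministic left to right; pairs involving a SNP
#' already removed, or a SNP with zero variance in a sample, are skipped for
#' that sample.
#'
#' @inheritParams filter_maf
#' @param r2_threshold R-squared above which a pair is pruned (default 0.99).
#' @param window_snps Maximum separation in SNP order (default 20).
#' @param window_bp Maximum separation in base pairs (default 50000).
#' @export
ld_prune <- function(panel, r2_threshold = 0.99, window_snps = 20,
                     window_bp = 50000) {
  G <- panel$genotypes
  map <- panel$snp_map
  groups <- .sample_groups(panel)
  group_idx <- split(seq_along(groups), groups)
  removed <- logical(ncol(G))

  for (scf in unique(map$scaffold)) {
    idx <- which(map$scaffold == scf)    # already position-sorted
    pos <- map$pos[idx]
    for (a in seq_along(idx)) {
      i <- idx[a]
      if (removed[i]) next
      upper <- min(a + window_snps, length(idx))
      if (upper <= a) next
      for (b in (a + 1L):upper) {
        j <- idx[b]
        if (pos[b] - pos[a] > window_bp) break
        if (removed[j]) next
        for (gi in group_idx) {
          x <- G[gi, i]; y <- G[gi, j]
          ok <- !is.na(x) & !is.na(y)
          if (sum(ok) < 2L) next
          x <- x[ok]; y <- y[ok]
          if (stats::var(x) == 0 || stats::var(y) == 0) next
          if (cor(x, y)^2 > r2_threshold) {
            removed[j] <- TRUE
            break
          }
        }
      }
    }
  }
  .panel_keep(panel, !removed)
}

#' Run the full four-step SNP filtering protocol
#'
#' Applies [filter_maf()], [filter_het()], [filter_missing()] and [ld_prune()]
#' in that order and reports telescoping SNP counts.
#'
#' @inheritParams filter_maf
#' @param maf,het MAF and heterozygosity cutoffs.
#' @param overall_min,sample_min,strict_min,n_strict Missingness rule, see
#'   [filter_missing()].
#' @param r2_threshold,window_snps,window_bp LD pruning rule, see [ld_prune()].
#' @return List with `panel` (filtered [geno_panel]) and `report`, a
#'   `filter_report` tibble: one row per step with `step`, `n_in`, `n_removed`,
#'   `n_out` and the removed SNP ids as a list-column.
#' @examples
#' sim <- simulate_panel(sim_config(devil_designs()$FN, n_snps = 50,
#'                                  missing_rate = 0.05, seed = 7))
#' out <- run_filters(sim$panel)
#' out$report
#' @export
run_filters <- function(panel, maf = 0.01, het = 0.5,
                        overall_min = 1 / 3, sample_min = 1 / 3,
                        strict_min = 1 / 2, n_strict = 2,
                        r2_threshold = 0.99, window_snps = 20,
                        window_bp = 50000) {
  steps <- list(
    maf = function(p) filter_maf(p, maf),
    het = function(p) filter_het(p, het),
    missing = function(p) filter_missing(p, overall_min, sample_min,
                                         strict_min, n_strict),
    ld = function(p) ld_prune(p, r2_threshold, window_snps, window_bp)
  )
  report <- vector("list", length(steps))
  cur <- panel
  for (i in seq_along(steps)) {
    nxt <- steps[[i]](cur)
    gone <- setdiff(cur$snp_map$snp_id, nxt$snp_map$snp_id)
    report[[i]] <- tibble(
      step = names(steps)[i],
      n_in = n_snps(cur),
      n_removed = length(gone),
      n_out = n_snps(nxt),
      removed_snps = list(gone)
    )
    cur <- nxt
  }
  report <- bind_rows(report)
  class(report) <- c("filter_report", class(report))
  list(panel = cur, report = report)
}

#' @export
autoplot.filter_report <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(step = factor(.data$step, levels = .data$step))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$n_out)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_text(ggplot2::aes(label = paste0("-", .data$n_removed)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "filter step", y = "SNPs retained",
                  title = "SNPs surviving each filter step") +
    ggplot2::theme_minimal()
}
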