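#' Scan one population's SNPs for temporal selection
#'
#' Runs the Wright-Fisher likelihood-ratio test on every SNP of a
#' single-population genotype panel. Per sampling event, the observed counts
#' are the non-missing genotypes: `n` = 2 x genotyped individuals and `k` = the
#' summed dosage. SNPs with no genotyped individual at some event cannot be
#' tested and are dropped with a warning; SNPs monomorphic across all events
#' carry no temporal information and get `s_hat = 0`, `lrt = 0`, `pvalue = 1`.
#' Benjamini-Hochberg q-values are computed within the population.
#'
#' @param panel A [geno_panel] containing one population whose individuals'
#'   collection years match the design's sampling events.
#' @param design The population's [population_design].
#' @param grid Selection-coefficient grid, see [s_grid_default()].
#' @param init Initial condition of the likelihood, see [wf_loglik()].
#' @return A `wf_scan` tibble, one row per tested SNP: `snp_id`, `scaffold`,
#'   `pos`, per-event counts `k1`, `n1`, `k2`, `n2`, ..., then `s_hat`,
#'   `logL0`, `logL1`, `lrt`, `pvalue`, `qvalue`.
#' @examples
#' sim <- simulate_panel(sim_config(devil_designs()$FN, n_snps = 30, seed = 3))
#' scan <- scan_population(sim$panel, devil_designs()$FN)
#' head(scan)
#' @export
scan_population <- function(panel, design, grid = s_grid_default(),
                            init = c("first_sample", "uniform")) {
  init <- match.arg(init)
  .check_grid(grid)
  pops <- unique(panel$sample_meta$population)
  if (length(pops) != 1L) {
    abort("`panel` must contain exactly one population; split by population first.")
  }
  ev <- design$events
  year_to_event <- rep(NA_integer_, nrow(panel$sample_meta))
  for (e in seq_len(nrow(ev))) {
    year_to_event[panel$sample_meta$year %in% ev$years[[e]]] <- ev$event[e]
  }
  if (anyNA(year_to_event)) {
    warn(sprintf("%d individual(s) with collection years outside the design were dropped.",
                 sum(is.na(year_to_event))))
  }

  G <- panel$genotypes
  E <- nrow(ev)
  K <- matrix(0L, ncol(G), E)
  N <- matrix(0L, ncol(G), E)
  for (e in seq_len(E)) {
    idx <- which(year_to_event == e)
    sub <- G[idx, , drop = FALSE]
    N[, e] <- 2L * colSums(!is.na(sub))
    K[, e] <- colSums(sub, na.rm = TRUE)
  }

  testable <- rowSums(N == 0L) == 0L
  if (any(!testable)) {
    warn(sprintf("%d SNP(s) with no genotypes at some sampling event were skipped.",
                 sum(!testable)))
  }
  mono <- testable & (rowSums(K) == 0L | rowSums(K) == rowSums(N))

  model <- .wf_model(design$Ne, ev$gen_offset, grid)
  res <- .wf_lrt_batch(K[testable, , drop = FALSE], N[testable, , drop = FALSE],
                       model, init = init)
  Kt <- K[testable, , drop = FALSE]
  Nt <- N[testable, , drop = FALSE]
  colnames(Kt) <- paste0("k", seq_len(E))
  colnames(Nt) <- paste0("n", seq_len(E))
  out <- bind_cols(panel$snp_map[testable, ], as_tibble(Kt), as_tibble(Nt), res)
  # monomorphic SNPs: no temporal signal by construction
  mono_here <- mono[testable]
  out$s_hat[mono_here] <- 0
  out$logL1[mono_here] <- out$logL0[mono_here]
  out$lrt[mono_here] <- 0
  out$pvalue[mono_here] <- 1
  out$qvalue <- bh_fdr(out$pvalue)
  attr(out, "population") <- design$name
  attr(out, "Ne") <- design$Ne
  class(out) <- c("wf_scan", class(out))
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; a thin wrapper around
#' [stats::p.adjust()] with input validation. Applied within each population's
#' scan separately.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length, each `>=` its p-value.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}

#' @export
tidy.wf_scan <- function(x, ...) as_tibble(x)

#' @export
glance.wf_scan <- function(x, p1 = 1e-4, p2 = 1e-2, ...) {
  tibble(
    population = attr(x, "population") %||% NA_character_,
    n_snp = nrow(x),
    n_p1 = sum(x$pvalue < p1),
    n_p2 = sum(x$pvalue < p2),
    min_pvalue = if (nrow(x)) min(x$pvalue) else NA_real_,
    median_s_hat = if (nrow(x)) stats::median(x$s_hat) else NA_real_
  )
}

#' Manhattan-style plot of a selection scan
#'
#' @param object A `wf_scan` from [scan_population()].
#' @param p1,p2 Significance thresholds drawn as horizontal lines.
#' @param ... Unused.
#' @return A ggplot object: -log10 p-value by position, faceted by scaffold.
#' @export
autoplot.wf_scan <- function(object, p1 = 1e-4, p2 = 1e-2, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6,
                                   y = -log10(pmax(.data$pvalue, 1e-300)))) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(c(p2, p1)), linetype = "dashed",
                        colour = c("steelblue", "firebrick")) +
    ggplot2::facet_wrap(~scaffold, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p)),
                  title = paste("Temporal selection scan",
                                attr(object, "population") %||% "")) +
    ggplot2::theme_minimal()
}
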