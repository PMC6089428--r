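#' Simulate a Wright-Fisher allele-count trajectory
#'
#' Forward-simulates the population allele count of one biallelic locus through
#' discrete generations: the count starts at `round(2 * Ne * p0)` and each
#' generation is drawn Binomial(`2*Ne`, `selection_update(p, s)`) from the
#' current frequency `p`. Counts 0 and `2*Ne` are absorbing.
#'
#' @inheritParams wf_transition_matrix
#' @param p0 Initial allele frequency in \[0, 1\].
#' @param generations Number of generations to simulate (>= 0).
#' @param seed Optional integer seed; if `NULL` the current RNG state is used.
#' @return Integer vector of length `generations + 1` of population counts.
#' @examples
#' simulate_trajectory(Ne = 34, s = 0.5, p0 = 0.3, generations = 6, seed = 1)
#' @export
simulate_trajectory <- function(Ne, s, p0, generations, seed = NULL) {
  if (generations < 0) abort("`generations` must be >= 0.")
  if (p0 < 0 || p0 > 1) abort("`p0` must lie in [0, 1].")
  if (!is.null(seed)) set.seed(seed)
  two_ne <- 2L * as.integer(Ne)
  counts <- integer(generations + 1L)
  counts[1L] <- as.integer(round(two_ne * p0))
  for (t in seq_len(generations)) {
    p <- selection_update(counts[t] / two_ne, s)
    counts[t + 1L] <- rbinom(1L, two_ne, p)
  }
  counts
}

#' Sample observed allele counts along a trajectory
#'
#' Binomially samples `2 * n_diploid` chromosomes at each sampling event of a
#' design from the population frequency of the supplied trajectory — the exact
#' sampling model the likelihood's emission term assumes.
#'
#' @param trajectory Integer population counts, one per generation starting at
#'   the design's first event (offset 0).
#' @param design A [population_design] with per-event `n_diploid`.
#' @param seed Optional integer seed.
#' @return Tibble with one row per event: `event`, `gen_offset`, `k`, `n`.
#' @export
sample_counts <- function(trajectory, design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ev <- design$events
  if (max(ev$gen_offset) + 1L > length(trajectory)) {
    abort("trajectory shorter than the design's last sampling event.")
  }
  two_ne <- 2L * design$Ne
  n <- 2L * ev$n_diploid
  cnt <- trajectory[ev$gen_offset + 1L]
  tibble(
    event = ev$event,
    gen_offset = ev$gen_offset,
    k = rbinom(nrow(ev), size = n, prob = cnt / two_ne),
    n = n
  )
}

#' Configuration for a synthetic temporal genotype panel
#'
#' Bundles everything [simulate_panel()] needs: the population design, the
#' selection coefficient planted in selected SNPs, the initial-frequency law,
#' panel size, the fraction of selected SNPs, the genotype missingness rate,
#' the size of copied LD blocks and the RNG seed.
#'
#' @param design A [population_design].
#' @param s Selection coefficient applied to selected SNPs.
#' @param p0_law Initial-frequency law: a single number for a point mass or a
#'   length-2 vector `c(lo, hi)` for Uniform(lo, hi).
#' @param n_snps Number of SNPs in the panel.
#' @param prop_selected Fraction of SNPs simulated with selection.
#' @param missing_rate Per-genotype missingness probability.
#' @param ld_block_size Consecutive SNPs per perfect-LD block (1 = none);
#'   within a block all genotype columns are copies of the block head.
#' @param snps_per_scaffold SNPs placed on each synthetic scaffold.
#' @param seed Integer seed (mandatory: panels must be reproducible).
#' @return A `sim_config` list.
#' @export
sim_config <- function(design, s = 0.5, p0_law = c(0.1, 0.9), n_snps = 100,
                       prop_selected = 0, missing_rate = 0, ld_block_size = 1,
                       snps_per_scaffold = 50, seed) {
  if (missing(seed)) abort("`seed` is mandatory for reproducible panels.")
  stopifnot(inherits(design, "population_design"),
            prop_selected >= 0, prop_selected <= 1,
            missing_rate >= 0, missing_rate <= 1,
            ld_block_size >= 1, n_snps >= 1)
  structure(
    list(design = design, s = s, p0_law = p0_law, n_snps = as.integer(n_snps),
         prop_selected = prop_selected, missing_rate = missing_rate,
         ld_block_size = as.integer(ld_block_size),
         snps_per_scaffold = as.integer(snps_per_scaffold),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

.draw_p0 <- function(p0_law, n) {
  if (length(p0_law) == 1L) rep(p0_law, n) else runif(n, p0_law[1], p0_law[2])
}

#' Simulate a temporal genotype panel with known truth
#'
#' Generates a full individuals-by-SNPs genotype panel under the Wright-Fisher
#' model: each SNP gets an initial frequency from `p0_law` and a trajectory
#' (neutral or selected, per `prop_selected`); at each sampling event, sampled
#' chromosomes are drawn binomially and paired at random into diploid 0/1/2
#' genotypes (Hardy-Weinberg within the sample). SNPs are laid on synthetic
#' scaffolds with increasing positions; optional perfect-LD blocks are created
#' by copying the block head's genotype column, and genotypes are then masked
#' at `missing_rate`.
#'
#' @param cfg A [sim_config].
#' @return List with `panel` (a [geno_panel]) and `truth` (tibble: `snp_id`,
#'   `scaffold`, `pos`, `s_true`, `selected`, `p0`, and the per-generation
#'   population-count `trajectory` as a list-column).
#' @examples
#' cfg <- sim_config(devil_designs()$FN, n_snps = 20, prop_selected = 0.1,
#'                   seed = 42)
#' sim <- simulate_panel(cfg)
#' sim$panel
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  design <- cfg$design
  ev <- design$events
  two_ne <- 2L * design$Ne
  gens <- max(ev$gen_offset)
  n_ind <- sum(ev$n_diploid)

  n_blocks <- ceiling(cfg$n_snps / cfg$ld_block_size)
  block_of <- rep(seq_len(n_blocks), each = cfg$ld_block_size)[seq_len(cfg$n_snps)]
  head_of_block <- match(unique(block_of), block_of)  # first SNP of each block
  is_head <- seq_len(cfg$n_snps) %in% head_of_block

  n_sel <- round(cfg$prop_selected * n_blocks)
  sel_blocks <- if (n_sel > 0) sample(n_blocks, n_sel) else integer(0)
  s_true <- ifelse(block_of %in% sel_blocks, cfg$s, 0)

  scaffold <- paste0("scf", sprintf("%03d", (seq_len(cfg$n_snps) - 1L) %/%
                                      cfg$snps_per_scaffold + 1L))
  pos <- unlist(lapply(split(seq_len(cfg$n_snps), scaffold), function(idx) {
    cumsum(sample(500:5000, length(idx), replace = TRUE))
  }), use.names = FALSE)
  snp_id <- sprintf("snp%05d", seq_len(cfg$n_snps))

  sample_meta <- tibble(
    individual = sprintf("ind%03d", seq_len(n_ind)),
    population = design$name,
    year = unlist(mapply(function(ys, nd) rep(min(ys), nd),
                         ev$years, ev$n_diploid, SIMPLIFY = FALSE))
  )
  ind_event <- rep(ev$event, ev$n_diploid)

  G <- matrix(NA_integer_, n_ind, cfg$n_snps,
              dimnames = list(sample_meta$individual, snp_id))
  p0 <- .draw_p0(cfg$p0_law, cfg$n_snps)
  trajectories <- vector("list", cfg$n_snps)
  for (j in seq_len(cfg$n_snps)) {
    if (is_head[j]) {
      traj <- simulate_trajectory(design$Ne, s_true[j], p0[j], gens)
      geno <- integer(n_ind)
      for (e in seq_len(nrow(ev))) {
        idx <- which(ind_event == ev$event[e])
        n_chr <- 2L * length(idx)
        kk <- rbinom(1L, n_chr, traj[ev$gen_offset[e] + 1L] / two_ne)
        chroms <- sample(c(rep(1L, kk), rep(0L, n_chr - kk)))
        geno[idx] <- chroms[c(TRUE, FALSE)] + chroms[c(FALSE, TRUE)]
      }
      G[, j] <- geno
      trajectories[[j]] <- traj
    } else {
      h <- head_of_block[block_of[j]]
      G[, j] <- G[, h]               # verbatim copy: R^2 = 1 within block
      trajectories[[j]] <- trajectories[[h]]
      p0[j] <- p0[h]
    }
  }
  if (cfg$missing_rate > 0) {
    G[runif(length(G)) < cfg$missing_rate] <- NA_integer_
  }

  snp_map <- tibble(snp_id = snp_id, scaffold = scaffold, pos = as.integer(pos))
  ord <- order(snp_map$scaffold, snp_map$pos)
  snp_map <- snp_map[ord, ]
  G <- G[, ord, drop = FALSE]

  truth <- tibble(
    snp_id = snp_id, scaffold = scaffold, pos = as.integer(pos),
    s_true = s_true, selected = s_true != 0, p0 = p0,
    trajectory = trajectories
  )[ord, ]

  list(panel = geno_panel(G, snp_map, sample_meta), truth = truth)
}
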