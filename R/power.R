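# vectorised Wright-Fisher forward simulation: one row per replicate
.simulate_trajectories <- function(Ne, s, p0, generations) {
  two_ne <- 2L * as.integer(Ne)
  R <- length(p0)
  cnt <- matrix(0L, R, generations + 1L)
  cnt[, 1L] <- as.integer(round(two_ne * p0))
  for (t in seq_len(generations)) {
    p <- selection_update(cnt[, t] / two_ne, s)
    cnt[, t + 1L] <- rbinom(R, two_ne, p)
  }
  cnt
}

# replicate x event matrices of sampled counts for a design
.sample_counts_batch <- function(cnt, design) {
  ev <- design$events
  two_ne <- 2L * design$Ne
  R <- nrow(cnt)
  K <- matrix(0L, R, nrow(ev))
  N <- matrix(rep(2L * ev$n_diploid, each = R), nrow = R)
  for (e in seq_len(nrow(ev))) {
    K[, e] <- rbinom(R, N[, e], cnt[, ev$gen_offset[e] + 1L] / two_ne)
  }
  list(K = K, N = N)
}

#' Power and false-positive rate of the temporal selection test
#'
#' Monte-Carlo experiment measuring, for a given temporal sampling design, how
#' often the likelihood-ratio test flags a SNP evolving under selection
#' (power) and how often it flags a neutral SNP (false-positive rate). Each
#' replicate draws an initial frequency from `p0_law`, forward-simulates a
#' Wright-Fisher trajectory (with coefficient `s` for the selected arm, 0 for
#' the neutral arm), samples allele counts at the design's events, and tests
#' at per-SNP level `alpha`.
#'
#' The default design is the Freycinet-like setting: `Ne = 34`, samples of 29
#' and 20 diploids 6 generations apart, `s = 0.5`, initial frequency uniform
#' on (0.1, 0.9), `alpha = 0.01`.
#'
#' @param design A [population_design] (default the FN design).
#' @param s Selection coefficient of the selected arm (default 0.5).
#' @param p0_law Initial-frequency law, as in [sim_config()].
#' @param alpha Per-SNP significance level (default 0.01); replicates with
#'   p-value `<= alpha` count as significant.
#' @param n_reps Replicates per arm (>= 100; default 1000).
#' @param grid Selection-coefficient grid for the test.
#' @param init Initial condition of the likelihood, see [wf_loglik()].
#' @param seed Integer seed.
#' @return A `wf_power` tibble with one row per arm (`selected`, `neutral`):
#'   `s_true`, `n_reps`, `n_significant`, `rate`, `se`, `ci_lo`, `ci_hi`
#'   (binomial standard errors and Wilson 95% intervals). `glance()` condenses
#'   it to one row with `power` and `fpr`.
#' @examples
#' pw <- power_experiment(n_reps = 200, seed = 1)
#' glance(pw)
#' @export
power_experiment <- function(design = devil_designs()$FN, s = 0.5,
                             p0_law = c(0.1, 0.9), alpha = 0.01,
                             n_reps = 1000, grid = s_grid_default(),
                             init = c("first_sample", "uniform"), seed = 1) {
  init <- match.arg(init)
  if (n_reps < 100) abort("`n_reps` must be at least 100.")
  .check_grid(grid)
  set.seed(seed)
  ev <- design$events
  gens <- max(ev$gen_offset)
  model <- .wf_model(design$Ne, ev$gen_offset, grid)

  run_arm <- function(s_arm) {
    p0 <- .draw_p0(p0_law, n_reps)
    cnt <- .simulate_trajectories(design$Ne, s_arm, p0, gens)
    obs <- .sample_counts_batch(cnt, design)
    .wf_lrt_batch(obs$K, obs$N, model, init = init)$pvalue
  }
  p_sel <- run_arm(s)
  p_neu <- run_arm(0)

  summarise_arm <- function(arm, s_true, pv) {
    hits <- sum(pv <= alpha)
    ci <- stats::prop.test(hits, n_reps, correct = FALSE)$conf.int
    tibble(arm = arm, s_true = s_true, n_reps = n_reps, n_significant = hits,
           rate = hits / n_reps,
           se = sqrt(hits / n_reps * (1 - hits / n_reps) / n_reps),
           ci_lo = ci[1], ci_hi = ci[2])
  }
  out <- bind_rows(summarise_arm("selected", s, p_sel),
                   summarise_arm("neutral", 0, p_neu))
  attr(out, "alpha") <- alpha
  attr(out, "design") <- design
  attr(out, "p0_law") <- p0_law
  class(out) <- c("wf_power", class(out))
  out
}

#' @export
tidy.wf_power <- function(x, ...) as_tibble(x)

#' @export
glance.wf_power <- function(x, ...) {
  tibble(
    power = x$rate[x$arm == "selected"],
    fpr = x$rate[x$arm == "neutral"],
    alpha = attr(x, "alpha"),
    n_reps = x$n_reps[1],
    Ne = attr(x, "design")$Ne
  )
}

#' @export
autoplot.wf_power <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arm, y = .data$rate)) +
    ggplot2::geom_col(fill = "grey35", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                           width = 0.15) +
    ggplot2::geom_hline(yintercept = attr(object, "alpha"),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "rejection rate",
                  title = "Detection power and false-positive rate") +
    ggplot2::theme_minimal()
}
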