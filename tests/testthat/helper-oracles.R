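# Independent oracles used across tests. These deliberately re-derive results
# by the dumbest correct route (path enumeration, textbook formulas) and never
# call the package's forward-pass internals.

# Exhaustive-path log-likelihood of a temporal allele-count series.
# Sums P(hidden path) * P(observations | path) over every hidden-state path,
# for both initial conditions the package supports.
oracle_loglik <- function(k, n, gen, Ne, s, init = "first_sample") {
  two_ne <- 2L * Ne
  S <- two_ne + 1L
  q <- (0:two_ne) / two_ne
  M <- outer(q * (1 + s) / (1 + q * s), 0:two_ne,
             function(p, j) dbinom(j, two_ne, p))
  gaps <- diff(gen)
  Mg <- lapply(gaps, function(g) {
    out <- diag(S)
    for (i in seq_len(g)) out <- out %*% M
    out
  })
  E <- length(k)
  paths <- as.matrix(expand.grid(rep(list(0:two_ne), E)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    st <- paths[r, ]
    if (init == "first_sample") {
      c0 <- round(two_ne * k[1] / n[1])
      if (st[1] != c0) next
      pr <- 1
    } else {
      pr <- dbinom(k[1], n[1], q[st[1] + 1]) / S
    }
    for (e in seq_along(gaps)) {
      pr <- pr * Mg[[e]][st[e] + 1, st[e + 1] + 1] *
        dbinom(k[e + 1], n[e + 1], q[st[e + 1] + 1])
    }
    total <- total + pr
  }
  log(total)
}

# Textbook Benjamini-Hochberg step-up adjusted p-values.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(m / (m:1) * p[o]))
  q[ro]
}

# Deterministic six-fold genic selection update, used as the drift-free limit.
oracle_deterministic_freq <- function(p0, s, generations) {
  p <- p0
  for (i in seq_len(generations)) p <- p * (1 + s) / (1 + p * s)
  p
}

# Minimal two-event panel: explicit genotype matrix on one scaffold.
# `geno` is individuals x SNPs; half the individuals are assigned to 1999 and
# half to 2012 (6 generations apart under the FN-like design).
make_panel <- function(geno, pos = NULL, scaffold = "scf1",
                       years = c(1999, 2012), population = "FN") {
  n_ind <- nrow(geno)
  n_snp <- ncol(geno)
  if (is.null(pos)) pos <- seq_len(n_snp) * 1000L
  half <- n_ind %/% 2
  meta <- tibble::tibble(
    individual = sprintf("i%03d", seq_len(n_ind)),
    population = population,
    year = rep(years, c(half, n_ind - half))
  )
  rownames(geno) <- meta$individual
  if (is.null(colnames(geno))) colnames(geno) <- sprintf("s%04d", seq_len(n_snp))
  geno_panel(geno,
             tibble::tibble(snp_id = colnames(geno),
                            scaffold = scaffold, pos = as.integer(pos)),
             meta)
}

# FN-like two-event design used throughout: Ne = 34, 29 + 20 diploids,
# 6 generations apart.
fn_design <- function() {
  population_design("FN", Ne = 34, years = list(1999, c(2012, 2013)),
                    n_diploid = c(29, 20))
}

# Genotype column with fixed composition (hom-ref / het / hom-alt), permuted
# deterministically by the caller's RNG state; passes all default filters.
filler_column <- function(n_hom0 = 20, n_het = 15, n_hom2 = 15) {
  sample(rep(c(0L, 1L, 2L), c(n_hom0, n_het, n_hom2)))
}
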