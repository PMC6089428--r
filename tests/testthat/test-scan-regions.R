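test_that("scanning a panel reproduces per-event counts and flags planted selection", {
  design <- fn_design()
  set.seed(90)
  sim <- simulate_panel(sim_config(design, n_snps = 60, prop_selected = 0,
                                   missing_rate = 0.1, seed = 90))
  scan <- scan_population(sim$panel, design)
  expect_s3_class(scan, "wf_scan")
  expect_true(all(scan$pvalue >= 0 & scan$pvalue <= 1))
  expect_true(all(scan$qvalue >= scan$pvalue))
  expect_true(all(scan$lrt >= -1e-9))
  # counts rebuilt from genotypes: k <= n, n = 2 x non-missing individuals
  expect_true(all(scan$k1 <= scan$n1 & scan$k2 <= scan$n2))
  expect_true(all(scan$n1 <= 58 & scan$n2 <= 40))

  # a hand-built panel with an untestable SNP (all missing at one event)
  # and a monomorphic SNP
  G <- cbind(
    gone2 = c(filler_column(25, 13, 12)[1:25], rep(NA_integer_, 25)),
    mono = rep(2L, 50),
    ok = filler_column(20, 15, 15)
  )
  panel <- make_panel(G)
  expect_warning(scan2 <- scan_population(panel, design), "skipped")
  expect_false("gone2" %in% scan2$snp_id)
  expect_identical(scan2$pvalue[scan2$snp_id == "mono"], 1)
  expect_identical(scan2$lrt[scan2$snp_id == "mono"], 0)
})

test_that("a strongly selected SNP planted among neutrals ranks first by p-value", {
  design <- fn_design()
  wins <- 0L
  for (seed in 1:5) {
    sim <- simulate_panel(sim_config(design, n_snps = 100,
                                     prop_selected = 0.01, s = 0.5,
                                     p0_law = c(0.2, 0.4), seed = seed))
    scan <- scan_population(sim$panel, design)
    planted <- sim$truth$snp_id[sim$truth$selected]
    ranked <- scan$snp_id[order(scan$pvalue)]
    if (ranked[1] %in% planted) wins <- wins + 1L
  }
  expect_gte(wins, 3L)
})

test_that("BH adjustment matches the textbook step-up on random and edge inputs", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(91)
  for (i in 1:5) {
    p <- runif(200)^2
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("signature calling applies the single-SNP and neighbour-pair rules", {
  scan <- tibble::tibble(
    snp_id = sprintf("m%02d", 1:12),
    scaffold = c(rep("scf1", 1), rep("scf2", 2), rep("scf3", 3),
                 rep("scf4", 3), rep("scf5", 2), "scf6"),
    pos = c(500L,                         # scf1: isolated strong single
            1000L, 1800L,                 # scf2: qualifying pair
            1000L, 2000L, 3000L,          # scf3: pair broken by interleaving
            1000L, 50000L, 51000L,        # scf4: single + pair, merged
            1000L, 150000L,               # scf5: two singles, too far to merge
            700L),                        # scf6: sub-threshold
    pvalue = c(5e-5,
               0.005, 0.008,
               0.005, 0.5, 0.005,
               1e-5, 0.001, 0.002,
               5e-5, 9e-5,
               0.02)
  )
  sig <- call_signatures(scan)
  expect_s3_class(sig, "selection_signatures")

  s1 <- sig[sig$scaffold == "scf1", ]
  expect_identical(nrow(s1), 1L)
  expect_identical(c(s1$start, s1$end), c(500L, 500L))
  expect_identical(s1$criterion, "single_p1")

  s2 <- sig[sig$scaffold == "scf2", ]
  expect_identical(s2$criterion, "pair_p2")
  expect_identical(s2$member_snps[[1]], c("m02", "m03"))

  expect_identical(nrow(sig[sig$scaffold == "scf3", ]), 0L)

  s4 <- sig[sig$scaffold == "scf4", ]
  expect_identical(nrow(s4), 1L)
  expect_identical(c(s4$start, s4$end), c(1000L, 51000L))
  expect_identical(s4$criterion, "single_p1")
  expect_identical(s4$n_snps, 3L)

  expect_identical(nrow(sig[sig$scaffold == "scf5", ]), 2L)
  expect_identical(nrow(sig[sig$scaffold == "scf6", ]), 0L)

  # no signature at all
  expect_identical(nrow(call_signatures(dplyr::mutate(scan, pvalue = 0.5))), 0L)
})

test_that("adjacent SNPs on different scaffolds never pair", {
  scan <- tibble::tibble(
    snp_id = c("a", "b"),
    scaffold = c("scf1", "scf2"),
    pos = c(999000L, 1000L),
    pvalue = c(0.005, 0.005)
  )
  expect_identical(nrow(call_signatures(scan)), 0L)
})

test_that("tightening thresholds never adds member SNPs and loses no candidate", {
  set.seed(92)
  scan <- tibble::tibble(
    snp_id = sprintf("x%03d", 1:300),
    scaffold = rep(sprintf("scf%d", 1:3), each = 100),
    pos = rep(cumsum(sample(500:20000, 100)), 3),
    pvalue = runif(300)^3
  )
  members <- function(p1, p2) {
    sig <- call_signatures(scan, p1 = p1, p2 = p2)
    sort(unique(unlist(sig$member_snps)))
  }
  lax <- members(1e-2, 5e-2)
  mid <- members(1e-3, 1e-2)
  tight <- members(1e-4, 1e-3)
  expect_true(all(tight %in% mid))
  expect_true(all(mid %in% lax))
  # completeness: every SNP below p1 is a member at that setting
  sig <- call_signatures(scan, p1 = 1e-3, p2 = 1e-2)
  got <- unique(unlist(sig$member_snps))
  expect_true(all(scan$snp_id[scan$pvalue < 1e-3] %in% got))
  # and every member satisfies one of the two rules
  expect_true(all(scan$pvalue[match(got, scan$snp_id)] < 1e-2))
})

test_that("gene annotation respects the 100 kb exclusive distance rule", {
  sig <- call_signatures(tibble::tibble(
    snp_id = "s", scaffold = "scf1", pos = 500000L, pvalue = 1e-6))
  genes <- tibble::tibble(
    gene_id = c("overlap", "touch", "at99999", "at100000", "elsewhere"),
    scaffold = c("scf1", "scf1", "scf1", "scf1", "scf9"),
    start = c(490000L, 500000L, 390001L, 390000L, 500000L),
    end = c(510000L, 500000L, 400001L, 400000L, 500000L)
  )
  ann <- annotate_genes(sig, genes)
  expect_setequal(ann$genes[[1]], c("overlap", "touch", "at99999"))

  # orthologue flag restricts the candidate pool
  genes$has_orthologue <- c(TRUE, FALSE, TRUE, TRUE, TRUE)
  ann2 <- annotate_genes(sig, genes)
  expect_setequal(ann2$genes[[1]], c("overlap", "at99999"))
})

test_that("end-to-end recall of planted sweeps is consistent with single-SNP power", {
  design <- fn_design()
  sim <- simulate_panel(sim_config(design, n_snps = 1000, prop_selected = 0.05,
                                   s = 0.5, seed = 93))
  scan <- scan_population(sim$panel, design)
  sig <- call_signatures(scan)
  planted <- sim$truth$snp_id[sim$truth$selected]
  members <- unique(unlist(sig$member_snps))
  recall <- mean(planted %in% members)
  p1_power <- glance(power_experiment(design, s = 0.5, alpha = 1e-4,
                                      n_reps = 500, seed = 94))$power
  # members include every SNP below the single-SNP threshold, so region
  # recall cannot fall below the per-SNP power at that threshold beyond
  # Monte-Carlo error on 50 planted SNPs
  expect_gte(recall, p1_power - 0.15)
})

test_that("scan summaries and plots carry the population context", {
  design <- fn_design()
  sim <- simulate_panel(sim_config(design, n_snps = 40, seed = 95))
  scan <- scan_population(sim$panel, design)
  g <- glance(scan)
  expect_identical(g$population, "FN")
  expect_identical(g$n_snp, nrow(scan))
  expect_s3_class(autoplot(scan), "ggplot")
  pw <- power_experiment(n_reps = 100, seed = 96)
  expect_s3_class(autoplot(pw), "ggplot")
})
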