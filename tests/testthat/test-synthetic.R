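test_that("generators are deterministic under the seed", {
  cfg <- sim_config(n_populations = 2, n_per_pop = 5, n_sites = 500,
                    admixed_n = 2, admixed_q = c(0.5, 0.5),
                    pop_labels = c("A", "B", "adm"), seed = 12)
  s1 <- simulate_admixed(simulate_populations(cfg))
  s2 <- simulate_admixed(simulate_populations(cfg))
  expect_identical(s1$matrix$calls, s2$matrix$calls)
  expect_identical(s1$matrix$sites, s2$matrix$sites)
  expect_identical(s1$truth$p_pop, s2$truth$p_pop)

  m1 <- simulate_mito(list(a = integer(0), b = 5), list(a = c(P = 2), b = c(P = 1)),
                      length_bp = 100, seed = 4)
  m2 <- simulate_mito(list(a = integer(0), b = 5), list(a = c(P = 2), b = c(P = 1)),
                      length_bp = 100, seed = 4)
  expect_identical(m1$sequences, m2$sequences)
})

test_that("F = 0 populations are panmictic and F = 0.2 is recovered", {
  sim0 <- simulate_populations(sim_config(n_populations = 2, n_per_pop = 20,
                                          fst_target = 0, n_sites = 8000,
                                          admixed_n = 0,
                                          pop_labels = c("A", "B"), seed = 1))
  expect_identical(sim0$truth$p_pop["A", ], sim0$truth$p_pop["B", ])
  f0 <- fst_windows(sim0$matrix, sim0$map, c("A", "B"))$overall_weighted_fst
  expect_lt(abs(f0), 0.01)

  sim2 <- simulate_populations(sim_config(n_populations = 2, n_per_pop = 20,
                                          fst_target = 0.2, n_sites = 8000,
                                          admixed_n = 0,
                                          pop_labels = c("A", "B"), seed = 2))
  f2 <- fst_windows(sim2$matrix, sim2$map, c("A", "B"))$overall_weighted_fst
  expect_lt(abs(f2 - 0.2), 0.02)
})

test_that("population ranking by pi follows simulated heterozygosity", {
  cfg <- sim_config(n_populations = 3, n_per_pop = 10,
                    fst_target = c(0.05, 0.2, 0.4), n_sites = 8000,
                    admixed_n = 0, pop_labels = c("lo", "mid", "hi"), seed = 3)
  sim <- simulate_populations(cfg)
  pi_hat <- vapply(c("lo", "mid", "hi"), function(p)
    pi_windows(sim$matrix, sim$map, p)$mean_pi, numeric(1))
  exp_het <- vapply(c("lo", "mid", "hi"), function(p)
    mean(2 * sim$truth$p_pop[p, ] * (1 - sim$truth$p_pop[p, ])), numeric(1))
  expect_identical(order(pi_hat), order(exp_het))
})

test_that("degenerate admixture matches its source; Q rows must sum to 1", {
  cfg <- sim_config(n_populations = 2, n_per_pop = 15, fst_target = 0.2,
                    n_sites = 6000, admixed_n = 8,
                    admixed_q = c(1, 0), pop_labels = c("A", "B", "adm"),
                    seed = 14)
  sim <- simulate_admixed(simulate_populations(cfg))
  f <- fst_windows(sim$matrix, sim$map, c("A", "adm"))$overall_weighted_fst
  expect_lt(abs(f), 0.01)
  expect_error(sim_config(admixed_q = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("degrade adds the requested missingness and dropout inflates F_ROH", {
  sim <- simulate_populations(sim_config(n_populations = 1, n_per_pop = 5,
                                         n_sites = 4000, admixed_n = 0,
                                         pop_labels = "A", seed = 15))
  gm <- degrade(sim$matrix, missing_rate = 0.1, seed = 6)
  frac <- mean(is.na(gm$calls))
  n <- length(gm$calls)
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / n))

  same <- degrade(sim$matrix, missing_rate = 0, seed = 6)
  expect_identical(same$calls, sim$matrix$calls)

  # allelic dropout turns hets into homs, raising called ROH burden
  cfg <- sim_config(n_populations = 1, n_per_pop = 2, fst_target = 0.05,
                    n_sites = 20000, scaffold_lengths = c(chr = 2e7),
                    admixed_n = 0, pop_labels = "A", seed = 16)
  dense <- simulate_populations(cfg)
  cov <- roh_coverage(dense$matrix)$min_kb_100$total_bp
  base_seg <- detect_roh(dense$matrix, "A_01")
  drop_seg <- detect_roh(degrade(dense$matrix, missing_rate = 0,
                                 dropout_rate = 0.9, seed = 7), "A_01")
  expect_gte(f_roh(drop_seg, cov, 100), f_roh(base_seg, cov, 100))
  expect_gt(f_roh(drop_seg, cov, 100), 0)
})

test_that("implant_roh validates tracts and produces homozygous stretches", {
  cfg <- sim_config(n_populations = 1, n_per_pop = 3, n_sites = 3000,
                    scaffold_lengths = c(chr = 1e7), admixed_n = 0,
                    pop_labels = "A", seed = 17)
  sim <- simulate_populations(cfg)
  expect_error(implant_roh(sim, "A_01",
                           data.frame(scaffold = "chr",
                                      start = c(1e6, 1.2e6),
                                      end = c(1.5e6, 1.7e6))), "overlap")
  expect_error(implant_roh(sim, "A_01",
                           data.frame(scaffold = "chr", start = 9e6,
                                      end = 1.2e7)), "bounds")
  sim <- implant_roh(sim, "A_01",
                     data.frame(scaffold = "chr", start = 2e6, end = 4e6),
                     het_error_rate = 0, seed = 18)
  inside <- sim$matrix$sites$pos >= 2e6 & sim$matrix$sites$pos <= 4e6
  expect_true(all(sim$matrix$calls["A_01", inside] != 1L))
  expect_equal(sim$truth$roh_tracts$A_01$start, 2e6)
})

test_that("mitochondrial simulator reproduces the distance spec and VCF round-trips", {
  subs <- list(h1 = integer(0), h2 = 10, h3 = 20, h4 = c(30, 40), h5 = c(50, 60, 70))
  carriers <- list(h1 = c(P1 = 3), h2 = c(P1 = 1), h3 = c(P2 = 2),
                   h4 = c(P2 = 1), h5 = c(P3 = 2))
  sim <- simulate_mito(subs, carriers, length_bp = 200, seed = 5)
  hs <- collapse_haplotypes(sim$sequences, sim$map)
  expect_equal(length(hs$haplotypes), 5)
  expect_equal(hs$n_segregating, 7)
  h <- vapply(names(subs), function(n)
    sim$sequences[[grep(paste0("_", n, "_"), names(sim$sequences))[1]]],
    character(1))
  expect_equal(hamming_distance(h["h1"], h["h2"]), 1)
  expect_equal(hamming_distance(h["h1"], h["h5"]), 3)
  expect_equal(hamming_distance(h["h4"], h["h5"]), 5)
  expect_error(simulate_mito(list(a = c(5, 5)), list(a = c(P = 1))), "duplicate")

  # simulated genotypes survive a VCF round-trip losslessly
  gm <- simulate_populations(sim_config(n_populations = 1, n_per_pop = 4,
                                        n_sites = 300, admixed_n = 0,
                                        pop_labels = "A", seed = 19))$matrix
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  expect_identical(unname(read_vcf(path)$calls), unname(gm$calls))
})
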