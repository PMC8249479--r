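test_that("per-site pi equals the pairwise-difference fraction", {
  # 4 diploids with allele counts 4/4: all C(8,2)=28 allele pairs, 16 differ
  gm <- toy_matrix(matrix(c(1L, 1L, 1L, 1L), 4, 1))
  map <- toy_map(gm, "P")
  expect_equal(pi_site(gm, map, "P"), 16 / 28)

  # 10 diploids with counts 19/1
  calls <- matrix(2L, 10, 1); calls[1, 1] <- 1L
  gm <- toy_matrix(calls)
  expect_equal(pi_site(gm, toy_map(gm, "P"), "P"), 19 / 190)

  # monomorphic -> 0; single called allele -> NA
  gm <- toy_matrix(matrix(c(0L, 0L, NA, NA), 2, 2))
  map <- toy_map(gm, "P")
  expect_equal(pi_site(gm, map, "P"), c(0, NA))
})

test_that("pi is invariant under allele-label swap and maximal at balance", {
  set.seed(3)
  calls <- matrix(sample(c(0:2, NA), 400, replace = TRUE, prob = c(.3, .3, .3, .1)),
                  20, 20)
  gm1 <- toy_matrix(calls); gm2 <- toy_matrix(2L - calls)
  map <- toy_map(gm1, "P")
  expect_equal(pi_site(gm1, map, "P"), pi_site(gm2, toy_map(gm2, "P"), "P"))

  # balanced counts maximize c_ref * c_alt for fixed n
  balanced <- toy_matrix(matrix(1L, 10, 1))
  for (nalt in c(2, 5, 8, 15)) {
    calls <- matrix(0L, 10, 1)
    calls[seq_len(ceiling(nalt / 2)), 1] <- 2L
    if (nalt %% 2) calls[ceiling(nalt / 2), 1] <- 1L
    gm <- toy_matrix(calls)
    expect_lte(pi_site(gm, toy_map(gm, "P"), "P"),
               pi_site(balanced, toy_map(balanced, "P"), "P"))
  }
})

test_that("windowed pi tiles from position 1 and averages occupied windows only", {
  calls <- matrix(c(1L, 1L, 1L, 1L), 4, 2)
  gm <- toy_matrix(calls, pos = c(5000, 25000), scaffold_len = 40000)
  map <- toy_map(gm, "P")
  pw <- pi_windows(gm, map, "P", window_bp = 10000)
  expect_equal(nrow(pw$windows), 2)           # windows 1 and 3; window 2 absent
  expect_equal(pw$windows$start, c(1, 20001))
  expect_equal(pw$windows$pi, rep((16 / 28) / 10000, 2))
  expect_equal(pw$mean_pi, (16 / 28) / 10000)
})

test_that("windowed pi matches the simulated expected heterozygosity", {
  cfg <- sim_config(n_populations = 1, n_per_pop = 20, fst_target = 0.2,
                    n_sites = 20000, admixed_n = 0, pop_labels = "A",
                    seed = 21)
  sim <- simulate_populations(cfg)
  pw <- pi_windows(sim$matrix, sim$map, "A")
  p <- sim$truth$p_pop["A", ]
  expected <- sum(2 * p * (1 - p)) / (10000 * nrow(pw$windows))
  expect_lt(abs(pw$mean_pi - expected) / expected, 0.1)
})

test_that("heterozygosity proportion uses the joint denominator", {
  calls <- rbind(rep(1L, 5), rep(0L, 5), c(1L, 1L, NA, NA, NA))
  gm <- toy_matrix(cbind(calls, matrix(0L, 3, 15)))
  H <- heterozygosity_proportion(gm)
  expect_equal(unname(H), c(5 / 20, 0, 2 / 20))
  Hc <- heterozygosity_proportion(gm, denominator = "called")
  expect_equal(unname(Hc[3]), 2 / 17)
  expect_error(heterozygosity_proportion(gm_subset(gm, sites = integer(0))),
               "empty")
})

test_that("polymorphic proportion counts sites segregating within the population", {
  calls <- rbind(c(rep(1L, 3), rep(0L, 7)),   # pop A sample
                 c(rep(1L, 3), rep(0L, 7)),
                 rep(2L, 10), rep(0L, 10))    # pop B fixed everywhere... per site
  gm <- toy_matrix(calls)
  map <- pop_map(gm$samples, c("A", "A", "B", "B"))
  expect_equal(polymorphic_proportion(gm, map, "A"), 0.3)
  expect_equal(polymorphic_proportion(gm, map, "B"), 1)  # 2 vs 0 segregates
  mapAA <- pop_map(gm$samples, c("A", "A", "C", "C"))
  gm0 <- gm_subset(gm, samples = c("S03", "S04"))
  gm0$calls[2, ] <- 2L
  expect_equal(polymorphic_proportion(gm0, pop_map(gm0$samples, "C"), "C"), 0)
})

test_that("subsampling never creates polymorphism absent from the full population", {
  sim <- simulate_populations(sim_config(n_populations = 1, n_per_pop = 12,
                                         n_sites = 2000, admixed_n = 0,
                                         pop_labels = "A", seed = 31))
  full_poly <- pi_site(sim$matrix, sim$map, "A") > 0
  set.seed(1)
  for (i in 1:5) {
    ids <- sample(sim$matrix$samples, 6)
    sub <- gm_subset(sim$matrix, samples = ids)
    sub_poly <- pi_site(sub, pop_map(ids, "A"), "A") > 0
    expect_true(all(which(sub_poly) %in% which(full_poly)))
  }
})

test_that("equal-n resampling is seed-deterministic and degenerate at full size", {
  sim <- simulate_populations(sim_config(n_populations = 2, n_per_pop = 8,
                                         n_sites = 1500, admixed_n = 0,
                                         pop_labels = c("A", "B"), seed = 41))
  r1 <- resample_equal_n(sim$matrix, sim$map, n_per_pop = 6, n_reps = 10,
                         statistic = "H", seed = 99)
  r2 <- resample_equal_n(sim$matrix, sim$map, n_per_pop = 6, n_reps = 10,
                         statistic = "H", seed = 99)
  expect_identical(attr(r1, "replicates"), attr(r2, "replicates"))

  # n_per_pop = population size: every replicate equals the full statistic
  rfull <- resample_equal_n(sim$matrix, sim$map, n_per_pop = 8, n_reps = 5,
                            statistic = "H", seed = 1)
  H <- heterozygosity_proportion(sim$matrix)
  for (p in c("A", "B")) {
    ids <- pop_samples(sim$map, p)
    expect_equal(rfull$mean[rfull$population == p], mean(H[ids]))
    expect_equal(rfull$sd[rfull$population == p], 0)
  }
  expect_error(resample_equal_n(sim$matrix, sim$map, n_per_pop = 9,
                                n_reps = 2, statistic = "H"), "fewer")

  # resampled mean of H consistent with full-sample H
  rH <- resample_equal_n(sim$matrix, sim$map, n_per_pop = 6, n_reps = 30,
                         statistic = "H", seed = 7)
  for (p in c("A", "B")) {
    ids <- pop_samples(sim$map, p)
    expect_lt(abs(rH$mean[rH$population == p] - mean(H[ids])),
              2 * max(rH$sd[rH$population == p], 1e-6) + 2 * sd(H[ids]))
  }
})
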