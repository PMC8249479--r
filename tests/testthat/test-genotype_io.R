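test_that("VCF genotypes encode to dosages, with any '.' component missing", {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=s1,length=100000>",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="d">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("S", 1:5)), collapse = "\t"),
    paste("s1", "100", ".", "A", "C", "50", ".", "DP=600", "GT",
          "0/0", "0/1", "1/1", "./.", "0|1", sep = "\t"),
    paste("s1", "200", ".", "G", "T", "50", ".", "DP=600", "GT",
          "0/0", "./1", "1/.", "0/0", "0/0", sep = "\t")
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(lines, path)
  gm <- read_vcf(path)
  expect_equal(unname(gm$calls[, 1]), c(0L, 1L, 2L, NA, 1L))
  expect_equal(unname(gm$calls[, 2]), c(0L, NA, NA, 0L, 0L))
  expect_equal(gm$scaffold_lengths[["s1"]], 100000)
  expect_equal(gm$sites$depth, c(600, 600))
})

test_that("only biallelic SNP records are loaded", {
  recs <- c(
    paste("s1", "100", ".", "A", "C", "50", ".", "DP=1", "GT", "0/0", sep = "\t"),
    paste("s1", "200", ".", "A", "C,G", "50", ".", "DP=1", "GT", "0/0", sep = "\t"),
    paste("s1", "300", ".", "AT", "A", "50", ".", "DP=1", "GT", "0/0", sep = "\t"),
    paste("s1", "400", ".", "G", "T", "50", ".", "DP=1", "GT", "1/1", sep = "\t"),
    paste("s1", "500", ".", "C", "CAA", "50", ".", "DP=1", "GT", "0/0", sep = "\t")
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "##contig=<ID=s1,length=1000>",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "S1"), collapse = "\t"), recs), path)
  gm <- read_vcf(path)
  expect_equal(nrow(gm$sites), 2)
  expect_equal(gm$sites$pos, c(100, 400))
})

test_that("write/read round-trip preserves calls, coordinates and annotations", {
  set.seed(7)
  sim <- simulate_populations(sim_config(n_populations = 2, n_per_pop = 4,
                                         n_sites = 200, admixed_n = 0,
                                         pop_labels = c("A", "B"), seed = 7))
  gm <- degrade(sim$matrix, missing_rate = 0.1, seed = 7)
  gm$sites$QD <- round(runif(200, 0, 40), 2)
  gm$sites$QUAL <- round(runif(200, 0, 2000), 1)
  gm$sites$MQRankSum <- round(rnorm(200), 3)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  back <- read_vcf(path)
  expect_identical(unname(back$calls), unname(gm$calls))
  expect_equal(back$sites$pos, gm$sites$pos)
  expect_equal(back$sites$scaffold, gm$sites$scaffold)
  expect_equal(back$sites$QD, gm$sites$QD)
  expect_equal(back$sites$QUAL, gm$sites$QUAL)
  expect_equal(back$sites$MQRankSum, gm$sites$MQRankSum)
  expect_equal(back$scaffold_lengths[names(gm$scaffold_lengths)],
               gm$scaffold_lengths)
})

test_that("empty site list writes a header-only VCF; contig lines per scaffold", {
  gm <- toy_matrix(matrix(0L, 2, 3), pos = c(10, 20, 30))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  txt <- readLines(path)
  expect_equal(sum(grepl("^##contig", txt)), 1)
  expect_equal(sum(!grepl("^#", txt)), 3)

  empty <- gm_subset(gm, sites = integer(0))
  write_vcf(empty, path)
  txt <- readLines(path)
  expect_true(all(grepl("^#", txt)))
})

test_that("site ordering after read is strictly increasing within scaffold", {
  sim <- simulate_populations(sim_config(n_populations = 1, n_per_pop = 3,
                                         n_sites = 300, admixed_n = 0,
                                         pop_labels = "A", seed = 3))
  s <- sim$matrix$sites
  for (sc in unique(s$scaffold))
    expect_false(is.unsorted(s$pos[s$scaffold == sc], strictly = TRUE))
})

test_that("population map reads the study layout and rejects duplicates", {
  path <- withr::local_tempfile(fileext = ".txt")
  samples <- c(sprintf("bav%02d", 1:20), sprintf("ema%02d", 1:20),
               sprintf("moc%02d", 1:20), sprintf("hel%02d", 1:6))
  pops <- rep(c("Baven", "Eman", "Mockeln", "HelgeA"), c(20, 20, 20, 6))
  writeLines(paste(samples, pops), path)
  map <- read_population_map(path)
  counts <- table(as.vector(map))
  expect_equal(as.vector(counts[c("Baven", "Eman", "Mockeln", "HelgeA")]),
               c(20L, 20L, 20L, 6L))

  writeLines(c("a P1", "a P2"), path)
  expect_error(read_population_map(path), "duplicate")
  writeLines(character(0), path)
  expect_error(read_population_map(path))
})

test_that("BED mask intervals merge and invalid intervals error", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("s1\t0\t100", "s1\t50\t150", "s2\t10\t20"), path)
  mask <- read_mask_bed(path)
  expect_equal(mask$start[mask$scaffold == "s1"], 0)
  expect_equal(mask$end[mask$scaffold == "s1"], 150)
  expect_equal(nrow(mask), 2)

  writeLines("s1\t100\t100", path)
  expect_error(read_mask_bed(path), "end")

  writeLines(character(0), path)
  expect_equal(nrow(read_mask_bed(path)), 0)
})

test_that("mask lookup is half-open: pos p excluded iff start <= p-1 < end", {
  mask <- genomic_mask(data.frame(scaffold = "s1", start = 100, end = 200))
  gm <- toy_matrix(matrix(0:2, 3, 4), pos = c(100, 101, 200, 201),
                   scaffold_len = 1000)
  res <- apply_site_filters(gm, mask, maf_min = 0, call_rate_min = 0,
                            min_scaffold_bp = 0)
  # pos 100 -> 99 not in [100,200); pos 101 -> 100 in; pos 200 -> 199 in;
  # pos 201 -> 200 out
  expect_equal(res$matrix$sites$pos, c(100, 201))
})
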