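# small fixture builders used across test files

# genotype matrix from a plain integer matrix (samples x sites), one scaffold
toy_matrix <- function(calls, pos = NULL, scaffold = "s1",
                       scaffold_len = NULL, depth = 500) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  if (is.null(scaffold_len)) scaffold_len <- max(pos) + 1000
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("S%02d", seq_len(nrow(calls)))
  genotype_matrix(
    calls,
    sites = data.frame(scaffold = scaffold, pos = pos, ref = "A", alt = "C",
                       depth = depth),
    scaffold_lengths = stats::setNames(scaffold_len, scaffold[1]))
}

toy_map <- function(matrix, pops) pop_map(matrix$samples, pops)

# random toy chromosome for ROH testing: genotype vector with hom runs,
# scattered hets and missing calls
random_roh_fixture <- function(n_snps, seed) {
  set.seed(seed)
  g <- integer(n_snps)
  i <- 1L
  while (i <= n_snps) {
    run <- sample(c(5L, 20L, 60L, 150L), 1)
    type <- sample(c("hom", "mixed"), 1, prob = c(0.6, 0.4))
    j <- min(i + run - 1L, n_snps)
    seg <- if (type == "hom") {
      s <- sample(c(0L, 2L), j - i + 1L, replace = TRUE)
      # sprinkle rare hets/missing inside hom stretches
      k <- j - i + 1L
      s[runif(k) < 0.01] <- 1L
      s
    } else sample(c(0L, 1L, 2L), j - i + 1L, replace = TRUE,
                  prob = c(0.35, 0.3, 0.35))
    g[i:j] <- seg
    i <- j + 1L
  }
  g[runif(n_snps) < 0.03] <- NA_integer_
  pos <- sort(sample.int(n_snps * 3000, n_snps))
  list(g = g, pos = pos)
}
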