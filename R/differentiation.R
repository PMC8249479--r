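#' @name differentiation
#' @title Weir-Cockerham F_ST
#' @description
#' Two-population differentiation via the Weir & Cockerham (1984) variance
#' components: `a` (among populations), `b` (among individuals within
#' populations) and `c` (within individuals, i.e. observed heterozygosity).
#' The per-site estimate is `a / (a + b + c)`; a window's "weighted" value is
#' the ratio of sums over its informative sites; the genome-wide summary is
#' either the unweighted mean of windowed values (default) or a single
#' ratio-of-sums over all sites.
NULL

#' Weir-Cockerham variance components per site for a population pair
#'
#' Components are computed with r = 2 populations from per-population sample
#' sizes (individuals with non-missing genotype at the site), alt-allele
#' frequencies and observed heterozygote fractions. Sites where either
#' population has no called individual, or where the pooled sample is
#' monomorphic, are non-informative and return `(0, 0, 0)` with
#' `informative = FALSE`.
#'
#' @param matrix a [genotype_matrix()].
#' @param map a [pop_map()].
#' @param pop_pair character vector of two population labels.
#' @return data.frame with per-site columns `a`, `b`, `c`, `informative`,
#'   and `fst` (`a/(a+b+c)`, NA when non-informative).
#' @export
wc_fst_site <- function(matrix, map, pop_pair) {
  stopifnot(length(pop_pair) == 2L)
  ac1 <- pop_allele_counts(matrix, map, pop_pair[1])
  ac2 <- pop_allele_counts(matrix, map, pop_pair[2])
  calls1 <- matrix$calls[pop_samples(map, pop_pair[1], matrix), , drop = FALSE]
  calls2 <- matrix$calls[pop_samples(map, pop_pair[2], matrix), , drop = FALSE]

  n1 <- ac1$n / 2; n2 <- ac2$n / 2                 # called individuals
  p1 <- ifelse(n1 > 0, ac1$alt / ac1$n, NA)
  p2 <- ifelse(n2 > 0, ac2$alt / ac2$n, NA)
  h1 <- ifelse(n1 > 0, colSums(calls1 == 1L, na.rm = TRUE) / n1, NA)
  h2 <- ifelse(n2 > 0, colSums(calls2 == 1L, na.rm = TRUE) / n2, NA)

  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  c <- hbar / 2

  informative <- n1 > 0 & n2 > 0 & nbar > 1 &
    is.finite(pbar) & pbar > 0 & pbar < 1
  a[!informative] <- 0; b[!informative] <- 0; c[!informative] <- 0
  tot <- a + b + c
  data.frame(a = a, b = b, c = c, informative = informative,
             fst = ifelse(informative & tot != 0, a / tot, NA_real_))
}

#' Windowed Weir-Cockerham F_ST for a population pair
#'
#' Non-overlapping windows tile each scaffold from position 1. A window's
#' value is the weighted (ratio-of-sums) estimate
#' `sum(a) / sum(a + b + c)` over its informative sites. Negative estimates
#' are retained. The genome-wide summary is the unweighted mean over windows
#' with at least one informative site (`mean_fst`); the pooled single
#' ratio-of-sums over all informative sites is also returned
#' (`overall_weighted_fst`), matching the two figures VCFtools prints.
#'
#' @param matrix a [genotype_matrix()].
#' @param map a [pop_map()].
#' @param pop_pair two population labels.
#' @param window_bp window size in bp (default 10000).
#' @return `list(windows, mean_fst, overall_weighted_fst)`.
#' @export
fst_windows <- function(matrix, map, pop_pair, window_bp = 10000) {
  comp <- wc_fst_site(matrix, map, pop_pair)
  s <- matrix$sites
  win <- window_index(s$pos, window_bp)
  key <- paste(s$scaffold, win, sep = "\r")
  agg <- rowsum(cbind(a = comp$a, tot = comp$a + comp$b + comp$c,
                      inf = as.numeric(comp$informative)), key)
  first <- !duplicated(key)
  ord <- which(first)
  k <- key[first]
  windows <- data.frame(
    scaffold = s$scaffold[ord],
    start = (win[ord] - 1) * window_bp + 1,
    end = win[ord] * window_bp,
    n_informative = as.integer(agg[k, "inf"]),
    fst = ifelse(agg[k, "inf"] > 0 & agg[k, "tot"] != 0,
                 agg[k, "a"] / agg[k, "tot"], NA_real_),
    stringsAsFactors = FALSE
  )
  rownames(windows) <- NULL
  ok <- windows$n_informative > 0 & !is.na(windows$fst)
  list(windows = windows,
       mean_fst = if (any(ok)) mean(windows$fst[ok]) else NA_real_,
       overall_weighted_fst = {
         inf <- comp$informative
         tot <- sum(comp$a[inf] + comp$b[inf] + comp$c[inf])
         if (tot != 0) sum(comp$a[inf]) / tot else NA_real_
       })
}

#' Random-subsampling null for within-population substructure
#'
#' Tests whether an observed two-way split of one population (e.g. the
#' subgroups an admixture fit suggests) is more differentiated than chance:
#' the population is repeatedly split at random into two groups of the same
#' sizes as the observed split, windowed weighted F_ST is computed for each
#' random split, and the observed value is located within that null
#' distribution.
#'
#' @param matrix a [genotype_matrix()].
#' @param map a [pop_map()].
#' @param population population to split.
#' @param observed_split character vector of sample ids forming one side of
#'   the observed split (the rest of the population forms the other side).
#' @param n_iter number of random splits (default 100).
#' @param seed integer seed.
#' @param window_bp window size for the F_ST estimate.
#' @return `list(observed_fst, null_fst (length n_iter), quantile)` where
#'   `quantile` is the empirical fraction of null values <= observed.
#' @export
substructure_null <- function(matrix, map, population, observed_split,
                              n_iter = 100, seed = 1, window_bp = 10000) {
  ids <- pop_samples(map, population, matrix)
  if (!all(observed_split %in% ids))
    stop("observed_split contains samples outside population ", population)
  side2 <- setdiff(ids, observed_split)
  if (!length(observed_split) || !length(side2))
    stop("observed_split must be a proper, non-empty subset of the population")

  split_fst <- function(g1) {
    g2 <- setdiff(ids, g1)
    m <- pop_map(c(g1, g2), rep(c("g1", "g2"), c(length(g1), length(g2))))
    fst_windows(gm_subset(matrix, samples = c(g1, g2)), m,
                c("g1", "g2"), window_bp)$mean_fst
  }

  observed <- split_fst(observed_split)
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max, n_iter)
  null <- vapply(seq_len(n_iter), function(i) {
    set.seed(iter_seeds[i])
    split_fst(sample(ids, length(observed_split)))
  }, numeric(1))
  list(observed_fst = observed, null_fst = null,
       quantile = mean(null <= observed))
}
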