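#' @name diversity
#' @title Diversity statistics
#' @description
#' Three statistics summarise within-population variation: windowed
#' nucleotide diversity pi (mean pairwise difference per bp), per-individual
#' heterozygosity proportion H (heterozygous sites over the joint SNP set),
#' and the proportion of polymorphic sites P (sites segregating within a
#' population over the joint SNP set). H and P deliberately share the joint
#' denominator so values are comparable across populations. An equal-sample-
#' size resampling correction removes the sample-size dependence of all
#' three.
NULL

# per-population allele counts at every site: list(alt, n_alleles)
pop_allele_counts <- function(matrix, map, population) {
  ids <- pop_samples(map, population, matrix)
  calls <- matrix$calls[ids, , drop = FALSE]
  list(alt = colSums(calls, na.rm = TRUE),
       n = 2L * colSums(!is.na(calls)))
}

#' Per-site nucleotide diversity within a population
#'
#' For a site with `c_ref` reference and `c_alt` alternate alleles among the
#' population's non-missing calls (`n = c_ref + c_alt`), pi is the fraction
#' of the `choose(n, 2)` allele pairs that differ:
#' `pi = c_ref * c_alt / choose(n, 2)`. Sites with fewer than two called
#' alleles are undefined (`NA`).
#'
#' @param matrix a [genotype_matrix()].
#' @param map a [pop_map()].
#' @param population population label.
#' @return Numeric vector, one pi per site (NA where < 2 alleles called).
#' @export
pi_site <- function(matrix, map, population) {
  ac <- pop_allele_counts(matrix, map, population)
  out <- ifelse(ac$n >= 2,
                ac$alt * (ac$n - ac$alt) / choose(ac$n, 2),
                NA_real_)
  as.numeric(out)
}

# assign each site to a window: windows tile scaffolds from position 1 in
# non-overlapping window_bp steps; window k covers [(k-1)*w + 1, k*w]
window_index <- function(pos, window_bp) ceiling(pos / window_bp)

#' Windowed nucleotide diversity
#'
#' Scaffolds are tiled from position 1 with non-overlapping windows of
#' `window_bp`. A window's value is the sum of per-site pi over SNPs in the
#' window divided by the full window length (per-bp units; monomorphic SNPs
#' contribute 0, positions without a SNP contribute 0 implicitly). The
#' genome-wide value is the unweighted mean over windows containing at least
#' one SNP; windows with no SNPs are unobservable from a SNP-only input and
#' are excluded.
#'
#' @param matrix a [genotype_matrix()].
#' @param map a [pop_map()].
#' @param population population label.
#' @param window_bp window size in bp (default 10000).
#' @return `list(windows = <data.frame scaffold,start,end,n_snps,pi>,
#'   mean_pi = <genome-wide per-bp mean>)`.
#' @export
pi_windows <- function(matrix, map, population, window_bp = 10000) {
  ps <- pi_site(matrix, map, population)
  ps[is.na(ps)] <- 0
  s <- matrix$sites
  win <- window_index(s$pos, window_bp)
  key <- paste(s$scaffold, win, sep = "\r")
  agg <- rowsum(cbind(pi = ps, n = 1), key)
  first <- !duplicated(key)
  ord <- which(first)
  k <- key[first]
  windows <- data.frame(
    scaffold = s$scaffold[ord],
    start = (win[ord] - 1) * window_bp + 1,
    end = win[ord] * window_bp,
    n_snps = as.integer(agg[k, "n"]),
    pi = agg[k, "pi"] / window_bp,
    stringsAsFactors = FALSE
  )
  rownames(windows) <- NULL
  list(windows = windows,
       mean_pi = if (nrow(windows)) mean(windows$pi) else NA_real_)
}

#' Per-individual heterozygosity proportion
#'
#' The number of heterozygous calls divided by the total number of SNP sites
#' in the (joint, all-population) matrix. By default missing sites stay in
#' the denominator, mirroring a fixed joint SNP count; set
#' `denominator = "called"` to divide by the individual's non-missing sites
#' instead.
#'
#' @param matrix a [genotype_matrix()] holding the joint SNP set.
#' @param samples sample ids (default all).
#' @param denominator `"all"` (joint SNP count, default) or `"called"`.
#' @return Named numeric vector of H per sample.
#' @export
heterozygosity_proportion <- function(matrix, samples = matrix$samples,
                                      denominator = c("all", "called")) {
  denominator <- match.arg(denominator)
  if (!nrow(matrix$sites)) stop("empty matrix: H is undefined")
  calls <- matrix$calls[samples, , drop = FALSE]
  het <- rowSums(calls == 1L, na.rm = TRUE)
  den <- if (denominator == "all") nrow(matrix$sites) else rowSums(!is.na(calls))
  stats::setNames(het / den, samples)
}

#' Proportion of polymorphic sites within a population
#'
#' The number of joint-SNP-set sites at which the population carries both
#' alleles (per-site pi > 0), divided by the total number of sites in the
#' joint set.
#'
#' @param matrix a [genotype_matrix()] holding the joint SNP set.
#' @param map a [pop_map()].
#' @param population population label.
#' @return Scalar proportion in [0, 1].
#' @export
polymorphic_proportion <- function(matrix, map, population) {
  if (!nrow(matrix$sites)) return(NA_real_)
  ps <- pi_site(matrix, map, population)
  sum(ps > 0, na.rm = TRUE) / nrow(matrix$sites)
}

#' Diversity summary for every population
#'
#' @param matrix joint-SNP-set [genotype_matrix()].
#' @param map a [pop_map()].
#' @param window_bp pi window size.
#' @return data.frame with one row per population: mean per-bp pi, mean H
#'   (and sd across individuals), P, and sample size.
#' @export
diversity_summary <- function(matrix, map, window_bp = 10000) {
  H <- heterozygosity_proportion(matrix)
  pops <- unique(as.vector(map))
  do.call(rbind, lapply(pops, function(p) {
    ids <- pop_samples(map, p, matrix)
    data.frame(population = p, n = length(ids),
               pi = pi_windows(matrix, map, p, window_bp)$mean_pi,
               H_mean = mean(H[ids]),
               H_sd = if (length(ids) > 1) stats::sd(H[ids]) else NA_real_,
               P = polymorphic_proportion(matrix, map, p),
               n_snps_joint = nrow(matrix$sites),
               stringsAsFactors = FALSE)
  }))
}

#' Equal-sample-size resampling of a diversity statistic
#'
#' Repeatedly draws `n_per_pop` individuals without replacement from each
#' listed population, rebuilds the joint matrix from the drawn individuals
#' only (so H/P denominators come from the subsetted joint SNP set), and
#' recomputes the statistic. Replicate seeds derive from the single user
#' seed, so runs are reproducible.
#'
#' @param matrix joint [genotype_matrix()].
#' @param map a [pop_map()].
#' @param populations populations to resample (default: all in `map`).
#' @param n_per_pop individuals drawn per population (default 6).
#' @param n_reps number of resampling replicates (default 100).
#' @param statistic `"pi"`, `"H"` or `"P"`.
#' @param seed integer seed.
#' @param window_bp pi window size.
#' @return data.frame per population with replicate mean, sd, and the matrix
#'   of per-replicate values as attribute `"replicates"`.
#' @export
resample_equal_n <- function(matrix, map, populations = unique(as.vector(map)),
                             n_per_pop = 6, n_reps = 100,
                             statistic = c("pi", "H", "P"), seed = 1,
                             window_bp = 10000) {
  statistic <- match.arg(statistic)
  for (p in populations)
    if (length(pop_samples(map, p, matrix)) < n_per_pop)
      stop("population ", p, " has fewer than ", n_per_pop, " samples")
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  vals <- matrix(NA_real_, nrow = n_reps, ncol = length(populations),
                 dimnames = list(NULL, populations))
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    drawn <- unlist(lapply(populations, function(p) {
      ids <- pop_samples(map, p, matrix)
      sample(ids, n_per_pop)
    }))
    sub <- gm_subset(matrix, samples = drawn)
    submap <- pop_map(drawn, as.vector(map[drawn]))
    vals[r, ] <- vapply(populations, function(p) {
      switch(statistic,
             pi = pi_windows(sub, submap, p, window_bp)$mean_pi,
             H = mean(heterozygosity_proportion(sub,
                                                pop_samples(submap, p, sub))),
             P = polymorphic_proportion(sub, submap, p))
    }, numeric(1))
  }
  out <- data.frame(population = populations,
                    statistic = statistic,
                    mean = colMeans(vals),
                    sd = apply(vals, 2, stats::sd),
                    n_per_pop = n_per_pop, n_reps = n_reps, seed = seed,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "replicates") <- vals
  out
}
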