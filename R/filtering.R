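#' @name filtering
#' @title SNP filtering cascade
#' @description
#' Each filter takes a [genotype_matrix()] and returns
#' `list(matrix = <filtered>, report = <filter_report>)`. Reports carry the
#' step name, parameters, and before/removed/after site counts, and telescope
#' across a cascade (`before - removed == after`, and one step's `after` is
#' the next step's `before`). The canonical order used by [run_native_arm()]
#' is: hard filters, depth, mask, MAF, call rate, scaffold length.
NULL

filter_report <- function(step, before, after, params = list()) {
  structure(
    data.frame(step = step, before = before, removed = before - after,
               after = after, params = I(list(params)),
               stringsAsFactors = FALSE),
    class = c("filter_report", "data.frame"))
}

#' Combine per-step filter reports into one cascade report
#' @param ... `filter_report` rows (or lists holding `$report`).
#' @return A `filter_report` data.frame with one row per step.
#' @export
bind_reports <- function(...) {
  parts <- lapply(list(...), function(x) if (!is.null(x$report)) x$report else x)
  out <- do.call(rbind, parts)
  class(out) <- c("filter_report", "data.frame")
  out
}

#' GATK-style hard filters on site annotations
#'
#' A site is retained iff every annotation that is *present* satisfies its
#' inequality; absent annotations pass by convention (the rank-sum
#' annotations are undefined at sites with no heterozygote, and dropping such
#' sites would discard fixed differences).
#'
#' @param matrix a [genotype_matrix()].
#' @param thresholds named list of cutoffs; defaults follow GATK Best
#'   Practices for SNPs: QD > 2, QUAL > 30, SOR < 3, FS < 60, MQ > 40,
#'   MQRankSum > -12.5, ReadPosRankSum > -8.0.
#' @return `list(matrix, report)`.
#' @export
apply_hard_filters <- function(matrix,
                               thresholds = list(QD = 2, QUAL = 30, SOR = 3,
                                                 FS = 60, MQ = 40,
                                                 MQRankSum = -12.5,
                                                 ReadPosRankSum = -8.0)) {
  s <- matrix$sites
  pass_gt <- function(x, cut) is.na(x) | x > cut   # keep if value exceeds cut
  pass_lt <- function(x, cut) is.na(x) | x < cut   # keep if value below cut
  keep <- pass_gt(s$QD, thresholds$QD) &
    pass_gt(s$QUAL, thresholds$QUAL) &
    pass_lt(s$SOR, thresholds$SOR) &
    pass_lt(s$FS, thresholds$FS) &
    pass_gt(s$MQ, thresholds$MQ) &
    pass_gt(s$MQRankSum, thresholds$MQRankSum) &
    pass_gt(s$ReadPosRankSum, thresholds$ReadPosRankSum)
  list(matrix = gm_subset(matrix, sites = keep),
       report = filter_report("hard_filters", nrow(s), sum(keep), thresholds))
}

#' Aggregate-depth filter bounds from mean per-sample coverage
#'
#' The aggregate mean depth is `A = mean_coverage * n_samples`; sites are
#' later excluded when their summed depth is below one third or above double
#' of `A`. Bounds are rounded to the nearest integer.
#'
#' @param mean_coverage mean mapped coverage per sample (x).
#' @param n_samples number of samples contributing to aggregate depth.
#' @return `list(min_depth, max_depth)` of class `depth_thresholds`.
#' @examples
#' compute_depth_thresholds(16.9, 60)  # min 338, max 2028
#' @export
compute_depth_thresholds <- function(mean_coverage, n_samples) {
  if (mean_coverage <= 0) stop("mean coverage must be positive")
  if (n_samples < 1) stop("need at least one sample")
  a <- mean_coverage * n_samples
  structure(list(min_depth = round(a / 3), max_depth = round(2 * a)),
            class = "depth_thresholds")
}

#' Filter sites on aggregate read depth
#'
#' @param matrix a [genotype_matrix()].
#' @param thresholds a `depth_thresholds` (or list with `min_depth`,
#'   `max_depth`). Bounds are inclusive.
#' @return `list(matrix, report)`.
#' @export
apply_depth_filter <- function(matrix, thresholds) {
  if (thresholds$min_depth >= thresholds$max_depth)
    stop("min_depth must be below max_depth")
  d <- matrix$sites$depth
  keep <- d >= thresholds$min_depth & d <= thresholds$max_depth
  list(matrix = gm_subset(matrix, sites = keep),
       report = filter_report("depth", length(d), sum(keep),
                              thresholds[c("min_depth", "max_depth")]))
}

# minor allele frequency over non-missing alleles; NA where no calls
site_maf <- function(calls) {
  alt <- colSums(calls, na.rm = TRUE)
  n <- 2L * colSums(!is.na(calls))
  p <- ifelse(n > 0, alt / n, NA)
  pmin(p, 1 - p)
}

#' Site-level filters: mask, MAF, call rate, scaffold length
#'
#' Applied in order, each step logged separately: (1) sites inside the
#' exclusion mask are removed; (2) minor allele frequency, computed on
#' non-missing alleles, below `maf_min` removed; (3) sites where the fraction
#' of genotyped samples is below `call_rate_min` removed; (4) sites on
#' scaffolds shorter than `min_scaffold_bp` removed. All bounds are
#' inclusive-at-threshold (a site exactly at `maf_min`, `call_rate_min` or on
#' a scaffold of exactly `min_scaffold_bp` is kept).
#'
#' @param matrix a [genotype_matrix()].
#' @param mask a `genomic_mask` or `NULL`.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param call_rate_min minimum genotyped fraction (default 0.90).
#' @param min_scaffold_bp minimum scaffold length (default 10000).
#' @return `list(matrix, report)` with one report row per step.
#' @export
apply_site_filters <- function(matrix, mask = NULL, maf_min = 0.01,
                               call_rate_min = 0.90, min_scaffold_bp = 10000) {
  reports <- list()
  if (!is.null(mask) && nrow(mask)) {
    keep <- !mask_hits(mask, matrix$sites$scaffold, matrix$sites$pos)
    reports$mask <- filter_report("mask", length(keep), sum(keep), list())
    matrix <- gm_subset(matrix, sites = keep)
  } else {
    reports$mask <- filter_report("mask", nrow(matrix$sites), nrow(matrix$sites), list())
  }

  maf <- site_maf(matrix$calls)
  keep <- !is.na(maf) & maf >= maf_min
  reports$maf <- filter_report("maf", length(keep), sum(keep),
                               list(maf_min = maf_min))
  matrix <- gm_subset(matrix, sites = keep)

  rate <- colMeans(!is.na(matrix$calls))
  keep <- rate >= call_rate_min
  reports$call_rate <- filter_report("call_rate", length(keep), sum(keep),
                                     list(call_rate_min = call_rate_min))
  matrix <- gm_subset(matrix, sites = keep)

  keep <- matrix$scaffold_lengths[matrix$sites$scaffold] >= min_scaffold_bp
  reports$scaffold <- filter_report("scaffold_length", length(keep), sum(keep),
                                    list(min_scaffold_bp = min_scaffold_bp))
  matrix <- gm_subset(matrix, sites = keep)

  list(matrix = matrix, report = do.call(bind_reports, reports))
}

#' LD pruning by pairwise genotype-dosage correlation
#'
#' Sliding windows of `window_snps` SNPs advance by `step_snps`; within a
#' window, ordered site pairs are scanned greedily and when squared Pearson
#' correlation of the dosage vectors (over samples non-missing at both sites)
#' exceeds `r2_max`, the *later* site of the pair is removed. Removed sites
#' never re-enter later windows, so pruning a pruned matrix is a no-op.
#'
#' @param matrix a [genotype_matrix()].
#' @param window_snps window size in SNPs (default 50).
#' @param step_snps window step in SNPs (default 5).
#' @param r2_max maximum tolerated r-squared (default 0.5).
#' @return `list(matrix, report)`.
#' @export
ld_prune <- function(matrix, window_snps = 50, step_snps = 5, r2_max = 0.5) {
  m <- nrow(matrix$sites)
  keep <- rep(TRUE, m)
  calls <- matrix$calls
  scaffolds <- matrix$sites$scaffold
  pass <- function(keep) {
    for (sc in unique(scaffolds)) {
      idx <- which(scaffolds == sc)
      if (length(idx) < 2L) next
      start <- 1L
      repeat {
        live <- idx[keep[idx]]
        if (start > length(live)) break
        win <- live[start:min(start + window_snps - 1L, length(live))]
        if (length(win) >= 2L) {
          cc <- suppressWarnings(
            stats::cor(calls[, win, drop = FALSE],
                       use = "pairwise.complete.obs"))
          cc[is.na(cc)] <- 0
          for (i in seq_len(length(win) - 1L)) {
            if (!keep[win[i]]) next
            for (j in (i + 1L):length(win)) {
              if (!keep[win[j]]) next
              if (cc[i, j]^2 > r2_max) keep[win[j]] <- FALSE
            }
          }
        }
        if (start + window_snps - 1L >= length(live)) break
        start <- start + step_snps
      }
    }
    keep
  }
  # iterate to a fixed point: window composition shifts as sites drop out,
  # so a single sweep can leave a correlated pair that only later share a
  # window; convergence makes the operation idempotent
  repeat {
    new <- pass(keep)
    if (sum(new) == sum(keep)) break
    keep <- new
  }
  list(matrix = gm_subset(matrix, sites = keep),
       report = filter_report("ld_prune", m, sum(keep),
                              list(window_snps = window_snps,
                                   step_snps = step_snps, r2_max = r2_max)))
}
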