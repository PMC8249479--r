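#' @name pipeline
#' @title End-to-end analysis arms
#' @description
#' Two orchestrations mirror the two arms of a resequencing study: the
#' high-coverage "native" arm (source populations only) and the
#' "downsampled" arm (all populations at degraded coverage, with equal-n
#' resampled diversity). Every stage records its parameters and seed so a
#' rerun with the same configuration is byte-identical.
NULL

#' Run the native (high-coverage) analysis arm
#'
#' Filtering cascade (hard filters, depth, mask, MAF, call rate, scaffold
#' length) -> diversity summary -> pairwise windowed F_ST -> LD pruning ->
#' PCA -> admixture over a K range with CV -> ROH and F_ROH.
#'
#' @param matrix a [genotype_matrix()] (e.g. from [read_vcf()] or
#'   [simulate_populations()]).
#' @param map a [pop_map()] covering the matrix samples.
#' @param mask optional `genomic_mask`.
#' @param mean_coverage,n_samples aggregate depth model for
#'   [compute_depth_thresholds()]; `NULL mean_coverage` skips the depth
#'   filter.
#' @param maf_min,call_rate_min,min_scaffold_bp site filter settings.
#' @param window_bp analysis window size (pi and F_ST).
#' @param K_range admixture K values (default 1:6).
#' @param roh the [roh_params()] to use.
#' @param admix_control optional overrides for the admixture stage:
#'   `max_iter`, `tol`, `n_restarts`, `cv_n_restarts`, `n_folds`.
#' @param seed integer seed for the stochastic stages.
#' @param out_dir optional directory; when given, tables are written as TSV
#'   and the report as JSON.
#' @return A list report: `filter_report`, `diversity`, `fst` (per pair),
#'   `pca`, `admixture` (fit per K + CV curve), `roh` (segments, coverage,
#'   `f_roh` table), `seed`.
#' @export
run_native_arm <- function(matrix, map, mask = NULL, mean_coverage = NULL,
                           n_samples = length(matrix$samples),
                           maf_min = 0.01, call_rate_min = 0.90,
                           min_scaffold_bp = 10000, window_bp = 10000,
                           K_range = 1:6, roh = roh_params(), seed = 1,
                           admix_control = list(), out_dir = NULL) {
  ac <- utils::modifyList(list(max_iter = 2000, tol = 1e-4, n_restarts = 5,
                               cv_n_restarts = 2, n_folds = 5), admix_control)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  reports <- list()
  hf <- stage("hard_filters", apply_hard_filters(matrix))
  reports$hard <- hf$report
  mat <- hf$matrix
  if (!is.null(mean_coverage)) {
    dt <- compute_depth_thresholds(mean_coverage, n_samples)
    df <- stage("depth", apply_depth_filter(mat, dt))
    reports$depth <- df$report
    mat <- df$matrix
  }
  sf <- stage("site_filters",
              apply_site_filters(mat, mask, maf_min, call_rate_min,
                                 min_scaffold_bp))
  reports$site <- sf$report
  mat <- sf$matrix
  filter_report <- do.call(bind_reports, reports)

  div <- stage("diversity", diversity_summary(mat, map, window_bp))

  pops <- intersect(unique(as.vector(map)), as.vector(map[mat$samples]))
  pairs <- if (length(pops) > 1) utils::combn(pops, 2, simplify = FALSE) else list()
  fst <- lapply(pairs, function(pr)
    stage(paste0("fst_", paste(pr, collapse = "_")),
          fst_windows(mat, map, pr, window_bp)))
  names(fst) <- vapply(pairs, paste, character(1), collapse = "_vs_")

  pr <- stage("ld_prune", ld_prune(mat))
  pruned <- pr$matrix
  filter_report <- bind_reports(filter_report, pr$report)

  pca <- stage("pca", pca_genotypes(pruned))
  fits <- lapply(K_range, function(k)
    stage(paste0("admixture_K", k),
          fit_admixture(pruned, k, seed = seed, max_iter = ac$max_iter,
                        tol = ac$tol, n_restarts = ac$n_restarts)))
  names(fits) <- paste0("K", K_range)
  cv <- stage("cv", cv_curve(pruned, K_range, seed = seed,
                             n_folds = ac$n_folds, max_iter = ac$max_iter,
                             tol = ac$tol, n_restarts = ac$cv_n_restarts))

  segments <- stage("roh", detect_roh_all(mat, roh))
  cov <- stage("roh_coverage", roh_coverage(mat, roh))
  froh <- lapply(names(cov), function(thr) {
    mk <- as.numeric(sub("min_kb_", "", thr))
    vals <- vapply(mat$samples, function(s)
      f_roh(segments[segments$sample == s, , drop = FALSE],
            cov[[thr]]$total_bp, mk), numeric(1))
    list(values = vals, by_population = compare_f_roh(vals, map))
  })
  names(froh) <- names(cov)

  report <- list(filter_report = filter_report, n_sites = nrow(mat$sites),
                 diversity = div, fst = fst, pca = pca,
                 admixture = list(fits = fits, cv = cv$curve,
                                  optimal_K = cv$optimal_K),
                 roh = list(segments = segments,
                            coverage = lapply(cov, `[[`, "total_bp"),
                            f_roh = froh),
                 seed = seed, window_bp = window_bp)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Run the downsampled (all-population) analysis arm
#'
#' The matrix is degraded per the settings (extra missingness, redrawn
#' depths, optional allelic dropout), refiltered with the same cascade, and
#' analysed with equal-sample-size resampled diversity (means +- sd over
#' resampling replicates for the large populations; the small cohort is
#' reported directly with between-sample sd for H), admixture including the
#' admixed cohort, and ROH across all groups.
#'
#' @param matrix joint [genotype_matrix()] including the admixed cohort.
#' @param map a [pop_map()].
#' @param resample_pops populations to resample (default: those larger than
#'   `n_per_pop`).
#' @param n_per_pop,n_reps resampling design (default 6 x 100).
#' @param missing_rate,dropout_rate,depth_mean degradation settings.
#' @param K_range,window_bp,roh,seed,out_dir as in [run_native_arm()].
#' @inheritParams run_native_arm
#' @return A list report like [run_native_arm()]'s plus `resampled`
#'   (per-statistic resampling tables) and `small_cohort` direct values.
#' @export
run_downsampled_arm <- function(matrix, map, mask = NULL,
                                resample_pops = NULL, n_per_pop = 6,
                                n_reps = 100, missing_rate = 0.05,
                                dropout_rate = 0, depth_mean = NULL,
                                maf_min = 0.01, call_rate_min = 0.90,
                                min_scaffold_bp = 10000, window_bp = 10000,
                                K_range = 1:6, roh = roh_params(), seed = 1,
                                admix_control = list(), out_dir = NULL) {
  degraded <- degrade(matrix, missing_rate = missing_rate,
                      depth_mean = depth_mean, dropout_rate = dropout_rate,
                      seed = seed)
  report <- run_native_arm(degraded, map, mask = mask,
                           maf_min = maf_min, call_rate_min = call_rate_min,
                           min_scaffold_bp = min_scaffold_bp,
                           window_bp = window_bp, K_range = K_range,
                           roh = roh, seed = seed,
                           admix_control = admix_control)
  mat <- NULL  # refiltered matrix is internal to run_native_arm; redo filters
  sf <- apply_site_filters(apply_hard_filters(degraded)$matrix, mask,
                           maf_min, call_rate_min, min_scaffold_bp)
  mat <- sf$matrix

  sizes <- table(as.vector(map[mat$samples]))
  if (is.null(resample_pops))
    resample_pops <- names(sizes)[sizes > n_per_pop]
  small <- setdiff(names(sizes), resample_pops)

  report$resampled <- lapply(c("pi", "H", "P"), function(st)
    resample_equal_n(mat, map, resample_pops, n_per_pop, n_reps, st,
                     seed = seed, window_bp = window_bp))
  names(report$resampled) <- c("pi", "H", "P")

  report$small_cohort <- lapply(small, function(p) {
    H <- heterozygosity_proportion(mat, pop_samples(map, p, mat))
    list(population = p,
         pi = pi_windows(mat, map, p, window_bp)$mean_pi,
         H_mean = mean(H), H_sd = if (length(H) > 1) stats::sd(H) else NA_real_,
         P = polymorphic_proportion(mat, map, p))
  })
  names(report$small_cohort) <- small
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# serialize the machine-readable parts of a report
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(report$filter_report[, c("step", "before", "removed", "after")],
    "filter_report.tsv")
  w(report$diversity, "diversity.tsv")
  for (nm in names(report$fst))
    w(report$fst[[nm]]$windows, paste0("fst_", nm, ".tsv"))
  w(data.frame(sample = rownames(report$pca$scores), report$pca$scores),
    "pca_scores.tsv")
  w(report$admixture$cv, "cv_curve.tsv")
  for (nm in names(report$admixture$fits))
    w(data.frame(sample = rownames(report$admixture$fits[[nm]]$Q),
                 report$admixture$fits[[nm]]$Q), paste0("Q_", nm, ".tsv"))
  w(report$roh$segments, "roh_segments.tsv")
  summary <- list(
    n_sites = report$n_sites, seed = report$seed,
    window_bp = report$window_bp,
    optimal_K = report$admixture$optimal_K,
    fst_genome_wide = lapply(report$fst, function(x)
      list(mean = x$mean_fst, overall_weighted = x$overall_weighted_fst)),
    roh_coverage_bp = report$roh$coverage,
    f_roh_by_population = lapply(report$roh$f_roh, `[[`, "by_population"))
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
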