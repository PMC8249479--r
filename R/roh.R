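#' Default parameters for run-of-homozygosity detection
#'
#' Sliding-window ROH semantics matching PLINK's `--homozyg` scan: windows of
#' `window_snps` SNPs allowing at most `window_het_max` heterozygous and
#' `window_missing_max` missing calls; a SNP belongs to a candidate run when
#' at least `hit_fraction` of the windows overlapping it are homozygous; runs
#' are split at inter-SNP gaps above `gap_kb` and kept when they span at
#' least `min_kb`, contain at least `min_snps` SNPs and have at least one SNP
#' per `density_kb_per_snp` kb.
#'
#' @param min_kb minimum segment length, kb (default 100).
#' @param min_snps minimum SNPs per segment (default 50).
#' @param window_snps scanning window size in SNPs (default 50).
#' @param window_het_max max heterozygous calls per window (default 1).
#' @param window_missing_max max missing calls per window (default 5).
#' @param density_kb_per_snp max kb per SNP within a segment (default 50).
#' @param gap_kb max gap between consecutive SNPs in one segment, kb
#'   (default 1000).
#' @param hit_fraction min fraction of overlapping windows that must be
#'   homozygous (default 0.05, the PLINK default).
#' @return List of class `roh_params`.
#' @export
roh_params <- function(min_kb = 100, min_snps = 50, window_snps = 50,
                       window_het_max = 1, window_missing_max = 5,
                       density_kb_per_snp = 50, gap_kb = 1000,
                       hit_fraction = 0.05) {
  p <- list(min_kb = min_kb, min_snps = min_snps, window_snps = window_snps,
            window_het_max = window_het_max,
            window_missing_max = window_missing_max,
            density_kb_per_snp = density_kb_per_snp, gap_kb = gap_kb,
            hit_fraction = hit_fraction)
  if (any(unlist(p) <= 0)) stop("all ROH parameters must be positive")
  if (hit_fraction > 1) stop("hit_fraction must be in (0, 1]")
  structure(p, class = "roh_params")
}

# hit status per SNP for one vector of genotype codes on one scaffold
roh_hits <- function(g, params) {
  m <- length(g)
  w <- params$window_snps
  if (m < w) return(rep(FALSE, m))
  het <- as.numeric(!is.na(g) & g == 1L)
  mis <- as.numeric(is.na(g))
  csh <- c(0, cumsum(het))
  csm <- c(0, cumsum(mis))
  nwin <- m - w + 1L
  ws <- seq_len(nwin)
  hom_win <- (csh[ws + w] - csh[ws]) <= params$window_het_max &
    (csm[ws + w] - csm[ws]) <= params$window_missing_max
  # SNP i is overlapped by windows max(1, i-w+1) .. min(nwin, i)
  csw <- c(0, cumsum(as.numeric(hom_win)))
  i <- seq_len(m)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(nwin, i)
  n_hom <- csw[hi + 1L] - csw[lo]
  n_tot <- hi - lo + 1L
  n_hom / n_tot >= params$hit_fraction
}

#' Detect runs of homozygosity for one sample
#'
#' Each scaffold is scanned independently: (i) windows of `window_snps`
#' consecutive SNPs slide one SNP at a time and are flagged homozygous when
#' they contain at most `window_het_max` het and `window_missing_max` missing
#' calls; (ii) a SNP is a hit when the homozygous fraction of the windows
#' overlapping it reaches `hit_fraction` (edge SNPs use only the windows that
#' exist); (iii) maximal runs of consecutive hits, split at inter-SNP gaps
#' above `gap_kb`, become candidates; (iv) candidates pass when their span
#' (first to last SNP position, inclusive) is at least `min_kb`, they hold at
#' least `min_snps` SNPs, and span / n_snps does not exceed
#' `density_kb_per_snp`. Scaffolds with fewer SNPs than one window yield no
#' calls.
#'
#' @param matrix a [genotype_matrix()].
#' @param sample sample identifier.
#' @param params a [roh_params()].
#' @return data.frame of segments: `sample`, `scaffold`, `start`, `end`
#'   (1-based positions of the first/last SNP), `length_bp`, `n_snps`,
#'   `n_het`, `n_missing`.
#' @export
detect_roh <- function(matrix, sample, params = roh_params()) {
  g_all <- matrix$calls[sample, ]
  out <- list()
  for (sc in unique(matrix$sites$scaffold)) {
    idx <- which(matrix$sites$scaffold == sc)
    g <- g_all[idx]
    pos <- matrix$sites$pos[idx]
    hits <- roh_hits(g, params)
    if (!any(hits)) next
    run_id <- cumsum(c(TRUE, diff(hits) != 0))
    for (rid in unique(run_id[hits])) {
      span <- which(run_id == rid & hits)
      # split at large gaps
      gaps <- diff(pos[span]) > params$gap_kb * 1000
      piece <- cumsum(c(0, gaps))
      for (pp in unique(piece)) {
        seg <- span[piece == pp]
        len <- pos[seg[length(seg)]] - pos[seg[1]] + 1
        nsnp <- length(seg)
        if (len < params$min_kb * 1000) next
        if (nsnp < params$min_snps) next
        if (len / nsnp > params$density_kb_per_snp * 1000) next
        out[[length(out) + 1L]] <- data.frame(
          sample = sample, scaffold = sc,
          start = pos[seg[1]], end = pos[seg[length(seg)]],
          length_bp = len, n_snps = nsnp,
          n_het = sum(g[seg] == 1L, na.rm = TRUE),
          n_missing = sum(is.na(g[seg])),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(sample = character(0), scaffold = character(0),
                      start = numeric(0), end = numeric(0),
                      length_bp = numeric(0), n_snps = integer(0),
                      n_het = integer(0), n_missing = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect ROH for every sample
#'
#' @param matrix a [genotype_matrix()].
#' @param params a [roh_params()].
#' @return Combined segment data.frame across samples.
#' @export
detect_roh_all <- function(matrix, params = roh_params()) {
  do.call(rbind, lapply(matrix$samples, function(s)
    detect_roh(matrix, s, params)))
}

#' ROH analysis coverage from an artificial all-homozygous sample
#'
#' The fraction of the genome *detectable* as ROH depends on SNP density. An
#' artificial sample homozygous at every site is scanned with the same
#' parameters, once per minimum-length threshold; the summed segment length
#' is the analyzable genome, used as the denominator of F_ROH.
#'
#' @param matrix a [genotype_matrix()].
#' @param params a [roh_params()].
#' @param min_kb_variants minimum-length thresholds, kb (default
#'   `c(100, 1000)`).
#' @return Named list per threshold: `list(total_bp, segments)`.
#' @export
roh_coverage <- function(matrix, params = roh_params(),
                         min_kb_variants = c(100, 1000)) {
  art <- matrix
  art$calls <- rbind(matrix$calls,
                     matrix(0L, 1, nrow(matrix$sites),
                            dimnames = list("ARTIFICIAL_HOM", NULL)))
  art$samples <- c(matrix$samples, "ARTIFICIAL_HOM")
  out <- lapply(min_kb_variants, function(mk) {
    p <- params
    p$min_kb <- mk
    seg <- detect_roh(art, "ARTIFICIAL_HOM", p)
    list(total_bp = sum(seg$length_bp), segments = seg)
  })
  names(out) <- paste0("min_kb_", min_kb_variants)
  out
}

#' Coverage-normalized fraction of the genome in ROH
#'
#' @param segments segment data.frame from [detect_roh()] (one sample).
#' @param coverage_bp analyzable genome length for the matching threshold
#'   (from [roh_coverage()]).
#' @param min_kb minimum segment length to count, kb.
#' @return Scalar F_ROH.
#' @export
f_roh <- function(segments, coverage_bp, min_kb = 100) {
  if (coverage_bp <= 0) stop("coverage must be positive")
  sum(segments$length_bp[segments$length_bp >= min_kb * 1000]) / coverage_bp
}

#' Per-population mean and sd of F_ROH
#'
#' @param values named numeric vector of F_ROH per sample.
#' @param map a [pop_map()].
#' @return data.frame: population, n, mean, sd (NA for single samples).
#' @export
compare_f_roh <- function(values, map) {
  pops <- unique(as.vector(map[names(values)]))
  out <- do.call(rbind, lapply(pops, function(p) {
    v <- values[names(values) %in% names(map)[map == p]]
    data.frame(population = p, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
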