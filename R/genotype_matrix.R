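#' Construct a genotype matrix
#'
#' The central data structure of the package: diploid genotype dosages for a
#' set of samples at a set of biallelic SNP sites, together with per-site
#' metadata (scaffold, position, alleles, aggregate depth, variant-caller
#' annotations) and the lengths of the scaffolds the sites live on.
#'
#' @param calls integer matrix, samples x sites; entries 0 (hom-ref),
#'   1 (het), 2 (hom-alt) or `NA` (missing).
#' @param sites data.frame with columns `scaffold`, `pos` (1-based), `ref`,
#'   `alt`, `depth` (aggregate mapped depth across samples) and optionally the
#'   annotation columns `QD`, `QUAL`, `SOR`, `FS`, `MQ`, `MQRankSum`,
#'   `ReadPosRankSum` (NA where absent).
#' @param samples character vector of sample identifiers (row names of
#'   `calls`).
#' @param scaffold_lengths named numeric vector, scaffold -> length in bp.
#'   Every scaffold appearing in `sites` must be present.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, sites, samples = rownames(calls),
                            scaffold_lengths) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) stop("sample identifiers are required")
  samples <- as.character(samples)
  if (nrow(calls) != length(samples))
    stop("calls has ", nrow(calls), " rows but ", length(samples), " samples")
  if (ncol(calls) != nrow(sites))
    stop("calls has ", ncol(calls), " columns but ", nrow(sites), " sites")
  if (anyDuplicated(samples)) stop("duplicate sample identifiers")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype codes must be 0, 1, 2 or NA")

  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  req <- c("scaffold", "pos", "ref", "alt", "depth")
  miss <- setdiff(req, names(sites))
  if (length(miss)) stop("sites is missing columns: ", paste(miss, collapse = ", "))
  for (key in anno_keys()) if (is.null(sites[[key]])) sites[[key]] <- NA_real_
  if (nrow(sites)) {
    if (any(sites$pos < 1)) stop("positions must be >= 1")
    if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
    if (any(sites$depth < 0, na.rm = TRUE)) stop("aggregate depth must be >= 0")
  }

  scaffold_lengths <- unlist(scaffold_lengths)
  nolen <- setdiff(unique(sites$scaffold), names(scaffold_lengths))
  if (length(nolen))
    stop("no recorded length for scaffold(s): ", paste(nolen, collapse = ", "))

  ord <- order(match(sites$scaffold, unique(sites$scaffold)), sites$pos)
  if (is.unsorted(ord)) {
    sites <- sites[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
  }
  rownames(sites) <- NULL
  dimnames(calls) <- list(samples, NULL)

  structure(
    list(calls = calls, sites = sites, samples = samples,
         scaffold_lengths = scaffold_lengths),
    class = "genotype_matrix"
  )
}

anno_keys <- function() {
  c("QD", "QUAL", "SOR", "FS", "MQ", "MQRankSum", "ReadPosRankSum")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x", nrow(x$sites),
      "sites on", length(unique(x$sites$scaffold)), "scaffold(s)\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing genotype rate: %.4f\n", if (length(x$calls)) miss else 0))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$samples), nrow(x$sites))

#' Subset a genotype matrix by samples and/or sites
#'
#' @param x a `genotype_matrix`.
#' @param samples sample identifiers or indices to keep (default all).
#' @param sites logical/integer index over sites to keep (default all).
#' @return A `genotype_matrix` restricted to the selection.
#' @export
gm_subset <- function(x, samples = NULL, sites = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  si <- if (is.null(samples)) seq_along(x$samples) else {
    if (is.character(samples)) {
      idx <- match(samples, x$samples)
      if (anyNA(idx)) stop("unknown sample(s): ",
                           paste(samples[is.na(idx)], collapse = ", "))
      idx
    } else samples
  }
  vi <- if (is.null(sites)) seq_len(nrow(x$sites)) else sites
  genotype_matrix(
    calls = x$calls[si, vi, drop = FALSE],
    sites = x$sites[vi, , drop = FALSE],
    samples = x$samples[si],
    scaffold_lengths = x$scaffold_lengths
  )
}

#' Construct a population map
#'
#' @param samples character vector of sample identifiers.
#' @param populations character vector of population labels, recycled against
#'   `samples` only if scalar.
#' @return Named character vector of class `pop_map` (names = samples).
#' @export
pop_map <- function(samples, populations) {
  samples <- as.character(samples)
  populations <- as.character(populations)
  if (length(populations) == 1L) populations <- rep(populations, length(samples))
  if (length(samples) != length(populations))
    stop("samples and populations differ in length")
  if (anyDuplicated(samples)) stop("duplicate sample identifier in population map")
  if (any(!nzchar(populations))) stop("empty population label")
  structure(stats::setNames(populations, samples), class = "pop_map")
}

#' Sample identifiers belonging to one population
#'
#' @param map a `pop_map`.
#' @param population population label.
#' @param matrix optional `genotype_matrix`; if given, membership is checked
#'   against its samples.
#' @return Character vector of sample ids.
#' @export
pop_samples <- function(map, population, matrix = NULL) {
  ids <- names(map)[map == population]
  if (!length(ids)) stop("no samples in population ", population)
  if (!is.null(matrix)) {
    unknown <- setdiff(ids, matrix$samples)
    if (length(unknown))
      stop("population map samples absent from matrix: ",
           paste(unknown, collapse = ", "))
  }
  ids
}
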