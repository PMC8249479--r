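#' Read a multi-sample VCF into a genotype matrix
#'
#' Loads biallelic SNP records from a VCF 4.x file. Diploid GT strings are
#' encoded as alt-allele dosage 0/1/2; any GT containing "." (including
#' half-calls such as "./1") becomes missing. Phasing is ignored.
#' Multiallelic records and non-SNP alleles are dropped, not split.
#' Aggregate site depth is taken from INFO/DP; the hard-filter annotations
#' QD, SOR, FS, MQ, MQRankSum, ReadPosRankSum from INFO and QUAL from the
#' QUAL column (NA where absent).
#'
#' @param path path to a VCF (optionally gzipped).
#' @param scaffold_lengths optional named vector of scaffold lengths; when
#'   `NULL` they are parsed from `##contig` header lines. A site on a scaffold
#'   with no known length is an error.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, scaffold_lengths = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)

  if (is.null(scaffold_lengths)) {
    contigs <- grep("^##contig=", vcf@meta, value = TRUE)
    ids <- sub('.*[<,]ID=([^,>]+).*', "\\1", contigs)
    lens <- suppressWarnings(as.numeric(sub('.*[<,]length=([0-9]+).*', "\\1", contigs)))
    scaffold_lengths <- stats::setNames(lens, ids)
    scaffold_lengths <- scaffold_lengths[!is.na(scaffold_lengths)]
  }

  nt <- c("A", "C", "G", "T")
  keep <- fix$REF %in% nt & fix$ALT %in% nt
  if (!any(keep)) {
    return(genotype_matrix(
      calls = matrix(integer(0), nrow = ncol(vcf@gt) - 1L, ncol = 0L,
                     dimnames = list(colnames(vcf@gt)[-1L], NULL)),
      sites = data.frame(scaffold = character(0), pos = numeric(0),
                         ref = character(0), alt = character(0),
                         depth = numeric(0)),
      scaffold_lengths = scaffold_lengths))
  }
  vcf <- vcf[keep, ]
  fix <- fix[keep, , drop = FALSE]

  gt <- vcfR::extract.gt(vcf, element = "GT")
  codes <- encode_gt(gt)

  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  info_field <- function(key) {
    num_or_na(vcfR::extract.info(vcf, element = key))
  }
  sites <- data.frame(
    scaffold = fix$CHROM,
    pos = as.numeric(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    depth = info_field("DP"),
    QD = info_field("QD"),
    QUAL = num_or_na(fix$QUAL),
    SOR = info_field("SOR"),
    FS = info_field("FS"),
    MQ = info_field("MQ"),
    MQRankSum = info_field("MQRankSum"),
    ReadPosRankSum = info_field("ReadPosRankSum"),
    stringsAsFactors = FALSE
  )
  sites$depth[is.na(sites$depth)] <- 0

  genotype_matrix(calls = t(codes), sites = sites,
                  samples = colnames(gt), scaffold_lengths = scaffold_lengths)
}

# GT string -> dosage; any "." component -> NA; strictly diploid otherwise.
encode_gt <- function(gt) {
  u <- unique(as.vector(gt))
  u <- u[!is.na(u)]
  map <- vapply(u, function(s) {
    if (grepl("\\.", s)) return(NA_integer_)
    alleles <- strsplit(s, "[/|]")[[1]]
    if (length(alleles) != 2L)
      stop("non-diploid GT string: '", s, "'")
    a <- suppressWarnings(as.integer(alleles))
    if (anyNA(a) || any(a > 1L) || any(a < 0L))
      stop("unsupported GT allele in '", s, "' (biallelic diploid expected)")
    sum(a)
  }, integer(1))
  out <- matrix(map[match(as.vector(gt), u)], nrow = nrow(gt),
                dimnames = dimnames(gt))
  out[is.na(gt)] <- NA_integer_
  out
}

#' Write a genotype matrix as a VCF file
#'
#' Emits a minimal VCF 4.2 with `##contig` lines for every recorded scaffold,
#' INFO DP and hard-filter annotations where present, and a GT-only FORMAT.
#' Missing genotypes are written as `./.`. Output ordering is the matrix's
#' site ordering (scaffold, then position), so writing is deterministic.
#'
#' @param matrix a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(matrix, path) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  s <- matrix$sites
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=popkit",
    sprintf("##contig=<ID=%s,length=%d>", names(matrix$scaffold_lengths),
            as.integer(matrix$scaffold_lengths)),
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Aggregate read depth">',
    sprintf('##INFO=<ID=%s,Number=1,Type=Float,Description="Variant annotation">',
            setdiff(anno_keys(), "QUAL")),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", matrix$samples), collapse = "\t")
  )
  writeLines(hdr, con)
  if (nrow(s)) {
    gt_str <- matrix(c("0/0", "0/1", "1/1")[matrix$calls + 1L],
                     nrow = nrow(matrix$calls))
    gt_str[is.na(matrix$calls)] <- "./."
    fmt_num <- function(x) ifelse(is.na(x), NA, format(x, trim = TRUE, scientific = FALSE))
    info <- sprintf("DP=%d", as.integer(round(s$depth)))
    for (key in setdiff(anno_keys(), "QUAL")) {
      v <- fmt_num(s[[key]])
      info <- ifelse(is.na(v), info, paste0(info, ";", key, "=", v))
    }
    qual <- ifelse(is.na(s$QUAL), ".", fmt_num(s$QUAL))
    rec <- paste(s$scaffold, format(s$pos, trim = TRUE, scientific = FALSE), ".",
                 s$ref, s$alt, qual, ".", info, "GT",
                 apply(gt_str, 2, paste, collapse = "\t"), sep = "\t")
    writeLines(rec, con)
  }
  invisible(path)
}

#' Read a two-column sample-to-population map
#'
#' @param path whitespace-delimited text file: sample id, population label.
#' @return A [pop_map()].
#' @export
read_population_map <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("sample", "population"))
  if (!nrow(tab)) stop("empty population map: ", path)
  pop_map(tab$sample, tab$population)
}

#' Write a population map to a two-column text file
#'
#' @param map a [pop_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_population_map <- function(map, path) {
  utils::write.table(data.frame(sample = names(map), population = as.vector(map)),
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3 mappability mask
#'
#' Intervals are 0-based half-open exclusion regions. They are normalized
#' (sorted and merged per scaffold) on read.
#'
#' @param path BED file path.
#' @return A `genomic_mask`: data.frame with columns `scaffold`, `start`,
#'   `end` (0-based half-open), non-overlapping and sorted.
#' @export
read_mask_bed <- function(path) {
  n <- length(readLines(path, n = 1L))
  if (n == 0L) return(genomic_mask(data.frame(
    scaffold = character(0), start = numeric(0), end = numeric(0))))
  bed <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)[, 1:3]
  names(bed) <- c("scaffold", "start", "end")
  genomic_mask(bed)
}

#' Construct a genomic exclusion mask
#'
#' @param intervals data.frame with `scaffold`, `start`, `end` (0-based
#'   half-open). Overlapping or adjacent intervals are merged.
#' @return A normalized `genomic_mask` data.frame.
#' @export
genomic_mask <- function(intervals) {
  intervals <- as.data.frame(intervals, stringsAsFactors = FALSE)
  if (nrow(intervals) && any(intervals$end <= intervals$start))
    stop("mask interval with end <= start")
  out <- do.call(rbind, lapply(split(intervals, intervals$scaffold), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    ms <- d$start[1]; me <- d$end[1]; acc <- list()
    if (nrow(d) > 1) for (i in 2:nrow(d)) {
      if (d$start[i] <= me) me <- max(me, d$end[i])
      else { acc[[length(acc) + 1L]] <- c(ms, me); ms <- d$start[i]; me <- d$end[i] }
    }
    acc[[length(acc) + 1L]] <- c(ms, me)
    m <- do.call(rbind, acc)
    data.frame(scaffold = d$scaffold[1], start = m[, 1], end = m[, 2],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) out <- data.frame(scaffold = character(0),
                                      start = numeric(0), end = numeric(0))
  rownames(out) <- NULL
  structure(out, class = c("genomic_mask", "data.frame"))
}

# TRUE for sites falling inside the mask (VCF pos p masked iff start <= p-1 < end)
mask_hits <- function(mask, scaffold, pos) {
  hit <- logical(length(pos))
  for (sc in unique(scaffold)) {
    iv <- mask[mask$scaffold == sc, , drop = FALSE]
    if (!nrow(iv)) next
    sel <- scaffold == sc
    p0 <- pos[sel] - 1
    idx <- findInterval(p0, iv$start)
    hit[sel] <- idx >= 1L & p0 < iv$end[pmax(idx, 1L)]
  }
  hit
}
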