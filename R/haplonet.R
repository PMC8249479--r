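#' Collapse aligned sequences into unique haplotypes
#'
#' Reads an aligned FASTA (all sequences equal length), merges identical
#' sequences into haplotypes, and tabulates carriers per population.
#' Comparison is case-insensitive. Alignment columns containing a gap (`-`)
#' in any sequence are removed before collapsing and distance computation;
#' the number of segregating (polymorphic) columns among the remaining
#' positions is reported.
#'
#' @param fasta path to an aligned FASTA, or a named character vector of
#'   sequences.
#' @param map a [pop_map()] covering every sequence id.
#' @return `list(haplotypes (named character), counts (haplotype x
#'   population matrix), members (list of carrier ids), n_segregating)` of
#'   class `haplotype_set`.
#' @export
collapse_haplotypes <- function(fasta, map) {
  seqs <- if (length(fasta) == 1L && file.exists(fasta)) {
    aln <- ape::read.dna(fasta, format = "fasta", as.character = TRUE,
                         as.matrix = FALSE)
    vapply(aln, function(x) paste(x, collapse = ""), character(1))
  } else fasta
  seqs <- toupper(seqs)
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences are not aligned: unequal lengths")
  unknown <- setdiff(names(seqs), names(map))
  if (length(unknown))
    stop("sequence ids missing from population map: ",
         paste(unknown, collapse = ", "))

  chars <- do.call(rbind, strsplit(seqs, ""))
  gap_col <- apply(chars == "-", 2, any)
  chars <- chars[, !gap_col, drop = FALSE]
  if (any(!chars %in% c("A", "C", "G", "T", "N")))
    warning("ambiguity codes present; compared literally")
  seqs_nogap <- apply(chars, 1, paste, collapse = "")
  names(seqs_nogap) <- names(seqs)

  uniq <- unique(seqs_nogap)
  hid <- paste0("H", seq_along(uniq))
  assign <- hid[match(seqs_nogap, uniq)]
  pops <- as.vector(map[names(seqs)])
  counts <- table(factor(assign, levels = hid), pops)
  counts <- matrix(counts, nrow = length(hid),
                   dimnames = list(hid, colnames(counts)))
  n_seg <- sum(apply(chars, 2, function(col) length(unique(col)) > 1L))
  structure(list(haplotypes = stats::setNames(uniq, hid),
                 counts = counts,
                 members = split(names(seqs), assign)[hid],
                 n_segregating = n_seg),
            class = "haplotype_set")
}

#' Hamming distance between two aligned sequences
#'
#' Counts mismatching positions (case-insensitive). Columns where either
#' sequence carries a gap are excluded.
#'
#' @param h1,h2 character scalars of equal length.
#' @return Integer substitution count.
#' @export
hamming_distance <- function(h1, h2) {
  if (nchar(h1) != nchar(h2)) stop("sequences differ in length")
  a <- strsplit(toupper(h1), "")[[1]]
  b <- strsplit(toupper(h2), "")[[1]]
  ok <- a != "-" & b != "-"
  sum(a[ok] != b[ok])
}

#' Minimum spanning network over haplotypes
#'
#' Builds the epsilon = 0 minimum spanning network: Kruskal-style growth over
#' the complete pairwise-distance graph where, at each distance value, *all*
#' edges joining distinct components at that value are admitted. The result
#' is the union of every minimum spanning tree. Each admitted edge is
#' labelled `essential` (present in every MST: it is a bridge among the
#' edges admitted at its level) or a tie-alternative.
#'
#' @param hapset a `haplotype_set` from [collapse_haplotypes()].
#' @return `list(nodes (haplotype ids + carrier counts), edges (data.frame
#'   from, to, steps, essential))` of class `haplotype_network`.
#' @export
minimum_spanning_network <- function(hapset) {
  hid <- names(hapset$haplotypes)
  n <- length(hid)
  edges <- data.frame(from = character(0), to = character(0),
                      steps = integer(0), essential = logical(0))
  if (n > 1) {
    pairs <- utils::combn(n, 2)
    d <- apply(pairs, 2, function(ij)
      hamming_distance(hapset$haplotypes[ij[1]], hapset$haplotypes[ij[2]]))
    comp <- seq_len(n)
    acc <- list()
    for (w in sort(unique(d))) {
      lvl <- which(d == w)
      # admissible: joins two distinct components as they stand at this level
      join <- lvl[comp[pairs[1, lvl]] != comp[pairs[2, lvl]]]
      if (!length(join)) next
      # essential iff unique bridge: removing the edge leaves its endpoints'
      # components unconnected by the other level edges
      for (e in join) {
        others <- setdiff(join, e)
        # union-find over components using the other admitted edges
        cc <- comp
        for (o in others) {
          c1 <- cc[pairs[1, o]]; c2 <- cc[pairs[2, o]]
          if (c1 != c2) cc[cc == c2] <- c1
        }
        ess <- cc[pairs[1, e]] != cc[pairs[2, e]]
        acc[[length(acc) + 1L]] <- data.frame(
          from = hid[pairs[1, e]], to = hid[pairs[2, e]],
          steps = w, essential = ess, stringsAsFactors = FALSE)
      }
      for (e in join) {
        c1 <- comp[pairs[1, e]]; c2 <- comp[pairs[2, e]]
        if (c1 != c2) comp[comp == c2] <- c1
      }
    }
    edges <- do.call(rbind, acc)
    rownames(edges) <- NULL
  }
  structure(list(
    nodes = data.frame(haplotype = hid,
                       count = rowSums(hapset$counts),
                       stringsAsFactors = FALSE),
    edges = edges,
    counts = hapset$counts), class = "haplotype_network")
}

#' Write a haplotype network edge list as TSV
#'
#' @param network a `haplotype_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
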