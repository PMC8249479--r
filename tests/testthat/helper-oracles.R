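# independent reference implementations ("oracles") that the package code is
# checked against; deliberately written in plain, literal style

# Weir & Cockerham (1984) two-population variance components, transcribed
# term by term for a single site given two genotype vectors (0/1/2/NA)
oracle_wc <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n1 <- length(g1); n2 <- length(g2)
  p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
  h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
  r <- 2
  nbar <- mean(c(n1, n2))
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  list(a = a, b = b, c = c)
}

# exhaustive ROH caller: windows, hits and candidate checks done with
# literal loops over every index
oracle_roh <- function(g, pos, params) {
  m <- length(g)
  w <- params$window_snps
  if (m < w) return(NULL)
  nwin <- m - w + 1
  hom_win <- logical(nwin)
  for (s in 1:nwin) {
    win <- g[s:(s + w - 1)]
    hom_win[s] <- sum(win == 1, na.rm = TRUE) <= params$window_het_max &&
      sum(is.na(win)) <= params$window_missing_max
  }
  hit <- logical(m)
  for (i in 1:m) {
    covering <- intersect(1:nwin, (i - w + 1):i)
    hit[i] <- mean(hom_win[covering]) >= params$hit_fraction
  }
  segs <- list()
  i <- 1
  while (i <= m) {
    if (!hit[i]) { i <- i + 1; next }
    j <- i
    while (j < m && hit[j + 1] &&
           pos[j + 1] - pos[j] <= params$gap_kb * 1000) j <- j + 1
    len <- pos[j] - pos[i] + 1
    nsnp <- j - i + 1
    if (len >= params$min_kb * 1000 && nsnp >= params$min_snps &&
        len / nsnp <= params$density_kb_per_snp * 1000)
      segs[[length(segs) + 1]] <- c(start = pos[i], end = pos[j],
                                    n_snps = nsnp)
    i <- j + 1
  }
  if (!length(segs)) return(NULL)
  do.call(rbind, segs)
}

# all spanning trees of a complete graph on n nodes by enumerating every
# (n-1)-subset of edges; returns the union of all minimum-weight ones and
# the intersection (edges present in every MST)
oracle_msn <- function(dist_mat) {
  n <- nrow(dist_mat)
  if (n == 1) return(list(union = NULL, essential = NULL, weight = 0))
  pairs <- t(utils::combn(n, 2))
  wts <- dist_mat[pairs]
  ne <- nrow(pairs)
  spanning <- function(edge_idx) {
    comp <- seq_len(n)
    for (e in edge_idx) {
      a <- comp[pairs[e, 1]]; b <- comp[pairs[e, 2]]
      if (a == b) return(FALSE)
      comp[comp == b] <- a
    }
    length(unique(comp)) == 1
  }
  subsets <- utils::combn(ne, n - 1, simplify = FALSE)
  trees <- Filter(spanning, subsets)
  wt <- vapply(trees, function(t) sum(wts[t]), numeric(1))
  minw <- min(wt)
  msts <- trees[wt == minw]
  idx_union <- sort(unique(unlist(msts)))
  idx_ess <- Reduce(intersect, msts)
  list(union = pairs[idx_union, , drop = FALSE],
       essential = pairs[sort(idx_ess), , drop = FALSE],
       weight = minw)
}

# edge set of a haplotype_network as a canonical "i-j" string vector,
# mapping haplotype ids back to their index
edge_keys <- function(edges, hid) {
  if (is.null(edges) || !nrow(edges)) return(character(0))
  i <- match(edges$from, hid); j <- match(edges$to, hid)
  sort(paste(pmin(i, j), pmax(i, j), sep = "-"))
}
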