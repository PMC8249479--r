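#' Simulation configuration
#'
#' Defaults emulate the study design this package targets: three diverged
#' source populations of 20 diploid individuals each, with Balding-Nichols
#' divergence parameters chosen so the three pairwise F_ST values fall in
#' the 0.17-0.20 range, 50,000 unlinked SNPs on 10 scaffolds totalling
#' 73 Mb (giving per-bp nucleotide diversity near 2e-4 under the
#' Uniform(0.05, 0.95) ancestral frequency law), a 6-individual admixed
#' cohort with mean ancestry (0.746, 0.135, 0.119), per-sample mean depth
#' 16.9x with negative-binomial site-level noise, 2% missingness and 0.5%
#' heterozygote miscall rate.
#'
#' @param n_populations number of source populations.
#' @param n_per_pop diploid individuals per source population.
#' @param fst_target per-population Balding-Nichols F (recycled).
#' @param n_sites number of SNP sites.
#' @param scaffold_lengths named vector of scaffold lengths (bp).
#' @param ancestral_range range of the uniform ancestral-frequency law.
#' @param admixed_n number of admixed individuals (0 disables).
#' @param admixed_q ancestry proportions for the admixed cohort (one vector,
#'   shared; must sum to 1) or a matrix with one row per individual.
#' @param missing_rate i.i.d. genotype missingness rate.
#' @param het_error_rate rate at which homozygous calls are flipped to het
#'   inside implanted tracts.
#' @param depth_mean mean per-sample coverage (x).
#' @param depth_dispersion negative-binomial size parameter for site depth.
#' @param pop_labels population labels (defaults to the study's rivers).
#' @param seed integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_populations = 3, n_per_pop = 20,
                       fst_target = c(0.221, 0.171, 0.169),
                       n_sites = 50000,
                       scaffold_lengths = stats::setNames(
                         rep(7.3e6, 10), paste0("scaffold_", 1:10)),
                       ancestral_range = c(0.05, 0.95),
                       admixed_n = 6,
                       admixed_q = c(0.746, 0.135, 0.119),
                       missing_rate = 0.02, het_error_rate = 0.005,
                       depth_mean = 16.9, depth_dispersion = 10,
                       pop_labels = c("Baven", "Eman", "Mockeln",
                                      "HelgeA")[seq_len(n_populations + (admixed_n > 0))],
                       seed = 1) {
  fst_target <- rep_len(fst_target, n_populations)
  if (any(fst_target < 0) || any(fst_target >= 1))
    stop("fst_target must lie in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1 || het_error_rate < 0 ||
      het_error_rate >= 1)
    stop("rates must lie in [0, 1)")
  if (is.matrix(admixed_q)) {
    if (any(abs(rowSums(admixed_q) - 1) > 1e-8))
      stop("admixed_q rows must sum to 1")
  } else if (admixed_n > 0 && abs(sum(admixed_q) - 1) > 1e-8) {
    stop("admixed_q must sum to 1")
  }
  structure(list(n_populations = n_populations, n_per_pop = n_per_pop,
                 fst_target = fst_target, n_sites = n_sites,
                 scaffold_lengths = scaffold_lengths,
                 ancestral_range = ancestral_range,
                 admixed_n = admixed_n, admixed_q = admixed_q,
                 missing_rate = missing_rate,
                 het_error_rate = het_error_rate,
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 pop_labels = pop_labels, seed = seed),
            class = "sim_config")
}

#' Simulate diverged populations under the Balding-Nichols model
#'
#' Ancestral allele frequencies are drawn uniformly on `ancestral_range`;
#' each population's frequency is drawn from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` (exactly `p` when `F = 0`), and
#' genotypes are independent `Binomial(2, p_pop)` draws. Sites are placed
#' uniformly at random on the scaffold layout (distinct positions, sorted).
#' Per-site aggregate depth is drawn as a scaled negative binomial around
#' `depth_mean * n_samples`. The returned truth object records ancestral and
#' per-population frequencies, making recovery tests exact.
#'
#' @param config a [sim_config()].
#' @return `list(matrix = genotype_matrix, map = pop_map, truth)` where
#'   `truth` holds `p_ancestral`, `p_pop` (populations x sites), per-site
#'   depth draws, and the admixed cohort's true Q when present.
#' @export
simulate_populations <- function(config = sim_config()) {
  set.seed(config$seed)
  npop <- config$n_populations
  m <- config$n_sites
  labels <- config$pop_labels[seq_len(npop)]

  # site placement: uniform over the genome, unique positions per scaffold
  lens <- config$scaffold_lengths
  sc <- sample(names(lens), m, replace = TRUE, prob = lens / sum(lens))
  pos <- floor(stats::runif(m, 1, lens[sc] + 1))
  dup <- duplicated(paste(sc, pos))
  while (any(dup)) {
    pos[dup] <- floor(stats::runif(sum(dup), 1, lens[sc[dup]] + 1))
    dup <- duplicated(paste(sc, pos))
  }

  p_anc <- stats::runif(m, config$ancestral_range[1], config$ancestral_range[2])
  p_pop <- matrix(NA_real_, npop, m, dimnames = list(labels, NULL))
  for (k in seq_len(npop)) {
    F <- config$fst_target[k]
    p_pop[k, ] <- if (F == 0) p_anc else
      stats::rbeta(m, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
  }
  # Beta draws can hit 0/1 at machine precision; keep sites segregating-able
  p_pop <- pmin(pmax(p_pop, 1e-6), 1 - 1e-6)

  n <- config$n_per_pop
  samples <- unlist(lapply(labels, function(l) sprintf("%s_%02d", l, seq_len(n))))
  calls <- matrix(NA_integer_, npop * n, m, dimnames = list(samples, NULL))
  for (k in seq_len(npop)) {
    rows <- (k - 1) * n + seq_len(n)
    calls[rows, ] <- matrix(
      stats::rbinom(n * m, 2, rep(p_pop[k, ], each = n)), n, m)
  }

  nsamp_total <- npop * n + config$admixed_n
  depth <- round(stats::rnbinom(m, size = config$depth_dispersion,
                                mu = config$depth_mean) * nsamp_total)

  # sort everything once so truth columns align with the site table
  ord <- order(match(sc, names(lens)), pos)
  sc <- sc[ord]; pos <- pos[ord]; depth <- depth[ord]
  p_anc <- p_anc[ord]
  p_pop <- p_pop[, ord, drop = FALSE]
  calls <- calls[, ord, drop = FALSE]

  ref_alt <- replicate(m, sample(c("A", "C", "G", "T"), 2))
  sites <- data.frame(scaffold = sc, pos = pos,
                      ref = ref_alt[1, ], alt = ref_alt[2, ],
                      depth = depth, stringsAsFactors = FALSE)
  gm <- genotype_matrix(calls, sites, samples, lens)
  map <- pop_map(samples, rep(labels, each = n))
  truth <- list(p_ancestral = p_anc, p_pop = p_pop, config = config)
  list(matrix = gm, map = map, truth = truth)
}

#' Append an admixed cohort drawn from simulated source populations
#'
#' Each allele copy of individual i at a site is drawn from source k with
#' probability `q_ik`, then Bernoulli with that source's site frequency.
#'
#' @param sim output of [simulate_populations()].
#' @param n number of admixed individuals (default from config).
#' @param q shared ancestry vector or n x K matrix (default from config).
#' @param label population label for the cohort.
#' @param seed integer seed.
#' @return `sim` with matrix/map extended and `truth$Q_admixed` recorded.
#' @export
simulate_admixed <- function(sim, n = sim$truth$config$admixed_n,
                             q = sim$truth$config$admixed_q,
                             label = utils::tail(sim$truth$config$pop_labels, 1),
                             seed = sim$truth$config$seed + 1) {
  if (n == 0) return(sim)
  K <- nrow(sim$truth$p_pop)
  Q <- if (is.matrix(q)) q else matrix(rep(q, each = n), n, K)
  if (ncol(Q) != K) stop("q must have one column per source population")
  if (any(abs(rowSums(Q) - 1) > 1e-8)) stop("Q rows must sum to 1")
  set.seed(seed)
  m <- ncol(sim$matrix$calls)
  calls <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    for (copy in 1:2) {
      src <- sample.int(K, m, replace = TRUE, prob = Q[i, ])
      p <- sim$truth$p_pop[cbind(src, seq_len(m))]
      calls[i, ] <- calls[i, ] + stats::rbinom(m, 1, p)
    }
  }
  ids <- sprintf("%s_%02d", label, seq_len(n))
  rownames(calls) <- ids
  gm <- sim$matrix
  gm$calls <- rbind(gm$calls, calls)
  gm$samples <- c(gm$samples, ids)
  sim$matrix <- gm
  sim$map <- pop_map(c(names(sim$map), ids),
                     c(as.vector(sim$map), rep(label, n)))
  sim$truth$Q_admixed <- Q
  sim
}

#' Implant autozygous tracts into a sample
#'
#' Within each tract the genotype is forced homozygous: at every site one
#' allele is drawn from the sample's population frequency and doubled;
#' `het_error_rate` then flips calls back to heterozygous, emulating
#' genotyping error inside true autozygous runs.
#'
#' @param sim output of [simulate_populations()].
#' @param sample sample identifier.
#' @param tracts data.frame with `scaffold`, `start`, `end` (1-based
#'   inclusive, bp); tracts must not overlap.
#' @param het_error_rate het miscall rate inside tracts (default from
#'   config).
#' @param seed integer seed.
#' @return `sim` with genotypes overwritten and
#'   `truth$roh_tracts[[sample]]` recorded.
#' @export
implant_roh <- function(sim, sample, tracts,
                        het_error_rate = sim$truth$config$het_error_rate,
                        seed = sim$truth$config$seed + 2) {
  tr <- tracts[order(tracts$scaffold, tracts$start), , drop = FALSE]
  by_sc <- split(tr, tr$scaffold)
  for (d in by_sc)
    if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)]))
      stop("overlapping tracts")
  if (any(tr$end > sim$matrix$scaffold_lengths[tr$scaffold]))
    stop("tract outside scaffold bounds")
  set.seed(seed)
  pop <- as.vector(sim$map[sample])
  sidx <- match(sample, sim$matrix$samples)
  s <- sim$matrix$sites
  for (i in seq_len(nrow(tr))) {
    inside <- which(s$scaffold == tr$scaffold[i] &
                      s$pos >= tr$start[i] & s$pos <= tr$end[i])
    if (!length(inside)) next
    p <- if (pop %in% rownames(sim$truth$p_pop))
      sim$truth$p_pop[pop, inside] else colMeans(sim$truth$p_pop)[inside]
    hom <- 2L * stats::rbinom(length(inside), 1, p)
    err <- stats::runif(length(inside)) < het_error_rate
    hom[err] <- 1L
    sim$matrix$calls[sidx, inside] <- hom
  }
  sim$truth$roh_tracts[[sample]] <-
    rbind(sim$truth$roh_tracts[[sample]], tr)
  sim
}

#' Degrade a genotype matrix with missingness and depth artifacts
#'
#' Emulates a lower-coverage sequencing arm at the genotype level: entries
#' are set missing i.i.d. at `missing_rate`; per-site aggregate depth is
#' redrawn from the negative-binomial depth model; optionally heterozygous
#' calls are flipped to a random homozygote at `dropout_rate` (allelic
#' dropout, the low-coverage failure mode that inflates homozygosity).
#'
#' @param matrix a [genotype_matrix()].
#' @param missing_rate i.i.d. missingness rate.
#' @param depth_mean,depth_dispersion depth model (per-sample mean x, NB
#'   size); `NULL depth_mean` keeps existing depths.
#' @param dropout_rate het -> hom flip rate (default 0).
#' @param seed integer seed.
#' @return The degraded `genotype_matrix`.
#' @export
degrade <- function(matrix, missing_rate = 0.1, depth_mean = NULL,
                    depth_dispersion = 10, dropout_rate = 0, seed = 1) {
  set.seed(seed)
  calls <- matrix$calls
  if (dropout_rate > 0) {
    het <- which(!is.na(calls) & calls == 1L)
    flip <- het[stats::runif(length(het)) < dropout_rate]
    calls[flip] <- 2L * stats::rbinom(length(flip), 1, 0.5)
  }
  if (missing_rate > 0) {
    drop <- stats::runif(length(calls)) < missing_rate
    calls[drop] <- NA_integer_
  }
  matrix$calls <- calls
  if (!is.null(depth_mean)) {
    m <- nrow(matrix$sites)
    matrix$sites$depth <- round(
      stats::rnbinom(m, size = depth_dispersion, mu = depth_mean) *
        length(matrix$samples))
  }
  matrix
}

#' Simulate aligned mitochondrial haplotypes
#'
#' Builds a random template sequence and derives each haplotype by applying
#' substitutions at the stated positions, so pairwise Hamming distances
#' equal the specification by construction. Carriers are emitted as an
#' aligned FASTA-style named vector plus a population map.
#'
#' @param substitutions named list: haplotype id -> integer vector of
#'   template positions mutated in that haplotype (empty vector = the
#'   template itself). Distances between haplotypes follow from symmetric
#'   difference of their position sets.
#' @param carriers named list: haplotype id -> named integer vector of
#'   carrier counts per population.
#' @param length_bp template length (default 16524).
#' @param seed integer seed.
#' @return `list(sequences (named character), map (pop_map))`.
#' @export
simulate_mito <- function(substitutions, carriers, length_bp = 16524,
                          seed = 1) {
  set.seed(seed)
  template <- sample(c("A", "C", "G", "T"), length_bp, replace = TRUE)
  mutate <- function(posv) {
    s <- template
    for (p in posv) {
      if (anyDuplicated(posv)) stop("duplicate substitution positions")
      s[p] <- setdiff(c("A", "C", "G", "T"), template[p])[1]
    }
    paste(s, collapse = "")
  }
  haps <- vapply(substitutions, mutate, character(1))
  seqs <- character(0); ids <- character(0); pops <- character(0)
  for (h in names(carriers)) {
    for (p in names(carriers[[h]])) {
      k <- carriers[[h]][[p]]
      if (k == 0) next
      new_ids <- sprintf("%s_mt_%s_%02d", p, h, seq_len(k))
      ids <- c(ids, new_ids)
      pops <- c(pops, rep(p, k))
      seqs <- c(seqs, stats::setNames(rep(haps[[h]], k), new_ids))
    }
  }
  list(sequences = seqs, map = pop_map(ids, pops))
}

#' Write aligned sequences as FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(sequences)) {
    writeLines(paste0(">", id), con)
    writeLines(sequences[[id]], con)
  }
  invisible(path)
}
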