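#' Simulate half-sib families by gamete dropping
#'
#' Generates one or more paternal half-sib families with full truth
#' records. Per SNP a population reference-allele frequency is drawn from
#' `Uniform(freq_range)`; each sire's two strands and every dam-contributed
#' allele are independent Bernoulli draws at that frequency (each offspring
#' has its own unrelated dam). Each paternal gamete carries a
#' `Poisson(chr_length_morgans)` number of crossovers (Haldane model, no
#' interference) placed uniformly over the inter-SNP intervals; the
#' transmission vector starts on a random strand and switches at each
#' crossover. Genotyping errors replace a cell with a uniformly chosen
#' different valid genotype; the missing mask is applied last. SNP
#' positions are equally spaced.
#'
#' @param n_families number of families.
#' @param family_size offspring per family (scalar or vector of length
#'   `n_families`).
#' @param n_snps SNPs per chromosome.
#' @param n_chromosomes number of chromosomes (each with `n_snps` SNPs and
#'   length `chr_length_morgans`).
#' @param chr_length_morgans genetic length per chromosome in Morgans;
#'   0 gives crossover-free gametes.
#' @param freq_range range of the uniform allele-frequency law (default
#'   `c(0.1, 0.9)`).
#' @param error_rate per-cell genotyping error probability.
#' @param missing_rate per-cell missing probability.
#' @param fixed_crossovers optional integer: every gamete gets exactly
#'   this many crossovers instead of the Poisson draw (deterministic
#'   tests).
#' @param unlinked if `TRUE`, every SNP's paternal transmission is an
#'   independent strand pick (free recombination between all markers).
#'   This is the linkage-equilibrium abstraction of a sparse genome-wide
#'   parentage panel and is the appropriate world for testing
#'   opposing-homozygote statistics and pedigree reconstruction; block
#'   and recombination analyses are meaningless in this mode. Overrides
#'   the crossover model.
#' @param seed optional seed fixing the full output.
#' @return list with `genotypes` (offspring matrix), `sire_genotypes`,
#'   `map`, `pedigree` and `truth`. `truth` holds `freqs` and one record
#'   per family: `sire_haplotypes` (2 x n_snps), `transmission` (offspring
#'   x SNP strand labels 1/2), `crossovers` (list of interval indices per
#'   offspring), `maternal` (dam-contributed alleles) and
#'   `genotypes_clean` (before error/missing masking).
#' @export
simulate_halfsib <- function(n_families = 1L, family_size = 8L,
                             n_snps = 2000L, n_chromosomes = 1L,
                             chr_length_morgans = 1,
                             freq_range = c(0.1, 0.9),
                             error_rate = 0, missing_rate = 0,
                             fixed_crossovers = NULL, unlinked = FALSE,
                             seed = NULL) {
  if (error_rate < 0 || error_rate > 1 || missing_rate < 0 ||
      missing_rate > 1)
    stop("error_rate and missing_rate must lie in [0, 1]")
  if (n_snps < 2L) stop("need at least 2 SNPs")
  if (chr_length_morgans < 0) stop("chromosome length must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  sizes <- rep_len(family_size, n_families)
  m_tot <- n_snps * n_chromosomes
  freqs <- stats::runif(m_tot, freq_range[1L], freq_range[2L])
  snp_id <- sprintf("SNP%05d", seq_len(m_tot))
  map <- data.frame(
    snp_id = snp_id,
    chromosome = as.character(rep(seq_len(n_chromosomes), each = n_snps)),
    position_bp = rep(seq_len(n_snps) * 1000L, n_chromosomes),
    stringsAsFactors = FALSE)

  sire_ids <- sprintf("SIRE%02d", seq_len(n_families))
  geno <- NULL
  sire_geno <- matrix(0L, n_families, m_tot,
                      dimnames = list(sire_ids, snp_id))
  ped <- list()
  fam_truth <- vector("list", n_families)
  names(fam_truth) <- sire_ids

  drop_gamete <- function() {
    if (unlinked) {
      lab <- sample(1:2, m_tot, replace = TRUE)
      return(list(lab = lab, xo = which(lab[-1L] != lab[-m_tot])))
    }
    # transmission labels per SNP for one multi-chromosome gamete
    lab <- integer(0)
    xo_all <- integer(0)
    for (ch in seq_len(n_chromosomes)) {
      nx <- if (!is.null(fixed_crossovers)) fixed_crossovers
            else stats::rpois(1L, chr_length_morgans)
      # uniform positions over the chromosome, mapped to intervals
      iv <- if (nx > 0L)
        sort(1L + as.integer(floor(stats::runif(nx) * (n_snps - 1L))))
      else integer(0)
      v <- rep(sample(1:2, 1L), n_snps)
      for (x in iv) v[(x + 1L):n_snps] <- 3L - v[(x + 1L):n_snps]
      lab <- c(lab, v)
      xo_all <- c(xo_all, iv + (ch - 1L) * n_snps)
    }
    list(lab = lab, xo = xo_all)
  }

  for (f in seq_len(n_families)) {
    ns <- sizes[f]
    sire_hap <- matrix(stats::rbinom(2L * m_tot, 1L, rep(freqs, each = 2L)),
                       2L, m_tot)
    storage.mode(sire_hap) <- "integer"
    sire_geno[f, ] <- sire_hap[1L, ] + sire_hap[2L, ]
    trans <- matrix(0L, ns, m_tot)
    xo <- vector("list", ns)
    maternal <- matrix(0L, ns, m_tot)
    off_ids <- sprintf("F%02d_O%02d", f, seq_len(ns))
    for (o in seq_len(ns)) {
      gam <- drop_gamete()
      trans[o, ] <- gam$lab
      xo[[o]] <- gam$xo
      maternal[o, ] <- stats::rbinom(m_tot, 1L, freqs)
    }
    pat_allele <- matrix(sire_hap[cbind(as.vector(trans),
                                        rep(seq_len(m_tot), each = ns))],
                         ns, m_tot)
    g_clean <- pat_allele + maternal
    storage.mode(g_clean) <- "integer"
    dimnames(g_clean) <- list(off_ids, snp_id)
    rownames(trans) <- rownames(maternal) <- off_ids
    colnames(trans) <- colnames(maternal) <- snp_id
    names(xo) <- off_ids
    geno <- rbind(geno, g_clean)
    ped[[f]] <- data.frame(individual_id = off_ids, sire_id = sire_ids[f],
                           stringsAsFactors = FALSE)
    fam_truth[[f]] <- list(sire_haplotypes = sire_hap, transmission = trans,
                           crossovers = xo, maternal = maternal,
                           genotypes_clean = g_clean)
  }

  g <- geno
  if (error_rate > 0) {
    hit <- which(stats::runif(length(g)) < error_rate)
    if (length(hit))
      g[hit] <- (g[hit] + sample(1:2, length(hit), replace = TRUE)) %% 3L
  }
  if (missing_rate > 0) {
    g[stats::runif(length(g)) < missing_rate] <- 9L
  }
  storage.mode(g) <- "integer"

  list(genotypes = g, sire_genotypes = sire_geno, map = map,
       pedigree = do.call(rbind, ped),
       truth = list(freqs = freqs, families = fam_truth))
}

#' Simulate genotype pairs of a given relationship
#'
#' Draws pairs of individuals that are unrelated, paternal half-sibs or
#' full sibs at the supplied allele frequencies and returns their
#' opposing-homozygote counts. Serves as the Monte-Carlo oracle for
#' [expected_oh()].
#'
#' @param n_pairs number of pairs.
#' @param relationship `"unrelated"`, `"halfsib"` or `"fullsib"`.
#' @param freqs per-SNP reference-allele frequencies.
#' @param seed optional seed.
#' @return integer vector of length `n_pairs` of opposing-homozygote
#'   counts.
#' @export
simulate_pairs <- function(n_pairs, relationship = c("unrelated", "halfsib",
                                                     "fullsib"),
                           freqs, seed = NULL) {
  relationship <- match.arg(relationship)
  if (!is.null(seed)) set.seed(seed)
  m <- length(freqs)
  draw <- function() stats::rbinom(m, 1L, freqs)
  out <- integer(n_pairs)
  for (i in seq_len(n_pairs)) {
    if (relationship == "unrelated") {
      g1 <- draw() + draw()
      g2 <- draw() + draw()
    } else {
      sire <- rbind(draw(), draw())
      pick <- function() sire[cbind(sample(1:2, m, replace = TRUE),
                                    seq_len(m))]
      if (relationship == "halfsib") {
        g1 <- pick() + draw()
        g2 <- pick() + draw()
      } else {
        dam <- rbind(draw(), draw())
        pick_dam <- function() dam[cbind(sample(1:2, m, replace = TRUE),
                                         seq_len(m))]
        g1 <- pick() + pick_dam()
        g2 <- pick() + pick_dam()
      }
    }
    out[i] <- count_oh(g1, g2)
  }
  out
}

# orientation-invariant squared correlation between label/allele vectors;
# degenerate (zero-variance) cases fall back to agreement under the best
# global label swap
squared_cor <- function(x, y, swap = function(v) v) {
  if (length(x) < 2L) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(max(mean(x == y), mean(swap(x) == y)))
  }
  stats::cor(x, y)^2
}

#' Score inferred blocks and haplotypes against simulator truth
#'
#' Compares a block label matrix (and optionally inferred/imputed paternal
#' haplotypes) with the truth record of one simulated family. The block
#' score is the squared Pearson correlation between true and inferred
#' strand labels over determined loci - squaring makes it invariant to the
#' global 1/2 label swap - plus the agreement after resolving the swap to
#' the better orientation. Haplotype accuracy is the fraction of called
#' alleles matching the truth.
#'
#' @param blocks inferred block label matrix for the family.
#' @param truth_family one element of `truth$families` from
#'   [simulate_halfsib()].
#' @param paternal optional inferred/imputed paternal allele matrix
#'   (n x n_snps, 9 = uncalled) to score against the true transmitted
#'   alleles.
#' @return list with `block_r2`, `block_accuracy` (best-orientation
#'   agreement), `block_call_rate`, `crossover_count_error` (mean absolute
#'   difference between inferred and true effective crossover counts) and,
#'   when `paternal` is given, `allele_r2`, `allele_accuracy`,
#'   `allele_call_rate`.
#' @export
score_against_truth <- function(blocks, truth_family, paternal = NULL) {
  trans <- truth_family$transmission
  if (!all(dim(blocks) == dim(trans)))
    stop("block matrix does not match the truth dimensions")
  det <- blocks != 0L
  x <- blocks[det]
  y <- trans[det]
  acc <- max(mean(x == y), mean((3L - x) == y))
  out <- list(
    block_r2 = squared_cor(x, y, swap = function(v) 3L - v),
    block_accuracy = acc,
    block_call_rate = mean(det))
  true_counts <- vapply(seq_len(nrow(trans)), function(i) {
    sum(trans[i, -1L] != trans[i, -ncol(trans)])
  }, 0L)
  out$crossover_count_error <-
    mean(abs(count_recombinations(blocks) - true_counts))
  if (!is.null(paternal)) {
    m <- ncol(trans)
    true_pat <- matrix(truth_family$sire_haplotypes[
      cbind(as.vector(trans), rep(seq_len(m), each = nrow(trans)))],
      nrow(trans), m)
    called <- paternal != 9L
    out$allele_r2 <- squared_cor(paternal[called], true_pat[called])
    out$allele_accuracy <- mean(paternal[called] == true_pat[called])
    out$allele_call_rate <- mean(called)
  }
  out
}
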