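#' Count opposing homozygotes between two genotype vectors
#'
#' An opposing homozygote is a locus where one individual is homozygous for
#' one allele (genotype 0) and the other is homozygous for the alternative
#' allele (genotype 2). Such Mendelian inconsistencies cannot occur between
#' a true parent and offspring barring genotyping error, which is what makes
#' the count informative about relationships. Loci where either vector is
#' missing (9) are excluded.
#'
#' @param gi,gj integer genotype vectors of equal length, coded 0/1/2/9.
#' @return integer count of opposing-homozygous loci.
#' @export
count_oh <- function(gi, gj) {
  if (length(gi) != length(gj))
    stop("genotype vectors differ in length (", length(gi), " vs ",
         length(gj), ")")
  sum((gi == 0L & gj == 2L) | (gi == 2L & gj == 0L))
}

#' Pairwise opposing-homozygote matrix
#'
#' Computes the symmetric individuals x individuals matrix of
#' opposing-homozygote counts. Implemented with two indicator
#' cross-products, so it scales to large panels without an explicit
#' pairwise loop.
#'
#' @param g integer genotype matrix (individuals x SNPs, coded 0/1/2/9).
#' @return symmetric integer matrix with zero diagonal and the individual
#'   ids as dimnames.
#' @export
oh_matrix <- function(g) {
  g <- validate_genotypes(g)
  if (nrow(g) < 2L) stop("need at least 2 individuals")
  h0 <- matrix(as.numeric(g == 0L), nrow(g))
  h2 <- matrix(as.numeric(g == 2L), nrow(g))
  cross <- tcrossprod(h0, h2)      # cross[i, j] = #loci i==0 & j==2
  oh <- cross + t(cross)
  diag(oh) <- 0
  storage.mode(oh) <- "integer"
  dimnames(oh) <- list(rownames(g), rownames(g))
  oh
}

#' Per-SNP reference-allele frequencies
#'
#' Mean genotype over non-missing calls divided by two. Used as the default
#' population frequency estimate for [expected_oh()].
#' @param g integer genotype matrix.
#' @return numeric vector of frequencies in `[0, 1]` (NaN for all-missing
#'   columns).
#' @export
allele_frequencies <- function(g) {
  g <- validate_genotypes(g)
  gm <- g
  gm[gm == 9L] <- NA_integer_
  colMeans(gm, na.rm = TRUE) / 2
}

#' Expected opposing-homozygote counts by relationship
#'
#' Closed-form expectations under Hardy-Weinberg and Mendelian transmission.
#' With reference-allele frequency `p` and `q = 1 - p` at a locus, the
#' per-locus probability of an opposing homozygote is `2 p^2 q^2` for
#' unrelated individuals, `p^2 q^2` for half-sibs (who share one parental
#' gamete half the time) and `p^2 q^2 / 2` for full sibs. Summing over loci
#' gives the expected genome-wide counts. The reported `cutoff` used to
#' accept a half-sib relationship is placed 90% of the way from the
#' half-sib expectation towards the unrelated expectation.
#'
#' @param freqs numeric vector of per-SNP reference-allele frequencies.
#' @return list with elements `e_unrelated`, `e_halfsib`, `e_fullsib`,
#'   `cutoff`.
#' @export
expected_oh <- function(freqs) {
  freqs <- as.numeric(freqs)
  if (any(is.na(freqs)) || any(freqs < 0) || any(freqs > 1))
    stop("allele frequencies must lie in [0, 1]")
  s <- sum(freqs^2 * (1 - freqs)^2)
  list(e_unrelated = 2 * s,
       e_halfsib = s,
       e_fullsib = s / 2,
       cutoff = s + 0.9 * (2 * s - s))
}

#' Parent-offspring assignment from opposing-homozygote counts
#'
#' For each individual, the candidate with the minimal opposing-homozygote
#' count is accepted as its parent-offspring partner when that count does
#' not exceed `max_mismatch` (by default 1% of the number of markers, the
#' usual genotyping-error allowance). Ties at the minimal count are not
#' broken silently: the individual is left unassigned and listed in
#' `attr(, "conflicts")`.
#'
#' @param oh opposing-homozygote matrix from [oh_matrix()].
#' @param max_mismatch maximum allowed mismatches; default
#'   `round(0.01 * n_snps)` when `n_snps` is given.
#' @param n_snps number of markers, used only for the default threshold.
#' @return pedigree data.frame (`individual_id`, `sire_id`; `NA` =
#'   unassigned) with a `conflicts` attribute (data.frame of tied
#'   assignments).
#' @export
assign_parentage <- function(oh, max_mismatch = NULL, n_snps = NULL) {
  if (is.null(max_mismatch)) {
    if (is.null(n_snps))
      stop("supply max_mismatch or n_snps (default is 1% of markers)")
    max_mismatch <- round(0.01 * n_snps)
  }
  if (max_mismatch < 0) stop("max_mismatch must be >= 0")
  ids <- rownames(oh)
  n <- nrow(oh)
  parent <- rep(NA_character_, n)
  conflicts <- list()
  for (i in seq_len(n)) {
    cand <- oh[i, -i]
    m <- min(cand)
    if (m <= max_mismatch) {
      hits <- names(cand)[cand == m]
      if (length(hits) == 1L) {
        parent[i] <- hits
      } else {
        conflicts[[length(conflicts) + 1L]] <-
          data.frame(individual_id = ids[i],
                     candidates = paste(hits, collapse = ";"),
                     oh = m, stringsAsFactors = FALSE)
      }
    }
  }
  out <- data.frame(individual_id = ids, sire_id = parent,
                    stringsAsFactors = FALSE)
  attr(out, "conflicts") <- if (length(conflicts))
    do.call(rbind, conflicts)
  else
    data.frame(individual_id = character(0), candidates = character(0),
               oh = integer(0))
  out
}

#' Separation value of an opposing-homozygote matrix
#'
#' With a pedigree, the separation value is `(min OH among false
#' sire-offspring pairs - max OH among true pairs) / max OH in the
#' dataset`: positive values mean parentage can be resolved without error.
#' Without a pedigree, the largest gap between consecutive sorted
#' upper-triangle counts plays the role of the true/false divide, and the
#' same ratio is reported. In both cases `cutoff_count` is the rounded
#' midpoint of the largest gap, a natural mismatch threshold for pedigree
#' reconstruction, and the sorted series is returned for plotting.
#'
#' @param oh opposing-homozygote matrix.
#' @param pedigree optional pedigree data.frame (`individual_id`,
#'   `sire_id`); only pairs with both members in `oh` are used.
#' @return list with `sv` (separation value), `cutoff_count` (integer) and
#'   `pairs` (data.frame: `rank`, `count` and, with a pedigree, `true`).
#' @export
separation_value <- function(oh, pedigree = NULL) {
  ids <- rownames(oh)
  ut <- upper.tri(oh)
  vals <- oh[ut]
  max_all <- max(vals)
  if (max_all == 0)
    stop("all pairwise counts are zero; separation value undefined")
  idx <- which(ut, arr.ind = TRUE)
  truth <- rep(FALSE, length(vals))
  if (!is.null(pedigree)) {
    ped <- pedigree[!is.na(pedigree$sire_id) &
                      pedigree$individual_id %in% ids &
                      pedigree$sire_id %in% ids, , drop = FALSE]
    if (nrow(ped) == 0L)
      stop("pedigree contains no usable sire-offspring pair")
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    true_keys <- key(ped$individual_id, ped$sire_id)
    truth <- key(ids[idx[, 1L]], ids[idx[, 2L]]) %in% true_keys
    sv <- (min(vals[!truth]) - max(vals[truth])) / max_all
    lo <- max(vals[truth])
    hi <- min(vals[!truth])
  } else {
    sv_sorted <- sort(vals)
    gaps <- diff(sv_sorted)
    k <- which.max(gaps)
    lo <- sv_sorted[k]
    hi <- sv_sorted[k + 1L]
    sv <- (hi - lo) / max_all
  }
  ord <- order(vals)
  pairs <- data.frame(rank = seq_along(vals), count = vals[ord])
  if (!is.null(pedigree)) pairs$true <- truth[ord]
  list(sv = sv, cutoff_count = as.integer(round((lo + hi) / 2)),
       pairs = pairs)
}
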