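#' Infer sire haplotypes from a family's block structure
#'
#' For each sire strand and SNP, the mean genotype of the offspring
#' currently assigned to that strand (missing genotypes ignored) estimates
#' the transmitted paternal allele plus the average maternal contribution.
#' A mean below 0.5 can only arise when the paternal allele is 0, and a
#' mean above 1.5 only when it is 1, so those calls are made; any mean in
#' between (including exactly 1) cannot separate the paternal from the
#' maternal contribution and the strand is left uncalled (9), as is any
#' strand with no assigned offspring at that SNP. On error-free data every
#' call made by this rule is therefore correct; the cost is call rate, not
#' accuracy.
#'
#' @param b block label matrix from [build_blocks()].
#' @param g genotype matrix of the same family, aligned with `b`.
#' @param lower,upper call thresholds on the group mean (defaults 0.5 and
#'   1.5).
#' @return 2 x n_snps integer matrix of sire strand alleles in
#'   `{0, 1, 9}`.
#' @export
infer_sire_haplotypes <- function(b, g, lower = 0.5, upper = 1.5) {
  if (!all(dim(b) == dim(g))) stop("block and genotype matrices must align")
  m <- ncol(g)
  hap <- matrix(9L, 2L, m, dimnames = list(c("strand1", "strand2"),
                                           colnames(g)))
  gm <- g
  gm[gm == 9L] <- NA_integer_
  for (s in 1:2) {
    sel <- b == s
    cnt <- colSums(sel & !is.na(gm))
    tot <- colSums(ifelse(sel, gm, NA_integer_), na.rm = TRUE)
    mu <- ifelse(cnt > 0L, tot / cnt, NA_real_)
    hap[s, which(!is.na(mu) & mu < lower)] <- 0L
    hap[s, which(!is.na(mu) & mu > upper)] <- 1L
  }
  hap
}

#' Phase the offspring of a half-sib family
#'
#' Overlays the block labels on the sire's phased haplotypes: each
#' offspring's paternal allele at a SNP is the allele of the sire strand
#' its label points at (9 where the label is 0 or the strand uncalled). A
#' homozygous offspring genotype that contradicts the assigned paternal
#' allele voids that call (9) and is logged, rather than silently
#' rewriting the block. Maternal alleles are then obtained by subtracting
#' the paternal haplotype from the genotype wherever both are defined.
#'
#' @param g genotype matrix of the family.
#' @param b block label matrix from [build_blocks()].
#' @param sire 2 x n_snps sire haplotypes from [infer_sire_haplotypes()].
#' @return list with integer matrices `paternal` and `maternal` (alleles
#'   in `{0, 1, 9}`) and `conflicts`, a data.frame of voided calls
#'   (`individual_id`, `snp`).
#' @export
phase_family <- function(g, b, sire) {
  if (!all(dim(b) == dim(g))) stop("block and genotype matrices must align")
  if (ncol(sire) != ncol(g)) stop("sire haplotypes must cover the same SNPs")
  n <- nrow(g)
  m <- ncol(g)
  pat <- matrix(9L, n, m, dimnames = dimnames(g))
  for (s in 1:2) {
    sel <- b == s
    pat[sel] <- rep(sire[s, ], each = n)[sel]
  }
  # homozygote that cannot carry the assigned paternal allele
  conflict <- (g == 0L & pat == 1L) | (g == 2L & pat == 0L)
  if (any(conflict)) {
    w <- which(conflict, arr.ind = TRUE)
    conflicts <- data.frame(individual_id = rownames(g)[w[, 1L]],
                            snp = w[, 2L], stringsAsFactors = FALSE)
    pat[conflict] <- 9L
  } else {
    conflicts <- data.frame(individual_id = character(0), snp = integer(0))
  }
  mat <- g - pat
  mat[g == 9L | pat == 9L | !(mat %in% c(0L, 1L))] <- 9L
  storage.mode(mat) <- "integer"
  list(paternal = pat, maternal = mat, conflicts = conflicts)
}

#' Impute offspring paternal haplotypes from low to high density
#'
#' Uses the sire's high-density haplotypes as a scaffold: blocks are built
#' on the low-density genotypes, each offspring's labels are expanded to
#' high-density coordinates (a high-density SNP strictly between two
#' low-density SNPs carrying the same non-zero label inherits that label;
#' intervals spanning a label change, undetermined labels or the map
#' boundaries stay unlabelled), and the paternal allele is read off the
#' labelled sire strand. Because block labels are only defined up to a
#' global 1/2 swap, the low-density blocking is first oriented against
#' the scaffold: its own strand estimates ([infer_sire_haplotypes()] on
#' the low-density panel) are matched to the scaffold strands and the
#' labels swapped if the crossed mapping agrees better. At low-density
#' positions the directly phased allele ([phase_family()] on the
#' low-density panel) takes precedence.
#' SNPs inside a recombination interval are deliberately left uncalled
#' rather than guessing the breakpoint.
#'
#' @param g_low genotype matrix on the low-density panel (family).
#' @param sire_hd 2 x n_hd sire haplotypes on the high-density panel.
#' @param ld_index integer positions of the low-density SNPs within the
#'   high-density panel (strictly increasing).
#' @param persistence passed to [build_blocks()].
#' @return list with `paternal` (n x n_hd integer matrix, alleles
#'   `{0, 1, 9}`), `blocks_ld` (the low-density block matrix) and
#'   `labels_hd` (the expanded label matrix).
#' @export
impute_paternal <- function(g_low, sire_hd, ld_index, persistence = 1L) {
  n_hd <- ncol(sire_hd)
  ld_index <- as.integer(ld_index)
  if (any(diff(ld_index) <= 0L) || min(ld_index) < 1L ||
      max(ld_index) > n_hd)
    stop("ld_index must be strictly increasing positions within the HD panel")
  if (length(ld_index) != ncol(g_low))
    stop("ld_index length must equal the number of low-density SNPs")
  n <- nrow(g_low)
  b_ld <- build_blocks(g_low, persistence = persistence)
  # orient the LD blocking against the scaffold (labels are exchangeable)
  sire_ld <- sire_hd[, ld_index, drop = FALSE]
  est <- infer_sire_haplotypes(b_ld, g_low)
  agree <- function(a, b) sum(a != 9L & b != 9L & a == b)
  same <- agree(est[1L, ], sire_ld[1L, ]) + agree(est[2L, ], sire_ld[2L, ])
  crossed <- agree(est[1L, ], sire_ld[2L, ]) + agree(est[2L, ], sire_ld[1L, ])
  if (crossed > same) {
    det <- b_ld != 0L
    b_ld[det] <- 3L - b_ld[det]
  }
  lab_hd <- matrix(0L, n, n_hd, dimnames = list(rownames(g_low), NULL))
  lab_hd[, ld_index] <- b_ld
  for (j in seq_len(length(ld_index) - 1L)) {
    a <- ld_index[j]
    z <- ld_index[j + 1L]
    if (z > a + 1L) {
      same <- b_ld[, j] == b_ld[, j + 1L] & b_ld[, j] != 0L
      if (any(same))
        lab_hd[same, (a + 1L):(z - 1L)] <- b_ld[same, j]
    }
  }
  pat <- matrix(9L, n, n_hd, dimnames = dimnames(lab_hd))
  for (s in 1:2) {
    sel <- lab_hd == s
    pat[sel] <- rep(sire_hd[s, ], each = n)[sel]
  }
  # direct phasing at the genotyped LD positions takes precedence
  direct <- phase_family(g_low, b_ld, sire_hd[, ld_index, drop = FALSE])
  pat[, ld_index] <- direct$paternal
  list(paternal = pat, blocks_ld = b_ld, labels_hd = lab_hd)
}

#' Per-chromosome phasing pipeline for one family
#'
#' Runs block construction, sire inference and offspring phasing on each
#' chromosome slice independently. Chromosomes share no state, so results
#' are identical whatever the execution order or worker count; with
#' `threads > 1` slices are processed with [parallel::mclapply()].
#'
#' @param g genotype matrix of one family (all chromosomes).
#' @param map SNP map aligned with `g` (see [align_inputs()]).
#' @param persistence passed to [build_blocks()].
#' @param threads number of worker processes (default 1).
#' @return named list (one element per chromosome) of lists with `blocks`,
#'   `sire` and `phased` (the [phase_family()] result).
#' @export
phase_halfsib_family <- function(g, map, persistence = 1L, threads = 1L) {
  bundle <- align_inputs(g, map)
  run_one <- function(cols) {
    gs <- bundle$genotypes[, cols, drop = FALSE]
    b <- build_blocks(gs, persistence = persistence)
    sire <- infer_sire_haplotypes(b, gs)
    list(blocks = b, sire = sire, phased = phase_family(gs, b, sire))
  }
  slices <- bundle$slices
  res <- if (threads > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(slices, run_one, mc.cores = threads)
  } else {
    lapply(slices, run_one)
  }
  names(res) <- names(slices)
  res
}
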