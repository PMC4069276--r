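#' Build the paternal-origin block structure of a half-sib family
#'
#' Within a half-sib family, a SNP with an opposing-homozygous pair proves
#' the sire heterozygous there, and the homozygous offspring reveal which
#' sire strand they inherited. Scanning such informative SNPs in map order,
#' the family is partitioned into two groups (label 1 / label 2, meaning
#' exchangeable) tracking the inherited strand: at each informative SNP the
#' two homozygote classes are oriented onto the groups so as to minimise
#' the number of already-labelled individuals that would have to switch
#' (ties keep the previous orientation, since a recombination between
#' adjacent SNPs is unlikely). A contradiction becomes a committed switch -
#' a recombination - only if it persists at the individual's next
#' informative observation(s); a single-SNP contradiction flanked by the
#' original group on both sides is recorded as a genotyping error and the
#' label is left unchanged. Labels propagate across uninformative SNPs;
#' individuals never anchored (e.g. heterozygous at every informative SNP)
#' stay 0.
#'
#' @param g integer genotype matrix for one family on one chromosome, SNP
#'   columns in map order.
#' @param persistence number of subsequent confirming informative
#'   observations required before a switch is committed (default 1). A
#'   switch still pending at the end of the chromosome is committed, as no
#'   later observation can contradict it.
#' @return integer matrix of the same shape with labels in `{0, 1, 2}`
#'   (0 = undetermined), carrying attributes `genotyping_errors`
#'   (data.frame `individual_id`, `snp`) and `informative` (logical per
#'   SNP). Returns an all-zero matrix with a warning when the chromosome
#'   has no informative SNP.
#' @seealso [recombination_events()], [count_recombinations()],
#'   [infer_sire_haplotypes()]
#' @export
build_blocks <- function(g, persistence = 1L) {
  g <- validate_genotypes(g)
  n <- nrow(g)
  m <- ncol(g)
  if (n < 2L) stop("need at least 2 family members")
  informative <- colSums(g == 0L) > 0L & colSums(g == 2L) > 0L
  labels <- matrix(0L, n, m, dimnames = dimnames(g))
  err_id <- integer(0)
  err_snp <- integer(0)
  if (!any(informative)) {
    warning("no opposing-homozygous SNP on this chromosome; all labels 0")
    attr(labels, "genotyping_errors") <-
      data.frame(individual_id = character(0), snp = integer(0))
    attr(labels, "informative") <- informative
    return(labels)
  }

  cur <- integer(n)            # current group per individual, 0 = none
  seg_start <- vector("list", n)   # committed segment starts
  seg_lab <- vector("list", n)
  pend_grp <- integer(n)       # pending switch group (0 = none)
  pend_snp <- integer(n)       # SNP where the pending run started
  pend_run <- vector("list", n) # SNPs of the pending run (for error logs)
  pend_conf <- integer(n)      # confirmations accumulated
  last_obs <- integer(n)       # last SNP where the current label was observed
  prev_orient <- 1L            # 1: hom0 -> group 1; 2: hom0 -> group 2

  # the switch is assigned to the interval following the last SNP where the
  # old group was actually observed (the gap convention of the event report)
  commit <- function(i) {
    seg_start[[i]] <<- c(seg_start[[i]], last_obs[i] + 1L)
    seg_lab[[i]] <<- c(seg_lab[[i]], pend_grp[i])
    cur[i] <<- pend_grp[i]
    pend_grp[i] <<- 0L
    pend_conf[i] <<- 0L
    pend_run[[i]] <<- integer(0)
  }

  for (k in which(informative)) {
    i0 <- which(g[, k] == 0L)
    i2 <- which(g[, k] == 2L)
    # orientation minimising switches among already-labelled individuals
    lab0 <- cur[i0][cur[i0] != 0L]
    lab2 <- cur[i2][cur[i2] != 0L]
    cost1 <- sum(lab0 != 1L) + sum(lab2 != 2L)  # hom0 -> 1
    cost2 <- sum(lab0 != 2L) + sum(lab2 != 1L)  # hom0 -> 2
    orient <- if (cost1 < cost2) 1L else if (cost2 < cost1) 2L else prev_orient
    prev_orient <- orient
    grp <- integer(n)
    grp[i0] <- orient
    grp[i2] <- 3L - orient
    for (i in c(i0, i2)) {
      gnew <- grp[i]
      if (cur[i] == 0L) {                       # anchor
        cur[i] <- gnew
        seg_start[[i]] <- c(seg_start[[i]], k)
        seg_lab[[i]] <- c(seg_lab[[i]], gnew)
        last_obs[i] <- k
      } else if (pend_grp[i] != 0L) {
        if (gnew == pend_grp[i]) {              # switch confirmed once more
          pend_conf[i] <- pend_conf[i] + 1L
          if (pend_conf[i] >= persistence) {
            commit(i)
            last_obs[i] <- k
          } else {
            pend_run[[i]] <- c(pend_run[[i]], k)
          }
        } else {                                # returned to the old group
          err_id <- c(err_id, rep(i, length(pend_run[[i]])))
          err_snp <- c(err_snp, pend_run[[i]])
          pend_grp[i] <- 0L
          pend_conf[i] <- 0L
          pend_run[[i]] <- integer(0)
          last_obs[i] <- k
        }
      } else if (gnew != cur[i]) {              # candidate switch
        pend_grp[i] <- gnew
        pend_snp[i] <- k
        pend_run[[i]] <- k
        pend_conf[i] <- 0L
        if (persistence <= 0L) {
          commit(i)
          last_obs[i] <- k
        }
      } else {                                  # confirmation of the label
        last_obs[i] <- k
      }
    }
  }
  # unresolved pending switches at chromosome end cannot be contradicted
  for (i in which(pend_grp != 0L)) commit(i)

  for (i in seq_len(n)) {
    st <- seg_start[[i]]
    if (is.null(st)) next
    ends <- c(st[-1L] - 1L, m)
    for (s in seq_along(st)) labels[i, st[s]:ends[s]] <- seg_lab[[i]][s]
  }
  o <- order(err_id, err_snp)
  attr(labels, "genotyping_errors") <-
    data.frame(individual_id = rownames(g)[err_id][o],
               snp = err_snp[o], stringsAsFactors = FALSE)
  attr(labels, "informative") <- informative
  labels
}

#' Recombination events from a block matrix
#'
#' An event is a change of an individual's label between its nearest
#' determined labels bracketing an interval; a switch across a run of
#' undetermined (0) labels is assigned to the interval following the last
#' determined SNP before the gap.
#'
#' @param b block label matrix in `{0, 1, 2}` from [build_blocks()] or
#'   [compare_haplotypes()].
#' @return integer matrix, rows = individuals, columns = the
#'   `ncol(b) - 1` inter-SNP intervals, entries 0/1.
#' @export
recombination_events <- function(b) {
  n <- nrow(b)
  m <- ncol(b)
  ev <- matrix(0L, n, m - 1L)
  rownames(ev) <- rownames(b)
  for (i in seq_len(n)) {
    d <- which(b[i, ] != 0L)
    if (length(d) < 2L) next
    lab <- b[i, d]
    chg <- which(lab[-1L] != lab[-length(lab)])
    if (length(chg)) ev[i, d[chg]] <- 1L
  }
  ev
}

#' Recombination counts per individual
#' @param b block label matrix.
#' @return named integer vector of per-individual event counts.
#' @export
count_recombinations <- function(b) {
  cnt <- rowSums(recombination_events(b))
  stats::setNames(as.integer(cnt), names(cnt))
}

#' Label an offspring's haplotypes against its sire's haplotypes
#'
#' For each offspring haplotype and SNP, the label is the sire strand that
#' matches the offspring allele when exactly one strand does; it is 0 when
#' both or neither match (sire homozygous or contradiction) or when any
#' allele is missing (9). The result has the same block structure as
#' [build_blocks()], so a single parent-offspring pair suffices to
#' evaluate phasing results from any program.
#'
#' @param offspring_hap 2 x n_snps integer matrix of offspring alleles in
#'   `{0, 1, 9}`.
#' @param sire_hap 2 x n_snps integer matrix of sire strand alleles in
#'   `{0, 1, 9}`.
#' @return 2 x n_snps integer label matrix in `{0, 1, 2}`.
#' @export
compare_haplotypes <- function(offspring_hap, sire_hap) {
  if (nrow(offspring_hap) != 2L || nrow(sire_hap) != 2L ||
      ncol(offspring_hap) != ncol(sire_hap))
    stop("offspring and sire haplotypes must both be 2 x n_snps")
  m <- ncol(sire_hap)
  out <- matrix(0L, 2L, m, dimnames = dimnames(offspring_hap))
  for (r in 1:2) {
    a <- offspring_hap[r, ]
    m1 <- sire_hap[1L, ] == a
    m2 <- sire_hap[2L, ] == a
    ok <- a != 9L & sire_hap[1L, ] != 9L & sire_hap[2L, ] != 9L
    out[r, ok & m1 & !m2] <- 1L
    out[r, ok & m2 & !m1] <- 2L
  }
  out
}

#' Per-interval recombination profile across families
#'
#' Aggregates event matrices over families sharing the same map slice. A
#' meiosis is informative at an interval when the individual carries a
#' determined label on both sides of it, so rates are events per
#' informative meiosis. Local rate variation and mapping errors show up as
#' interval-level spikes.
#'
#' @param blocks list of block label matrices (one per family) on the same
#'   SNP set.
#' @return data.frame with one row per interval: `interval`, `events`,
#'   `meioses`, `rate`, `n_families_with_event`; the number of families is
#'   attached as `attr(, "n_families")`.
#' @export
recombination_profile <- function(blocks) {
  if (!length(blocks)) stop("need at least one block matrix")
  m <- ncol(blocks[[1L]])
  if (any(vapply(blocks, ncol, 0L) != m))
    stop("all block matrices must share the same SNP set")
  n_int <- m - 1L
  events <- integer(n_int)
  meioses <- integer(n_int)
  fam_with <- integer(n_int)
  for (b in blocks) {
    ev <- recombination_events(b)
    events <- events + as.integer(colSums(ev))
    # informative: determined label somewhere at <= k and somewhere > k
    det <- b != 0L
    left <- t(apply(det, 1L, cumsum)) > 0L
    right <- t(apply(det[, m:1, drop = FALSE], 1L, cumsum))[, m:1,
                                                           drop = FALSE] > 0L
    inf <- left[, -m, drop = FALSE] & right[, -1L, drop = FALSE]
    meioses <- meioses + as.integer(colSums(inf))
    fam_with <- fam_with + (colSums(ev) > 0L)
  }
  out <- data.frame(interval = seq_len(n_int), events = events,
                    meioses = meioses,
                    rate = ifelse(meioses > 0L, events / meioses, 0),
                    n_families_with_event = fam_with)
  attr(out, "n_families") <- length(blocks)
  out
}

#' Flag putative map errors from a recombination profile
#'
#' A misplaced SNP produces an excess of apparent recombinations at its
#' flanking intervals, and - unlike a genuine recombination hotspot sampled
#' at desk scale - does so consistently across families. An interval is
#' flagged when its event rate exceeds `rate_factor` times the baseline
#' rate and at least `min_families` families independently show an event
#' there; the baseline is the median over intervals with at least one
#' event (the resolution floor of the profile), since the plain median
#' per-interval rate is zero on any realistic map. Both SNPs flanking a
#' flagged interval are reported.
#'
#' @param profile data.frame from [recombination_profile()] (with its
#'   `n_families` attribute).
#' @param min_families minimum number of families that must independently
#'   show an event at the interval (default 3). Profiles built from fewer
#'   families than this return no flags.
#' @param rate_factor multiple of the baseline rate to exceed (default 5).
#' @return integer vector of flagged SNP indices, with the flagged
#'   intervals as `attr(, "intervals")`.
#' @export
flag_map_errors <- function(profile, min_families = 3L, rate_factor = 5) {
  n_fam <- attr(profile, "n_families")
  if (is.null(n_fam) || n_fam < min_families) {
    out <- integer(0)
    attr(out, "intervals") <- integer(0)
    return(out)
  }
  pos <- profile$rate[profile$events > 0L]
  if (!length(pos)) {
    out <- integer(0)
    attr(out, "intervals") <- integer(0)
    return(out)
  }
  baseline <- stats::median(pos)
  hit <- profile$rate > rate_factor * baseline &
    profile$n_families_with_event >= min_families
  iv <- profile$interval[hit]
  out <- sort(unique(c(iv, iv + 1L)))
  attr(out, "intervals") <- iv
  out
}
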