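#' Opposing-homozygote threshold from regression coefficients
#'
#' Linear-in-markers threshold `round(intercept + slope * n_snps)`,
#' floored at zero with a warning. No default coefficients are shipped:
#' population-specific values must be supplied (coefficients fitted on
#' one population transfer poorly to another).
#'
#' @param n_snps number of markers.
#' @param intercept,slope regression coefficients.
#' @return non-negative integer threshold.
#' @export
regression_threshold <- function(n_snps, intercept, slope) {
  thr <- round(intercept + slope * n_snps)
  if (thr < 0) {
    warning("regression threshold negative (", thr, "); clamped to 0")
    thr <- 0
  }
  as.integer(thr)
}

#' Reconstruct half-sib family groups by recursive clustering
#'
#' Computes the opposing-homozygote matrix, then recursively bisects the
#' individuals: each individual's row of OH counts (restricted to the
#' current set) is its feature vector, Manhattan distances between rows
#' are clustered with Ward's minimum variance method (the Lance-Williams
#' `ward.D` update applied directly to the Manhattan matrix), and the tree
#' is cut into two. A cluster is terminal when it satisfies the separation
#' criterion - for the `manual`, `regression` and `calus` criteria, all
#' within-cluster pairwise OH counts at or below the threshold; for the
#' `recombination` criterion, every member needing at most `max_rec`
#' recombinations on the reference chromosome when blocked with its
#' cluster - or when it has at most two members (a further bisection is
#' meaningless; such clusters failing the criterion are left unassigned
#' and flagged). Terminal groups are labelled 1, 2, ... ordered by their
#' smallest member id, so the output is invariant to the input ordering.
#'
#' @param g genotype matrix (all candidate half-sibs, no parents).
#' @param method separation criterion: `"manual"`, `"regression"`,
#'   `"calus"` (allele-frequency expectations) or `"recombination"`.
#' @param max_oh threshold for the manual criterion.
#' @param intercept,slope coefficients for the regression criterion (no
#'   defaults; see [regression_threshold()]).
#' @param freqs allele frequencies for the calus criterion; estimated from
#'   `g` when `NULL`.
#' @param map SNP map, required for the recombination criterion.
#' @param chromosome reference chromosome for the recombination
#'   criterion; defaults to the chromosome with the smallest base-pair
#'   span (shorter chromosomes recombine less and separate families more
#'   cleanly).
#' @param max_rec maximum recombinations allowed per member (default 10).
#' @return named integer vector of group labels (0 = unassigned), with
#'   attributes `threshold` (where applicable) and `flagged` (ids of
#'   criterion-failing terminal clusters).
#' @export
reconstruct_families <- function(g, method = c("manual", "regression",
                                               "calus", "recombination"),
                                 max_oh = NULL, intercept = NULL,
                                 slope = NULL, freqs = NULL, map = NULL,
                                 chromosome = NULL, max_rec = 10L) {
  method <- match.arg(method)
  g <- validate_genotypes(g)
  if (nrow(g) < 2L) stop("need at least 2 individuals")
  oh <- oh_matrix(g)
  threshold <- NULL
  if (method == "manual") {
    if (is.null(max_oh)) stop("manual criterion needs max_oh")
    threshold <- max_oh
  } else if (method == "regression") {
    if (is.null(intercept) || is.null(slope))
      stop("regression criterion needs explicit intercept and slope")
    threshold <- regression_threshold(ncol(g), intercept, slope)
  } else if (method == "calus") {
    if (is.null(freqs)) freqs <- allele_frequencies(g)
    threshold <- expected_oh(freqs)$cutoff
  } else {
    if (is.null(map)) stop("recombination criterion needs a map")
    bundle <- align_inputs(g, map)
    g <- bundle$genotypes
    if (is.null(chromosome)) {
      span <- vapply(bundle$slices, function(ix) {
        diff(range(map$position_bp[ix]))
      }, 0)
      chromosome <- names(which.min(span))
    }
    chr_cols <- bundle$slices[[as.character(chromosome)]]
    if (is.null(chr_cols)) stop("chromosome not in map: ", chromosome)
  }

  criterion_ok <- function(idx) {
    if (length(idx) < 2L) return(TRUE)
    if (method != "recombination") {
      return(all(oh[idx, idx] <= threshold))
    }
    b <- suppressWarnings(build_blocks(g[idx, chr_cols, drop = FALSE]))
    all(count_recombinations(b) <= max_rec)
  }

  groups <- list()
  flagged <- character(0)
  recurse <- function(idx) {
    if (criterion_ok(idx)) {
      groups[[length(groups) + 1L]] <<- idx
      return(invisible())
    }
    if (length(idx) <= 2L) {
      flagged <<- c(flagged, rownames(g)[idx])
      return(invisible())
    }
    d <- stats::dist(oh[idx, idx, drop = FALSE], method = "manhattan")
    hc <- stats::hclust(d, method = "ward.D")
    cut <- stats::cutree(hc, k = 2L)
    recurse(idx[cut == 1L])
    recurse(idx[cut == 2L])
  }
  recurse(seq_len(nrow(g)))

  out <- stats::setNames(integer(nrow(g)), rownames(g))
  if (length(groups)) {
    min_id <- vapply(groups, function(ix) min(rownames(g)[ix]), "")
    groups <- groups[order(min_id)]
    for (k in seq_along(groups)) out[groups[[k]]] <- k
  }
  attr(out, "threshold") <- threshold
  attr(out, "flagged") <- flagged
  out
}

#' Match reconstructed family groups to candidate sires
#'
#' Assigns to each family group the candidate sire with the smallest total
#' opposing-homozygote count against the group members. Ties are broken
#' deterministically towards the smaller sire id and flagged; a sire
#' claimed by more than one group (possible with overlapping generations)
#' is also flagged rather than rejected.
#'
#' @param assignment named group-label vector from
#'   [reconstruct_families()] (0 = unassigned individuals are skipped).
#' @param g_offspring offspring genotype matrix (rows must cover the names
#'   of `assignment`).
#' @param g_sires candidate sire genotype matrix on the same SNPs.
#' @return pedigree data.frame (`individual_id`, `sire_id`) with
#'   attributes `group_sires` (group -> sire table with total OH),
#'   `tied_groups` and `shared_sires`.
#' @export
name_families <- function(assignment, g_offspring, g_sires) {
  if (nrow(g_sires) < 1L) stop("no candidate sires supplied")
  if (ncol(g_offspring) != ncol(g_sires))
    stop("offspring and sire genotypes must share the SNP panel")
  ids <- names(assignment)
  g_offspring <- g_offspring[ids, , drop = FALSE]
  # cross OH counts: sires x offspring
  h0s <- matrix(as.numeric(g_sires == 0L), nrow(g_sires))
  h2s <- matrix(as.numeric(g_sires == 2L), nrow(g_sires))
  h0o <- matrix(as.numeric(g_offspring == 0L), nrow(g_offspring))
  h2o <- matrix(as.numeric(g_offspring == 2L), nrow(g_offspring))
  cross <- tcrossprod(h0s, h2o) + tcrossprod(h2s, h0o)
  dimnames(cross) <- list(rownames(g_sires), ids)

  labels <- sort(unique(assignment[assignment > 0L]))
  sire_of_group <- character(0)
  tied <- integer(0)
  rows <- list()
  for (gl in labels) {
    members <- ids[assignment == gl]
    tot <- rowSums(cross[, members, drop = FALSE])
    best <- sort(names(tot)[tot == min(tot)])
    if (length(best) > 1L) tied <- c(tied, gl)
    sire_of_group[as.character(gl)] <- best[1L]
    rows[[length(rows) + 1L]] <-
      data.frame(group = gl, sire_id = best[1L], total_oh = min(tot),
                 stringsAsFactors = FALSE)
  }
  shared <- unique(sire_of_group[duplicated(sire_of_group)])
  ped <- data.frame(
    individual_id = ids,
    sire_id = ifelse(assignment > 0L,
                     sire_of_group[as.character(assignment)],
                     NA_character_),
    stringsAsFactors = FALSE)
  rownames(ped) <- NULL
  attr(ped, "group_sires") <- do.call(rbind, rows)
  attr(ped, "tied_groups") <- tied
  attr(ped, "shared_sires") <- shared
  ped
}
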