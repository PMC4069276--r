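GENO_CODES <- c(0L, 1L, 2L, 9L)

detect_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) return("\t")
  if (grepl(",", line)) return(",")
  " "
}

#' Read a genotype matrix
#'
#' Reads an individuals x SNP genotype file. In the default `matrix` dialect
#' the file has a header row of SNP ids and the first column holds individual
#' ids; cells are coded 0/1/2 (count of the reference allele) with 9 for a
#' missing genotype. The `plink_ped` dialect reads a PLINK-style .ped file
#' (six leading columns, then two allele columns per SNP) and converts each
#' SNP to a 0/1/2 count of the first allele observed at that SNP; any
#' missing allele (`0`) gives 9. Heterozygote phase in .ped is ignored.
#'
#' @param path path to the genotype file.
#' @param dialect `"matrix"` (default) or `"plink_ped"`.
#' @param sep field separator; auto-detected among tab/comma/space when `NULL`.
#' @param snp_ids optional SNP ids for the `plink_ped` dialect (e.g. from an
#'   accompanying .map read with [read_snp_map()]).
#' @return integer matrix with individual ids as rownames and SNP ids as
#'   colnames; every cell in `{0, 1, 2, 9}`.
#' @seealso [write_genotypes()], [read_snp_map()], [align_inputs()]
#' @export
read_genotypes <- function(path, dialect = c("matrix", "plink_ped"),
                           sep = NULL, snp_ids = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (is.null(sep)) sep <- detect_sep(path)
  if (dialect == "plink_ped") return(read_ped(path, sep, snp_ids))
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- tab[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate individual id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  g <- suppressWarnings(matrix(as.integer(vals), nrow = nrow(vals),
                               dimnames = list(ids, colnames(vals))))
  bad <- which(is.na(g) | !(g %in% GENO_CODES))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(g))
    stop(sprintf("invalid genotype %s at row %d (%s), column %d (%s): must be 0/1/2/9",
                 vals[bad[1L]], rc[1L], ids[rc[1L]], rc[2L],
                 colnames(g)[rc[2L]]))
  }
  validate_genotypes(g)
}

read_ped <- function(path, sep, snp_ids) {
  tab <- utils::read.table(path, header = FALSE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 8L || (ncol(tab) - 6L) %% 2L != 0L)
    stop("malformed .ped file: expected 6 columns plus 2 per SNP")
  ids <- tab[[2L]]
  if (anyDuplicated(ids)) stop("duplicate individual id(s) in .ped")
  n_snp <- (ncol(tab) - 6L) %/% 2L
  alle <- as.matrix(tab[, -(1:6), drop = FALSE])
  g <- matrix(9L, nrow(alle), n_snp)
  for (k in seq_len(n_snp)) {
    a1 <- alle[, 2L * k - 1L]
    a2 <- alle[, 2L * k]
    seen <- setdiff(unique(c(a1, a2)), "0")
    if (length(seen) > 2L)
      stop("SNP ", k, " in .ped has more than two alleles")
    ref <- if (length(seen)) seen[1L] else "0"
    ok <- a1 != "0" & a2 != "0"
    g[ok, k] <- (a1[ok] == ref) + (a2[ok] == ref)
  }
  if (is.null(snp_ids)) snp_ids <- paste0("SNP", seq_len(n_snp))
  dimnames(g) <- list(ids, snp_ids)
  validate_genotypes(g)
}

validate_genotypes <- function(g) {
  if (!is.matrix(g)) stop("genotypes must be a matrix")
  storage.mode(g) <- "integer"
  if (!all(g %in% GENO_CODES)) stop("genotype cells must be in {0, 1, 2, 9}")
  if (is.null(rownames(g))) rownames(g) <- paste0("ID", seq_len(nrow(g)))
  if (anyDuplicated(rownames(g))) stop("duplicate individual ids")
  g
}

#' Write a genotype matrix
#'
#' Inverse of [read_genotypes()] (matrix dialect): header of SNP ids,
#' first column of individual ids, tab-separated by default.
#' @param g integer genotype matrix (rownames = individual ids).
#' @param path output path.
#' @param sep field separator.
#' @export
write_genotypes <- function(g, path, sep = "\t") {
  g <- validate_genotypes(g)
  df <- data.frame(id = rownames(g), g, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNP map
#'
#' Three columns: SNP id, chromosome, base-pair position (1-based). The map
#' is returned in canonical order (chromosome, then position); if the input
#' was not already sorted, the applied permutation is attached as
#' `attr(, "permutation")` (and `attr(, "was_unsorted")` is `TRUE`) so
#' genotype columns can be permuted identically. Only the order of SNPs is
#' ever used by the algorithms, never the physical distances.
#'
#' @param path path to the map file (header expected for the default
#'   dialect).
#' @param dialect `"table"` (snp, chr, pos with header) or `"plink"`
#'   (headerless PLINK .map: chr, snp, cM, pos).
#' @param sep separator; auto-detected when `NULL`.
#' @return data.frame with columns `snp_id`, `chromosome`, `position_bp`.
#' @export
read_snp_map <- function(path, dialect = c("table", "plink"), sep = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("map file not found: ", path)
  if (is.null(sep)) sep <- detect_sep(path)
  if (dialect == "plink") {
    tab <- utils::read.table(path, header = FALSE, sep = sep,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 4L) stop(".map file needs 4 columns (chr, snp, cM, pos)")
    map <- data.frame(snp_id = as.character(tab[[2L]]),
                      chromosome = as.character(tab[[1L]]),
                      position_bp = as.integer(tab[[4L]]),
                      stringsAsFactors = FALSE)
    return(validate_snp_map(map))
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("map file needs >= 3 columns (snp, chr, pos)")
  map <- data.frame(snp_id = as.character(tab[[1L]]),
                    chromosome = as.character(tab[[2L]]),
                    position_bp = as.integer(tab[[3L]]),
                    stringsAsFactors = FALSE)
  validate_snp_map(map)
}

validate_snp_map <- function(map) {
  if (anyDuplicated(map$snp_id))
    stop("duplicated snp_id: ",
         paste(unique(map$snp_id[duplicated(map$snp_id)]), collapse = ", "))
  if (any(is.na(map$position_bp)) || any(map$position_bp < 0L))
    stop("map positions must be non-negative integers")
  ord <- order(chromosome_rank(map$chromosome), map$position_bp)
  unsorted <- !identical(ord, seq_len(nrow(map)))
  out <- map[ord, , drop = FALSE]
  rownames(out) <- NULL
  dup <- stats::ave(out$position_bp, out$chromosome,
                    FUN = function(x) duplicated(x))
  if (any(dup == 1)) stop("duplicate position within a chromosome")
  attr(out, "permutation") <- ord
  attr(out, "was_unsorted") <- unsorted
  if (unsorted) warning("map was not in (chromosome, position) order; sorted")
  out
}

# numeric chromosome names sort numerically, others lexically after them
chromosome_rank <- function(chr) {
  num <- suppressWarnings(as.numeric(chr))
  r <- rank(num, na.last = "keep", ties.method = "min")
  other <- is.na(num)
  if (any(other)) {
    r[other] <- max(0, r[!other]) + rank(chr[other], ties.method = "min")
  }
  r
}

#' @rdname read_snp_map
#' @param map SNP map data.frame as returned by `read_snp_map()`.
#' @export
write_snp_map <- function(map, path, sep = "\t") {
  utils::write.table(map[c("snp_id", "chromosome", "position_bp")], path,
                     sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pedigree file
#'
#' Two columns: individual id and sire id. A sire field of `"0"`, empty or
#' `NA` means unknown (the usual livestock-file convention).
#' @param path path to the pedigree file.
#' @param sep separator; auto-detected when `NULL`.
#' @return data.frame with columns `individual_id`, `sire_id` (`NA` =
#'   unknown sire).
#' @export
read_pedigree <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  if (is.null(sep)) sep <- detect_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  ped <- data.frame(individual_id = tab[[1L]], sire_id = tab[[2L]],
                    stringsAsFactors = FALSE)
  validate_pedigree(ped)
}

validate_pedigree <- function(ped) {
  ped$sire_id[ped$sire_id %in% c("0", "") | is.na(ped$sire_id)] <- NA_character_
  if (anyDuplicated(ped$individual_id)) stop("duplicate individual_id in pedigree")
  self <- !is.na(ped$sire_id) & ped$individual_id == ped$sire_id
  if (any(self))
    stop("individual recorded as its own sire: ",
         paste(ped$individual_id[self], collapse = ", "))
  rownames(ped) <- NULL
  ped
}

#' @rdname read_pedigree
#' @param ped pedigree data.frame.
#' @export
write_pedigree <- function(ped, path, sep = "\t") {
  out <- ped[c("individual_id", "sire_id")]
  out$sire_id[is.na(out$sire_id)] <- "0"
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align genotypes, map and pedigree
#'
#' Validates that the three inputs describe the same data: the genotype
#' matrix must have one column per map SNP (matched by id when both carry
#' names) and pedigree ids not present among the genotyped individuals are
#' flagged rather than dropped. Returns the validated bundle together with
#' per-chromosome column index slices, within which map positions are
#' strictly increasing.
#'
#' @param genotypes integer genotype matrix.
#' @param map SNP map (see [read_snp_map()]).
#' @param pedigree optional pedigree data.frame.
#' @return list with elements `genotypes`, `map`, `pedigree`, `slices`
#'   (named list of integer column indices per chromosome) and `flagged`
#'   (pedigree ids absent from the genotypes).
#' @export
align_inputs <- function(genotypes, map, pedigree = NULL) {
  genotypes <- validate_genotypes(genotypes)
  if (ncol(genotypes) != nrow(map))
    stop("genotypes have ", ncol(genotypes), " SNP columns but map lists ",
         nrow(map), " SNPs")
  gn <- colnames(genotypes)
  if (!is.null(gn) && any(gn %in% map$snp_id)) {
    if (!setequal(gn, map$snp_id)) {
      miss <- setdiff(map$snp_id, gn)
      stop("SNP ids disagree between genotypes and map; e.g. missing: ",
           paste(utils::head(miss, 5L), collapse = ", "))
    }
    genotypes <- genotypes[, map$snp_id, drop = FALSE]
  }
  flagged <- character(0)
  if (!is.null(pedigree)) {
    flagged <- setdiff(pedigree$individual_id, rownames(genotypes))
  }
  chrs <- unique(map$chromosome)
  slices <- lapply(chrs, function(ch) which(map$chromosome == ch))
  names(slices) <- chrs
  for (ch in chrs) {
    pos <- map$position_bp[slices[[ch]]]
    if (any(diff(pos) <= 0))
      stop("positions not strictly increasing on chromosome ", ch)
  }
  list(genotypes = genotypes, map = map, pedigree = pedigree,
       slices = slices, flagged = flagged)
}
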