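# Worked three-sib family used throughout: sire strands 00000/11111,
# A inherited strand 1 everywhere, B strand 2 everywhere, C recombines
# between SNP 2 and 3. Dams contribute the 0 allele everywhere.
trace_family <- function() {
  rbind(A = c(0L, 0L, 0L, 0L, 0L),
        B = c(2L, 2L, 2L, 2L, 2L),
        C = c(0L, 0L, 2L, 2L, 2L))
}

# strip dimnames and ancillary attributes for bare-value comparisons
bare <- function(m) matrix(as.vector(m), nrow(m))

# brute-force pairwise OH oracle: explicit double loop, per-locus check
oh_bruteforce <- function(g) {
  n <- nrow(g)
  out <- matrix(0L, n, n, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cnt <- 0L
      for (k in seq_len(ncol(g))) {
        a <- g[i, k]; b <- g[j, k]
        if (a != 9L && b != 9L && a + b == 2L && a != 1L) cnt <- cnt + 1L
      }
      out[i, j] <- cnt
    }
  }
  out
}

random_genotypes <- function(n, m, missing_rate = 0.05) {
  g <- matrix(sample(c(0L, 1L, 2L), n * m, replace = TRUE), n, m)
  g[matrix(stats::runif(n * m) < missing_rate, n, m)] <- 9L
  rownames(g) <- sprintf("R%02d", seq_len(n))
  g
}

# does a group assignment reproduce the true family partition exactly?
partition_matches <- function(assignment, true_sires) {
  if (any(assignment == 0L)) return(FALSE)
  tab <- table(assignment, true_sires)
  nrow(tab) == length(unique(true_sires)) &&
    all(rowSums(tab > 0L) == 1L) && all(colSums(tab > 0L) == 1L)
}
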