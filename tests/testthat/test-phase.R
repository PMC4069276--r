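test_that("sire inference reproduces the worked family and ambiguity rule", {
  g <- trace_family()
  b <- build_blocks(g)
  sire <- infer_sire_haplotypes(b, g)
  expect_identical(unname(sire[1L, ]), rep(0L, 5))
  expect_identical(unname(sire[2L, ]), rep(1L, 5))
  # group mean exactly 1 cannot separate paternal from maternal: uncalled
  g2 <- rbind(a = c(0L, 0L), b = c(2L, 2L))
  b2 <- matrix(1L, 2L, 2L, dimnames = dimnames(g2))
  expect_true(all(infer_sire_haplotypes(b2, g2) == 9L))
  # empty group at a SNP stays uncalled
  b3 <- build_blocks(trace_family())
  b3[, 1L] <- c(1L, 1L, 1L)
  expect_equal(unname(infer_sire_haplotypes(b3, trace_family())[2L, 1L]), 9L)
})

test_that("called sire alleles are essentially always right on clean data", {
  sim <- simulate_halfsib(n_families = 4, family_size = 8, n_snps = 2000,
                          seed = 41)
  for (fam in sim$truth$families) {
    g <- sim$genotypes[rownames(fam$transmission), ]
    b <- build_blocks(g)
    sire <- infer_sire_haplotypes(b, g)
    called <- sire != 9L
    truth <- fam$sire_haplotypes
    acc <- max(mean(sire[called] == truth[called]),
               mean(sire[called] == truth[2:1, ][called]))
    expect_gte(acc, 0.99)
    expect_gt(mean(called), 0.3)
  }
})

test_that("phase_family overlays blocks on sire strands and subtracts", {
  g <- trace_family()
  b <- build_blocks(g)
  sire <- infer_sire_haplotypes(b, g)
  ph <- phase_family(g, b, sire)
  expect_identical(unname(ph$paternal["C", ]), c(0L, 0L, 1L, 1L, 1L))
  expect_identical(unname(ph$maternal["C", ]), c(0L, 0L, 1L, 1L, 1L))
  expect_identical(nrow(ph$conflicts), 0L)
  # label 0 everywhere: everything uncalled
  ph0 <- phase_family(g, matrix(0L, 3, 5, dimnames = dimnames(g)), sire)
  expect_true(all(ph0$paternal == 9L) && all(ph0$maternal == 9L))
  # contradicting homozygote voids the paternal call and is logged
  g3 <- g
  g3["A", 3L] <- 2L  # block says strand 1 (allele 0), genotype is hom 2
  ph3 <- phase_family(g3, b, sire)
  expect_equal(unname(ph3$paternal["A", 3L]), 9L)
  expect_identical(ph3$conflicts$individual_id, "A")
  expect_identical(ph3$conflicts$snp, 3L)
})

test_that("paternal + maternal reconstructs the genotype wherever called", {
  sim <- simulate_halfsib(n_families = 5, family_size = 8, n_snps = 500,
                          missing_rate = 0.02, seed = 53)
  for (fam in sim$truth$families) {
    g <- sim$genotypes[rownames(fam$transmission), ]
    b <- build_blocks(g)
    sire <- infer_sire_haplotypes(b, g)
    ph <- phase_family(g, b, sire)
    full <- ph$paternal != 9L & ph$maternal != 9L & g != 9L
    expect_true(all((ph$paternal + ph$maternal)[full] == g[full]))
    # maternal alleles are dam gametes: block mislabels near switch
    # windows can flip a few het-site calls, but only a few
    expect_gte(mean(ph$maternal[full] == fam$maternal[full]), 0.99)
  }
})

test_that("label swap flips sire strands but not offspring haplotypes", {
  sim <- simulate_halfsib(n_families = 1, family_size = 8, n_snps = 400,
                          seed = 61)
  g <- sim$genotypes
  b <- build_blocks(g)
  det <- b != 0L
  bs <- b
  bs[det] <- 3L - b[det]
  ph <- phase_family(g, b, infer_sire_haplotypes(b, g))
  ph_s <- phase_family(g, bs, infer_sire_haplotypes(bs, g))
  expect_identical(ph$paternal, ph_s$paternal)
  expect_identical(ph$maternal, ph_s$maternal)
  expect_identical(unname(infer_sire_haplotypes(b, g)),
                   unname(infer_sire_haplotypes(bs, g)[2:1, ]))
})

test_that("impute_paternal follows the scaffold and respects breakpoints", {
  # 10 HD SNPs, LD = every other SNP, no recombination: the sire strand is
  # recovered across the whole LD span; the SNP beyond the last LD marker
  # is a boundary interval and deliberately stays uncalled
  sire <- rbind(rep(0L, 10), rep(1L, 10))
  g <- rbind(a = rep(0L, 10), b = rep(2L, 10), c = rep(0L, 10))
  ld <- seq(1L, 10L, by = 2L)
  imp <- impute_paternal(g[, ld], sire, ld)
  expect_identical(unname(imp$paternal["a", ]), c(rep(0L, 9), 9L))
  expect_identical(unname(imp$paternal["b", ]), c(rep(1L, 9), 9L))
  # recombination between LD SNPs leaves the HD SNPs in between uncalled
  g2 <- rbind(a = c(rep(0L, 6), rep(2L, 4)),
              b = rep(2L, 10),
              c = rep(0L, 10))
  imp2 <- impute_paternal(g2[, ld], sire, ld)
  # a switches between LD SNPs 5 and 7: HD SNP 6 is ambiguous
  expect_identical(unname(imp2$paternal["a", 5:7]), c(0L, 9L, 1L))
  expect_error(impute_paternal(g[, ld], sire, c(1L, 1L, 3L, 5L, 7L)),
               "strictly increasing")
})

test_that("imputation recovers true paternal alleles on simulated families", {
  sim <- simulate_halfsib(n_families = 3, family_size = 8, n_snps = 2000,
                          seed = 71)
  ld <- seq(1L, 2000L, by = 10L)
  for (fam in sim$truth$families) {
    g <- sim$genotypes[rownames(fam$transmission), ]
    b <- build_blocks(g)
    sire <- infer_sire_haplotypes(b, g)
    imp <- impute_paternal(g[, ld], sire, ld)
    sc <- score_against_truth(b, fam, paternal = imp$paternal)
    expect_gte(sc$allele_accuracy, 0.95)
    expect_gte(sc$allele_r2, 0.9)
  }
})

test_that("per-chromosome pipeline is order- and thread-independent", {
  sim <- simulate_halfsib(n_families = 1, family_size = 6, n_snps = 150,
                          n_chromosomes = 2, seed = 83)
  res1 <- phase_halfsib_family(sim$genotypes, sim$map, threads = 1L)
  res2 <- phase_halfsib_family(sim$genotypes, sim$map, threads = 2L)
  expect_identical(res1, res2)
  # equals the concatenation of independent per-chromosome runs
  for (chr in c("1", "2")) {
    cols <- which(sim$map$chromosome == chr)
    g <- sim$genotypes[, cols]
    b <- suppressWarnings(build_blocks(g))
    expect_identical(unname(res1[[chr]]$blocks), unname(b))
    expect_identical(res1[[chr]]$sire,
                     infer_sire_haplotypes(b, g))
  }
})
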