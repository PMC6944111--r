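test_that("SNP QC applies strict missingness and MAF bounds", {
  n <- 20
  d <- rbind(
    ok      = rep(1, n),
    miss15  = c(rep(NA, 3), rep(1, n - 3)),   # 15% missing > 10%
    miss10  = c(rep(NA, 2), rep(1, n - 2)),   # exactly 10%: retained
    mono    = rep(0, n),                      # MAF 0 < 1%
    rare    = c(2, rep(0, n - 1)))            # MAF 5%: retained
  colnames(d) <- sprintf("s%03d", 1:n)
  rownames(d)[1] <- "ok"
  g <- GenotypeExperiment(d)
  kept <- rownames(filterSnps(g, maxMissing = 0.10, mafMin = 0.01))
  expect_setequal(kept, c("ok", "miss10", "rare"))

  # MAF exactly at the bound survives the strict "< 1%" exclusion
  n2 <- 100
  d2 <- rbind(boundary = c(rep(1, 2), rep(0, n2 - 2)))  # f = 0.01
  colnames(d2) <- sprintf("s%03d", 1:n2)
  expect_equal(nrow(filterSnps(GenotypeExperiment(d2), mafMin = 0.01)), 1)
  expect_error(filterSnps(GenotypeExperiment(d2), mafMin = 0.05), "all SNPs")
})

test_that("EM linkage disequilibrium recovers complete LD and independence", {
  dup <- genoFromHaps(500, c(0.3, 0, 0, 0.7), seed = 1)
  ld <- ldEm(dup[1, ], dup[2, ])
  expect_equal(ld$r2, 1, tolerance = 1e-9)
  expect_equal(ld$d_prime, 1, tolerance = 1e-9)
  expect_true(ld$converged)

  set.seed(2)
  a <- rbinom(2000, 2, 0.3); b <- rbinom(2000, 2, 0.4)
  indep <- ldEm(a, b)
  expect_lt(indep$r2, 0.01)

  # monomorphic locus: statistics reported 0 with a flag
  mono <- ldEm(rep(0, 50), rbinom(50, 2, 0.3))
  expect_true(mono$monomorphic)
  expect_equal(mono$r2, 0)
  expect_equal(mono$d_prime, 0)

  expect_error(ldEm(a[1:10], b[1:10]), ">= 20")
})

test_that("EM haplotype frequencies maximize the multinomial likelihood", {
  tables <- list(
    matrix(c(20, 12, 3, 14, 25, 8, 2, 9, 7), 3, 3),
    matrix(c(40, 5, 1, 6, 20, 4, 0, 3, 21), 3, 3),
    matrix(c(10, 10, 10, 10, 10, 10, 10, 10, 10), 3, 3))
  for (cnt in tables) {
    em <- ldEmFromTable(cnt)
    expect_true(em$converged)
    expect_equal(unname(em$hap_freq), unname(gridLdOracle(cnt)),
                 tolerance = 1e-4)
    expect_equal(sum(em$hap_freq), 1, tolerance = 1e-12)
    expect_true(all(em$hap_freq >= 0))
  }
})

test_that("the EM log-likelihood never decreases across iterations", {
  cnt <- matrix(c(20, 12, 3, 14, 25, 8, 2, 9, 7), 3, 3)
  lls <- vapply(1:15, function(k)
    ldEmFromTable(cnt, maxIter = k, tol = 0)$log_lik, 0)
  expect_true(all(diff(lls) >= -1e-10))
})

test_that("LD pruning drops the smaller-weight member of conjunctive pairs", {
  n <- 200
  dup <- genoFromHaps(n, c(0.4, 0, 0, 0.6), seed = 3)
  # rsA/rsB identical (r2 = 1, D' = 1); rsC independent
  set.seed(4)
  d <- rbind(rsA = dup[1, ], rsB = dup[2, ], rsC = rbinom(n, 2, 0.3))
  colnames(d) <- sprintf("s%03d", 1:n)
  g <- GenotypeExperiment(d, chrom = "1", pos = c(1e5, 1.5e5, 2e5))
  w <- data.frame(snp_id = c("rsA", "rsB", "rsC"), beta = c(0.1, 0.2, 0.3))
  pruned <- ldPrune(g, w)
  expect_setequal(rownames(pruned), c("rsB", "rsC"))  # |0.1| < |0.2|

  # surviving set contains no violating pair (exhaustive scan)
  dd <- dosages(pruned)
  for (i in seq_len(nrow(dd) - 1)) for (j in (i + 1):nrow(dd)) {
    ld <- ldEm(dd[i, ], dd[j, ])
    expect_false(ld$d_prime >= 0.95 && ld$r2 > 0.8)
  }

  # idempotence
  again <- ldPrune(pruned, w)
  expect_identical(rownames(again), rownames(pruned))

  # conjunctive rule: D' = 1 but low r2 (rare allele nested in common one)
  nested <- genoFromHaps(2000, c(0.05, 0, 0.45, 0.5), seed = 5)
  ldn <- ldEm(nested[1, ], nested[2, ])
  expect_gt(ldn$d_prime, 0.95)
  expect_lt(ldn$r2, 0.8)
  d2 <- rbind(rsA = nested[1, ], rsB = nested[2, ])
  colnames(d2) <- sprintf("t%04d", 1:2000)
  g2 <- GenotypeExperiment(d2, chrom = "1", pos = c(1e5, 1.5e5))
  expect_equal(nrow(ldPrune(g2, w[1:2, ])), 2)

  # identical SNPs 300 kb apart are outside the window: both retained
  g3 <- GenotypeExperiment(d[1:2, ], chrom = "1", pos = c(1e5, 4e5))
  expect_equal(nrow(ldPrune(g3, w[1:2, ])), 2)
})

test_that("surrogate search is filter-then-argmax with strict bounds", {
  n <- 400
  target <- genoFromHaps(n, c(0.395, 0.005, 0.005, 0.595), seed = 6)  # high LD pair
  weak <- genoFromHaps(n, c(0.2, 0.2, 0.2, 0.4), seed = 7)        # low LD pair
  set.seed(8)
  d <- rbind(target = target[1, ],
             good = target[2, ],
             far = target[1, ],                      # perfect LD but too far
             weak = weak[2, ],
             rare = c(rep(1, 2), rep(0, n - 2)))     # MAF 0.25% < 1%
  colnames(d) <- sprintf("s%04d", 1:n)
  g <- GenotypeExperiment(d, chrom = "1",
                          pos = c(5e5, 6e5, 5e5 + 250000, 55e4, 56e4))
  res <- findSurrogate("target", g)
  expect_equal(res$surrogate, "good")
  expect_gt(res$r2, 0.8)
  expect_gte(res$d_prime, 0.95)

  # oracle: exhaustive filter then argmax over the same criteria
  info <- snpInfo(g)
  cand <- setdiff(rownames(d), "target")
  ok <- vapply(cand, function(s) {
    i <- match(s, info$snp_id)
    maf <- min(mean(d[s, ]) / 2, 1 - mean(d[s, ]) / 2)
    if (abs(info$pos[i] - 5e5) >= 250000 || maf < 0.01) return(NA_real_)
    ld <- ldEm(d["target", ], d[s, ])
    if (ld$d_prime >= 0.95 && ld$r2 > 0.8) ld$r2 else NA_real_
  }, 0)
  expect_equal(res$surrogate, names(which.max(ok)))

  # candidate at exactly 250 kb is excluded even in perfect LD ("far");
  # with "good" removed nothing qualifies
  g2 <- g[c("target", "far", "weak", "rare"), ]
  res2 <- findSurrogate("target", g2)
  expect_true(is.na(res2$surrogate))
  expect_match(res2$reason, "no qualifying")

  # monomorphic target is flagged
  d3 <- rbind(mono = rep(0, n), other = d["good", ])
  colnames(d3) <- colnames(d)
  g3 <- GenotypeExperiment(d3, chrom = "1", pos = c(1e5, 1.2e5))
  expect_match(findSurrogate("mono", g3)$reason, "monomorphic")
})

test_that("the GRS is the weighted dosage sum with mean substitution", {
  d <- matrix(c(2, 1,
                1, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("rs1", "rs2"), c("s1", "s2")))
  g <- GenotypeExperiment(d)
  w <- data.frame(snp_id = c("rs1", "rs2"), beta = c(0.1, 0.2))
  s <- computeGrs(g, w)
  expect_equal(unname(scoreValues(s)), c(0.1 * 2 + 0.2 * 1, 0.1 * 1))
  expect_equal(unname(nFeaturesUsed(s)), c(2L, 2L))

  # all dosages zero -> score zero
  g0 <- GenotypeExperiment(d * 0)
  expect_equal(unname(scoreValues(computeGrs(g0, w))), c(0, 0))

  # missing dosage at a SNP with mean 0.5 and beta 0.2 contributes 0.1
  d2 <- matrix(c(1, 1, 1,
                 NA, 1, 0), 2, 3, byrow = TRUE,
               dimnames = list(c("rs1", "rs2"), c("s1", "s2", "s3")))
  s2 <- computeGrs(GenotypeExperiment(d2), w)
  expect_equal(unname(scoreValues(s2)["s1"]), 0.1 * 1 + 0.2 * 0.5)
  expect_equal(unname(nFeaturesUsed(s2)), c(1L, 2L, 2L))

  expect_error(computeGrs(GenotypeExperiment(d2),
                          data.frame(snp_id = "rsX", beta = 1)),
               "no SNPs shared")
})

test_that("allele flips leave GRS ranks and OR per SD invariant", {
  ch <- smallCohort(seed = 14)
  g <- ch$genotypes
  w <- ch$weights
  base <- computeGrs(g, w)

  # flip every SNP's labels and dosages in the file representation, then
  # let orientation against the weight table restore the effect allele
  info <- snpInfo(g)
  flipped <- GenotypeExperiment(2 - dosages(g), chrom = info$chrom,
                                pos = info$pos,
                                effectAllele = info$other_allele,
                                otherAllele = info$effect_allele)
  restored <- bcrisk:::orientToWeights(flipped, w)
  flip <- computeGrs(restored, w)
  expect_equal(scoreValues(flip), scoreValues(base), tolerance = 1e-12)

  # flipping without re-orientation changes values only by a constant
  naive <- computeGrs(GenotypeExperiment(2 - dosages(g)), w)
  diffs <- scoreValues(naive) - scoreValues(base) * (-1)
  expect_lt(diff(range(diffs)), 1e-10)
  o1 <- orPerSd(base, ch$labels)
  o2 <- orPerSd(ScoreSet(sampleIds(naive), -scoreValues(naive), "grs"),
                ch$labels)
  expect_equal(o1$or, o2$or, tolerance = 1e-8)
})

test_that("GRS discrimination grows with the planted effect variance", {
  set.seed(31)
  grid <- c(0.0, 0.12, 0.3)
  meds <- vapply(grid, function(b) {
    aucs <- vapply(1:15, function(r) {
      ch <- simulateCohort(simulationSpec(
        nCases = 60, nControls = 140, nCpgs = 4, nSnps = 20,
        snpBeta = b, cpgEffect = 0, envVariables = nullEnvVariables(),
        poolFactor = 5, seed = 1000 * b + r))
      computeAuc(computeGrs(ch$genotypes, ch$weights), ch$labels)$auc
    }, 0)
    median(aucs)
  }, 0)
  expect_true(all(diff(meds) > 0))
})
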