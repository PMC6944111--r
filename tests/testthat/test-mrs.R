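test_that("probe filter removes CpGs strictly above the missingness bound", {
  b <- randomBeta(3, 10)
  b[1, 1:2] <- NA  # 20% missing > 10% bound
  m <- MethylationExperiment(b)
  expect_identical(rownames(filterProbes(m, 0.10)), c("cg002", "cg003"))
  # exactly at the bound is retained; a vacuous bound removes nothing
  b2 <- randomBeta(2, 10); b2[1, 1] <- NA  # 10% missing
  expect_equal(nrow(filterProbes(MethylationExperiment(b2), 0.10)), 2)
  expect_equal(nrow(filterProbes(m, 1.0)), 3)
  expect_identical(betaValues(filterProbes(m, 0.5)), b)  # identity when all pass
  ball <- b; ball[] <- NA
  expect_error(filterProbes(MethylationExperiment(ball), 0.1), "all probes")
})

test_that("control quartiles use linear interpolation over controls only", {
  b <- matrix(NA_real_, 2, 8,
              dimnames = list(c("cg001", "cg002"), sprintf("s%03d", 1:8)))
  b[1, ] <- c(0.9, 0.9, 0.9, 0.9, 0.1, 0.2, 0.3, 0.4)  # cases then controls
  b[2, ] <- 0.5
  labels <- makeLabels(4, 4)
  thr <- controlQuartiles(MethylationExperiment(b), labels)
  # type-7 interpolation on {0.1,0.2,0.3,0.4}
  expect_equal(thr$q1[1], 0.175)
  expect_equal(thr$q3[1], 0.325)
  # degenerate constant column: q1 = q3 = c
  expect_equal(thr$q1[2], 0.5)
  expect_equal(thr$q3[2], 0.5)
  expect_equal(thr$n_controls_used, c(4L, 4L))

  # perturbing every case beta must not move the thresholds
  b2 <- b; b2[, 1:4] <- runif(8)
  thr2 <- controlQuartiles(MethylationExperiment(b2), labels)
  expect_equal(thr2$q1, thr$q1)
  expect_equal(thr2$q3, thr$q3)

  # < 4 non-missing control values flags the CpG unusable
  b3 <- b; b3[1, 5:6] <- NA
  expect_warning(thr3 <- controlQuartiles(MethylationExperiment(b3), labels),
                 "unusable")
  expect_false(thr3$usable[1])
})

test_that("MRS counting matches an exhaustive hand-count oracle", {
  set.seed(42)
  for (rep in 1:20) {
    nCpg <- sample(3:8, 1); nSam <- sample(5:12, 1)
    b <- matrix(runif(nCpg * nSam), nCpg, nSam,
                dimnames = list(sprintf("cg%03d", 1:nCpg),
                                sprintf("s%03d", 1:nSam)))
    b[runif(length(b)) < 0.15] <- NA
    panel <- data.frame(cpg_id = rownames(b),
                        direction = sample(c("hyper", "hypo"), nCpg, TRUE),
                        set_label = "t")
    thr <- data.frame(cpg_id = rownames(b),
                      q1 = runif(nCpg, 0.1, 0.4), q3 = runif(nCpg, 0.6, 0.9),
                      n_controls_used = 10L, usable = TRUE)
    got <- computeMrs(MethylationExperiment(b), panel, thr)
    # oracle: direct per-cell count
    for (s in seq_len(nSam)) {
      want <- 0
      for (j in seq_len(nCpg)) {
        v <- b[j, s]
        if (is.na(v)) next
        if (panel$direction[j] == "hyper" && v > thr$q3[j]) want <- want + 1
        if (panel$direction[j] == "hypo" && v < thr$q1[j]) want <- want + 1
      }
      expect_identical(unname(scoreValues(got)[s]), as.numeric(want))
    }
    expect_true(all(scoreValues(got) == round(scoreValues(got))))
    expect_true(all(scoreValues(got) <= nCpg))
  }
})

test_that("ties sit outside the quartile count and missing panels score 0", {
  b <- matrix(c(0.8, 0.1), 2, 3,
              dimnames = list(c("cg001", "cg002"), c("s1", "s2", "s3")))
  panel <- data.frame(cpg_id = c("cg001", "cg002"),
                      direction = c("hyper", "hypo"), set_label = "t")
  thr <- data.frame(cpg_id = c("cg001", "cg002"), q1 = c(0.2, 0.1),
                    q3 = c(0.8, 0.6), n_controls_used = 4L, usable = TRUE)
  # betas exactly at their thresholds: strict inequalities -> score 0
  s <- computeMrs(MethylationExperiment(b), panel, thr)
  expect_equal(unname(scoreValues(s)), c(0, 0, 0))

  # a fully missing sample scores 0 with n_features_used 0 and a warning
  b2 <- b; b2[, 1] <- NA
  expect_warning(s2 <- computeMrs(MethylationExperiment(b2), panel, thr),
                 "no non-missing")
  expect_equal(unname(scoreValues(s2)["s1"]), 0)
  expect_equal(unname(nFeaturesUsed(s2)["s1"]), 0L)

  # panel CpGs absent from the matrix are dropped, not fatal
  panel3 <- rbind(panel, data.frame(cpg_id = "cg999", direction = "hyper",
                                    set_label = "t"))
  s3 <- computeMrs(MethylationExperiment(b), panel3, thr)
  expect_equal(scoreValues(s3), scoreValues(s))
  expect_error(computeMrs(MethylationExperiment(b),
                          data.frame(cpg_id = "cg999", direction = "hyper",
                                     set_label = "t"), thr),
               "empty")
})

test_that("raising one hyper-CpG beta never lowers that sample's MRS", {
  set.seed(7)
  ch <- smallCohort(seed = 7)
  m <- ch$methylation
  thr <- controlQuartiles(m, ch$labels)
  base <- computeMrs(m, ch$panel, thr)
  hyperCpg <- ch$panel$cpg_id[ch$panel$direction == "hyper"][1]
  b <- betaValues(m)
  for (step in c(0.05, 0.2, 0.5)) {
    b2 <- b
    b2[hyperCpg, 1] <- min(1, b[hyperCpg, 1] + step)
    bumped <- computeMrs(MethylationExperiment(b2), ch$panel, thr)
    expect_gte(scoreValues(bumped)[1], scoreValues(base)[1])
  }
})

test_that("MRS carries no signal once labels are permuted", {
  ch <- simulateCohort(simulationSpec(nCases = 80, nControls = 160,
                                      nCpgs = 20, nSnps = 4, cpgEffect = 0.4,
                                      poolFactor = 5, seed = 21))
  set.seed(99)
  aucs <- replicate(20, {
    perm <- ch$labels
    perm$status <- sample(perm$status)
    perm$time_to_diagnosis_years <- NA_real_
    thr <- controlQuartiles(ch$methylation, perm)
    s <- computeMrs(ch$methylation, ch$panel, thr)
    computeAuc(s, perm)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("the per-CpG scan reports adjusted odds ratios and BH p-values", {
  ch <- simulateCohort(simulationSpec(nCases = 60, nControls = 140,
                                      nCpgs = 15, nSnps = 4, cpgEffect = 0.8,
                                      poolFactor = 5, seed = 13))
  cov <- data.frame(sample_id = ch$labels$sample_id,
                    age = ch$covariates$age,
                    batch = ch$batch$batch)
  scan <- cpgAssociationScan(ch$methylation, ch$labels, cov)
  expect_equal(nrow(scan), 15)
  ok <- scan$status == "ok"
  expect_true(any(ok))
  expect_equal(scan$p_bh[ok], p.adjust(scan$p[ok], "BH"))
  expect_true(all(scan$p_bh[ok] >= scan$p[ok]))
  # with a single scanned CpG the adjusted p equals the raw p
  one <- cpgAssociationScan(ch$methylation[1, ], ch$labels, cov)
  expect_equal(one$p_bh, one$p)
  # a constant CpG is flagged, not fatal
  b <- betaValues(ch$methylation)
  b[2, ] <- 0.5
  flat <- cpgAssociationScan(MethylationExperiment(b), ch$labels, cov)
  expect_equal(flat$status[2], "degenerate")
  expect_true(is.na(flat$p_bh[2]))
})
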