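test_that("2x2 logistic fits equal the cross-product closed form to 1e-10", {
  set.seed(61)
  for (rep in 1:10) {
    cells <- sample(5:80, 4)
    dat <- expand2x2(cells[1], cells[2], cells[3], cells[4])
    fit <- fitLogistic(cbind("(Intercept)" = 1, x = dat$x), dat$y)
    expect_true(fit$converged)
    expect_equal(unname(fit$or["x"]), do.call(crossProductOr, as.list(cells)),
                 tolerance = 1e-10)
    ci <- do.call(waldCi, as.list(cells))
    expect_equal(unname(fit$ci_low["x"]), ci[1], tolerance = 1e-10)
    expect_equal(unname(fit$ci_high["x"]), ci[2], tolerance = 1e-10)
  }
  # independence in a balanced table gives OR exactly 1
  dat <- expand2x2(30, 30, 30, 30)
  fit <- fitLogistic(cbind("(Intercept)" = 1, x = dat$x), dat$y)
  expect_equal(unname(fit$or["x"]), 1, tolerance = 1e-12)
})

test_that("separated fits are flagged and report no odds ratios", {
  x <- c(rep(0, 20), rep(1, 20))
  fit <- fitLogistic(cbind("(Intercept)" = 1, x = x), x)
  expect_false(fit$converged)
  expect_true(all(is.na(fit$or)))
  expect_error(fitLogistic(cbind(1, matrix(rnorm(20), 4)), c(1, 0, 1, 0)),
               "more observations")
})

test_that("quartile bins come from controls and ORs match cross-products", {
  set.seed(62)
  lab <- makeLabels(60, 120, ttd = runif(60, 1, 10))
  v <- setNames(c(rnorm(60, 0.4), rnorm(120)), lab$sample_id)
  q <- quartileOr(v, lab)
  expect_equal(unname(q$edges),
               unname(quantile(v[lab$status == "control"], c(.25, .5, .75))))
  # mutating case values never moves the edges
  v2 <- v; v2[lab$status == "case"] <- v2[lab$status == "case"] + 100
  expect_equal(quartileOr(v2, lab)$edges, q$edges)

  # unadjusted indicator ORs are the per-bin cross-product ratios
  cnt <- q$counts
  for (k in 2:4) {
    or <- (cnt[k, "case"] * cnt[1, "control"]) /
      (cnt[k, "control"] * cnt[1, "case"])
    expect_equal(unname(q$or[paste0("Q", k)]), or, tolerance = 1e-8)
  }
  # bin rule: lower bins closed on the right
  expect_equal(unname(q$bin[which(v == max(v[v <= q$edges[1]]))[1]]), 1L)

  expect_error(quartileOr(setNames(rep(1, 180), lab$sample_id), lab),
               "degenerate")
  expect_error(quartileOr(v[1:66], lab[1:66, ]), ">= 8 controls")
})

test_that("OR per SD is scale-invariant and null-calibrated", {
  set.seed(63)
  lab <- makeLabels(50, 100, ttd = runif(50, 1, 5))
  v <- setNames(rnorm(150), lab$sample_id)
  o1 <- orPerSd(v, lab)
  o2 <- orPerSd(v * 2, lab)
  expect_equal(o1$or, o2$or, tolerance = 1e-10)
  expect_equal(o2$sd, o1$sd * 2)
  # independent score: CI covers 1
  expect_true(o1$ci_low < 1 && 1 < o1$ci_high)
  expect_error(orPerSd(v * 0, lab), "zero SD")
})

test_that("AUC equals the exhaustive pair count, with standard anchors", {
  set.seed(64)
  for (rep in 1:10) {
    nc <- sample(3:12, 1); nt <- sample(3:12, 1)
    lab <- makeLabels(nc, nt, ttd = rep(1, nc))
    v <- setNames(sample(1:6, nc + nt, replace = TRUE), lab$sample_id)
    got <- computeAuc(v, lab)$auc
    want <- pairCountAuc(unname(v), as.integer(lab$status == "case"))
    expect_equal(got, want, tolerance = 1e-12)
  }
  lab <- makeLabels(5, 5, ttd = rep(1, 5))
  sep <- setNames(c(rep(2, 5), rep(1, 5)), lab$sample_id)
  expect_equal(computeAuc(sep, lab)$auc, 1)
  tie <- setNames(rep(3, 10), lab$sample_id)
  expect_equal(computeAuc(tie, lab)$auc, 0.5)
  expect_error(computeAuc(sep[1:5], lab[1:5, ]), ">= 1 case")
})

test_that("AUC of a unit mean shift approaches its closed form", {
  # two equal-variance normals separated by delta have AUC = pnorm(delta/sqrt(2))
  set.seed(65)
  lab <- makeLabels(2000, 2000, ttd = rep(1, 2000))
  v <- setNames(c(rnorm(2000, 1), rnorm(2000)), lab$sample_id)
  a <- computeAuc(v, lab)
  expect_lt(abs(a$auc - pnorm(1 / sqrt(2))), 0.02)
  expect_true(a$ci_low < a$auc & a$auc < a$ci_high)
})

test_that("combining a score with itself leaves the AUC unchanged", {
  ch <- smallCohort(seed = 19)
  raw <- computeGrs(ch$genotypes, ch$weights)
  # round to keep distinct score values separated well beyond float noise:
  # the monotone fitted-probability transform must then preserve all ties
  grs <- ScoreSet(sampleIds(raw), round(scoreValues(raw), 6), "grs")
  single <- computeAuc(grs, ch$labels)$auc
  expect_warning(
    both <- combineScores(list(a = grs, b = grs), ch$labels,
                          cvRepetitions = 0),
    "collinear")
  expect_equal(both$apparent_auc$auc, single, tolerance = 1e-9)
})

test_that("repeated cross-validation is deterministic and guards its folds", {
  ch <- smallCohort(seed = 20)
  grs <- computeGrs(ch$genotypes, ch$weights)
  mrs <- computeMrs(ch$methylation, ch$panel,
                    controlQuartiles(ch$methylation, ch$labels))
  cv1 <- crossValidate(list(grs = grs, mrs = mrs), ch$labels,
                       repetitions = 5, seed = 9)
  cv2 <- crossValidate(list(grs = grs, mrs = mrs), ch$labels,
                       repetitions = 5, seed = 9)
  expect_identical(cv1$auc, cv2$auc)
  expect_equal(length(cv1$auc), 5)
  cv3 <- crossValidate(list(grs = grs, mrs = mrs), ch$labels,
                       repetitions = 5, seed = 10)
  expect_false(identical(cv1$auc, cv3$auc))
  # a fold layout that cannot hold one case per fold errors out
  tiny <- ch$labels[c(1:3, 41:80), ]
  expect_error(crossValidate(list(grs = grs), tiny, folds = 10,
                             repetitions = 1, seed = 1),
               "folds")
  expect_error(crossValidate(list(grs = grs), ch$labels, folds = 1,
                             repetitions = 1), ">= 2")
})

test_that("Hosmer-Lemeshow rejects gross miscalibration but guards its df", {
  set.seed(66)
  rej <- vapply(1:10, function(r) {
    p <- runif(1000, 0.05, 0.95)
    y <- rbinom(1000, 1, p)
    hosmerLemeshow(p^3, y)$p_value < 0.05  # badly miscalibrated
  }, TRUE)
  expect_gt(mean(rej), 0.8)
  p <- runif(100, 0.2, 0.8)
  expect_error(hosmerLemeshow(p, rbinom(100, 1, p), groups = 2), ">= 3")
  expect_error(hosmerLemeshow(p[1:20], rbinom(20, 1, 0.5), groups = 10),
               "n >= 5")
  hl <- hosmerLemeshow(p, rbinom(100, 1, p))
  expect_equal(hl$df, 8)
  expect_equal(sum(hl$table$n), 100)
})

test_that("score correlations are symmetric with unit diagonal", {
  ch <- smallCohort(seed = 22)
  grs <- computeGrs(ch$genotypes, ch$weights)
  mrs <- computeMrs(ch$methylation, ch$panel,
                    controlQuartiles(ch$methylation, ch$labels))
  cc <- scoreCorrelations(list(grs = grs, mrs = mrs))
  expect_equal(diag(cc$r), c(grs = 1, mrs = 1))
  expect_equal(cc$r["grs", "mrs"], cc$r["mrs", "grs"])
  # affine transforms leave r untouched
  shifted <- ScoreSet(sampleIds(grs), 3 * scoreValues(grs) - 2, "grs")
  cc2 <- scoreCorrelations(list(grs = shifted, mrs = mrs))
  expect_equal(cc2$r["grs", "mrs"], cc$r["grs", "mrs"], tolerance = 1e-12)
  expect_error(scoreCorrelations(list(
    a = ScoreSet(sampleIds(grs), rep(1, length(sampleIds(grs))), "grs"),
    b = mrs)), "constant")
})

test_that("follow-up subsetting keeps controls and honours the boundary", {
  lab <- makeLabels(4, 3, ttd = c(6.8, 7.0, 7.2, 13.6))
  early <- subsetByFollowup(lab, 7, "le")
  expect_setequal(early$sample_id[early$status == "case"],
                  lab$sample_id[1:2])  # 6.8 and exactly 7.0 retained
  late <- subsetByFollowup(lab, 7, "gt")
  expect_setequal(late$sample_id[late$status == "case"], lab$sample_id[3:4])
  expect_equal(sum(early$status == "control"), 3)
  expect_equal(sum(late$status == "control"), 3)
  lab$time_to_diagnosis_years[1] <- NA
  expect_error(subsetByFollowup(lab, 7, "le"), "time_to_diagnosis")
})

test_that("evaluation results are invariant to sample order", {
  ch <- smallCohort(seed = 23)
  grs <- computeGrs(ch$genotypes, ch$weights)
  perm <- sample(nrow(ch$labels))
  labP <- ch$labels[perm, ]
  expect_equal(computeAuc(grs, labP)$auc, computeAuc(grs, ch$labels)$auc)
  expect_equal(quartileOr(grs, labP)$or, quartileOr(grs, ch$labels)$or,
               tolerance = 1e-9)
  expect_equal(orPerSd(grs, labP)$or, orPerSd(grs, ch$labels)$or,
               tolerance = 1e-9)
})

test_that("the full report assembles every block and serialises to JSON", {
  ch <- smallCohort(seed = 24)
  cov <- imputeWithinGroup(ch$covariates, ch$labels,
                           c("age_at_menarche", "parity", "menopausal_status",
                             "age_at_menopause", "mht_current"))
  scores <- list(
    mrs = computeMrs(ch$methylation, ch$panel,
                     controlQuartiles(ch$methylation, ch$labels)),
    grs = computeGrs(ch$genotypes, ch$weights),
    ers = computeLinearErs(cov, syntheticErsSpec()))
  rep <- riskScoreReport(scores, ch$labels, leukocytes = ch$leukocytes,
                         cvRepetitions = 3, seed = 2)
  expect_named(rep$scores, c("mrs", "grs", "ers"))
  expect_s3_class(rep$combined$cv, "CvResult")
  expect_true(!is.null(rep$scores$grs$quartiles_model1))
  f <- withr::local_tempfile(fileext = ".json")
  writeReportJson(rep, f)
  parsed <- jsonlite::read_json(f)
  expect_true(all(c("scores", "combined") %in% names(parsed)))
  expect_type(parsed$combined$apparent_auc$auc, "double")
})
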