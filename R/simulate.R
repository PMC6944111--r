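# Synthetic nested case-control cohorts with planted methylation, genetic
# and environmental effects. The generator exists so that every downstream
# stage (scores, QC, evaluation) can be exercised end-to-end with known
# truth; it emulates the statistical structure the analysis assumes, not the
# measurement platform.

#' Default environmental variable definitions
#'
#' Twelve baseline variables mimicking the reproductive, lifestyle and
#' anthropometric profile of a cohort of women aged 50-75: age, age at
#' menarche, parity, BMI, height, alcohol intake, menopausal status, age at
#' menopause, current menopausal hormone therapy, oral contraceptive use,
#' smoking and family history of breast cancer. Each definition carries the
#' sampling distribution, the planted log-odds effect per unit (or per
#' level), and whether missingness may be injected.
#'
#' @return list of variable definitions consumed by [simulationSpec()].
#' @export
defaultEnvironmentVariables <- function() {
  list(
    list(name = "age", kind = "normal", mean = 61, sd = 6, beta = 0.01,
         missing = FALSE),
    list(name = "age_at_menarche", kind = "normal", mean = 13, sd = 1.5,
         beta = -0.05, missing = TRUE),
    list(name = "parity", kind = "categorical", levels = 0:4,
         probs = c(0.06, 0.25, 0.38, 0.22, 0.09),
         beta = c(0, -0.1, -0.2, -0.3, -0.4), missing = TRUE),
    list(name = "bmi", kind = "normal", mean = 27.5, sd = 4.5, beta = 0.02,
         missing = FALSE),
    list(name = "height_m", kind = "normal", mean = 1.63, sd = 0.065,
         beta = 0, missing = FALSE),
    list(name = "alcohol_g_day", kind = "zero_gamma", p_zero = 0.44,
         shape = 1.5, scale = 8, beta = 0.005, missing = FALSE),
    list(name = "menopausal_status", kind = "binary", p = 0.86, beta = 0.1,
         missing = TRUE),
    list(name = "age_at_menopause", kind = "normal", mean = 49, sd = 4,
         beta = 0.02, missing = TRUE),
    list(name = "mht_current", kind = "binary", p = 0.58, beta = 0.25,
         missing = TRUE),
    list(name = "oc_ever", kind = "binary", p = 0.63, beta = 0,
         missing = FALSE),
    list(name = "smoking_status", kind = "categorical",
         levels = c("never", "former", "current"),
         probs = c(0.64, 0.19, 0.17), beta = c(0, 0.05, 0.10),
         missing = FALSE),
    list(name = "fdr_bc", kind = "binary", p = 0.09, beta = 0.35,
         missing = FALSE)
  )
}

#' Specification of a synthetic nested case-control cohort
#'
#' Defaults mirror the analysed sample: 101 incident cases and 263 controls
#' drawn from a 20x pool, CpG effects applied on the logit scale in the
#' direction previously reported for disease, SNP effects on the per-allele
#' log-OR scale typical of published breast-cancer weights (0.03-0.18), and
#' low completely-at-random missingness.
#'
#' @param nCases,nControls requested case/control counts.
#' @param nCpgs number of panel CpGs (half hyper-, half hypomethylated).
#' @param cpgEffect logit-scale mean shift added to cases (+ for hyper CpGs,
#'   - for hypo CpGs).
#' @param cpgSd logit-scale within-group SD of beta values.
#' @param nSnps number of SNPs.
#' @param alleleFreq effect-allele frequencies (recycled; default an even
#'   grid over 0.05-0.5).
#' @param snpBeta per-allele log-OR weights (recycled; default an even grid
#'   over 0.03-0.18).
#' @param fractionalDosage if TRUE, jitter hard genotypes into fractional
#'   imputed-style dosages.
#' @param envVariables list of variable definitions
#'   (see [defaultEnvironmentVariables()]); set each \code{beta} to 0 for a
#'   null cohort.
#' @param missingRates named list with elements \code{methylation},
#'   \code{genotype}, \code{covariate}: completely-at-random missingness per
#'   data type.
#' @param nBatches,batchEffect number of processing batches (assigned
#'   round-robin) and the CpG-independent logit-scale mean shift per batch
#'   step.
#' @param leukocyteAlpha Dirichlet concentration for the six leukocyte
#'   fractions (granulocytes dominant, as in whole blood).
#' @param ldBlocks optional list of \code{list(snps=, rho=)} blocks; within a
#'   block genotypes are drawn through a Gaussian copula with exchangeable
#'   correlation \code{rho}, to exercise LD pruning and surrogate search.
#' @param poolFactor pool size relative to \code{nCases + nControls} from
#'   which cases and controls are sampled.
#' @param baselineRisk marginal case probability at zero planted risk.
#' @param seed master seed.
#' @return list of class \code{"SimulationSpec"}.
#' @export
simulationSpec <- function(nCases = 101L, nControls = 263L, nCpgs = 60L,
                           cpgEffect = 0.015, cpgSd = 0.5, nSnps = 40L,
                           alleleFreq = NULL, snpBeta = NULL,
                           fractionalDosage = FALSE,
                           envVariables = defaultEnvironmentVariables(),
                           missingRates = list(methylation = 0.01,
                                               genotype = 0.01,
                                               covariate = 0.02),
                           nBatches = 4L, batchEffect = 0.05,
                           leukocyteAlpha = c(Gran = 28, CD4T = 7, CD8T = 4,
                                              Bcell = 3, NK = 3, Mono = 5),
                           ldBlocks = NULL, poolFactor = 20L,
                           baselineRisk = 0.28, seed = 1L) {
  if (is.null(alleleFreq))
    alleleFreq <- seq(0.05, 0.5, length.out = max(nSnps, 1))
  if (is.null(snpBeta))
    snpBeta <- seq(0.03, 0.18, length.out = max(nSnps, 1))
  alleleFreq <- rep_len(alleleFreq, nSnps)
  snpBeta <- rep_len(snpBeta, nSnps)
  if (nCases < 1 || nControls < 1) bcStop("need >= 1 case and >= 1 control")
  if (any(alleleFreq <= 0 | alleleFreq > 0.5))
    bcStop("allele frequencies must lie in (0, 0.5]")
  if (any(!is.finite(snpBeta))) bcStop("snpBeta must be finite")
  for (r in unlist(missingRates))
    if (r < 0 || r >= 1) bcStop("missingness rates must lie in [0,1)")
  spec <- list(nCases = as.integer(nCases), nControls = as.integer(nControls),
               nCpgs = as.integer(nCpgs), cpgEffect = cpgEffect, cpgSd = cpgSd,
               nSnps = as.integer(nSnps), alleleFreq = alleleFreq,
               snpBeta = snpBeta, fractionalDosage = fractionalDosage,
               envVariables = envVariables, missingRates = missingRates,
               nBatches = as.integer(nBatches), batchEffect = batchEffect,
               leukocyteAlpha = leukocyteAlpha, ldBlocks = ldBlocks,
               poolFactor = as.integer(poolFactor),
               baselineRisk = baselineRisk, seed = as.integer(seed))
  class(spec) <- "SimulationSpec"
  spec
}

#' Coefficient spec matching the generator's planted environmental effects
#'
#' Converts a list of environmental variable definitions (see
#' [defaultEnvironmentVariables()]) into the coefficient-table format
#' consumed by [computeLinearErs()], so the score built from the true
#' planted coefficients can be computed and evaluated.
#'
#' @param envVariables list of variable definitions.
#' @param scoreName name recorded in the spec.
#' @return list of class \code{"ErsCoefficientSpec"}.
#' @export
syntheticErsSpec <- function(envVariables = defaultEnvironmentVariables(),
                             scoreName = "synthetic_true_effects") {
  rules <- lapply(envVariables, function(def) {
    if (def$kind == "categorical" && is.numeric(def$levels)) {
      # numeric categories become half-open intervals so that unrounded
      # within-group imputed means still categorize
      br <- c(def$levels - 0.5, Inf)
      list(name = def$name, type = "categorical", breaks = br,
           betas = def$beta)
    } else if (def$kind == "categorical") {
      lv <- as.list(stats::setNames(def$beta, as.character(def$levels)))
      list(name = def$name, type = "categorical", levels = lv)
    } else {
      list(name = def$name, type = "continuous", beta = def$beta)
    }
  })
  spec <- list(score_name = scoreName, variables = rules,
               unavailable = list())
  class(spec) <- "ErsCoefficientSpec"
  spec
}

# numeric value of an environmental variable for the linear predictor
envNumeric <- function(def, x) {
  if (def$kind == "categorical" && is.character(def$levels[1]))
    return(def$beta[match(x, def$levels)])
  if (def$kind == "categorical")
    return(def$beta[match(x, def$levels)])
  def$beta * x
}

drawEnvVariable <- function(def, n) {
  switch(def$kind,
    normal = stats::rnorm(n, def$mean, def$sd),
    binary = stats::rbinom(n, 1, def$p),
    categorical = sample(def$levels, n, replace = TRUE, prob = def$probs),
    zero_gamma = ifelse(stats::rbinom(n, 1, def$p_zero) == 1, 0,
                        stats::rgamma(n, shape = def$shape,
                                      scale = def$scale)),
    bcStop("unknown variable kind '%s'", def$kind))
}

rdirichlet1 <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), ncol = n)
  sweep(t(g), 1, colSums(g), "/")
}

# genotypes for one pool: binomial(2, f) per SNP, optionally with
# exchangeable-correlation copula blocks
drawGenotypes <- function(n, freq, ldBlocks) {
  nSnp <- length(freq)
  g <- matrix(0L, nrow = nSnp, ncol = n)
  inBlock <- rep(FALSE, nSnp)
  for (blk in ldBlocks %||% list()) {
    snps <- blk$snps; rho <- blk$rho
    inBlock[snps] <- TRUE
    for (copy in 1:2) {
      shared <- stats::rnorm(n)
      for (j in snps) {
        z <- sqrt(rho) * shared + sqrt(1 - rho) * stats::rnorm(n)
        g[j, ] <- g[j, ] + as.integer(z < stats::qnorm(freq[j]))
      }
    }
  }
  for (j in which(!inBlock))
    g[j, ] <- stats::rbinom(n, 2, freq[j])
  g
}

#' Simulate a nested case-control cohort
#'
#' Draws a large pool of individuals, assigns case status from a logistic
#' model on the weighted sum of the planted genetic and environmental
#' effects, samples the requested numbers of cases and controls, and only
#' then generates methylation conditional on status: beta values are
#' logit-normal, with cases shifted by \code{+cpgEffect} (hyper CpGs) or
#' \code{-cpgEffect} (hypo CpGs) on the logit scale, plus a CpG-independent
#' batch shift. Missingness is applied completely at random. Deterministic
#' given \code{spec$seed}: every stage draws from its own named substream.
#'
#' @param spec a [simulationSpec()].
#' @return list of class \code{"SyntheticCohort"} with elements
#'   \code{methylation} ([MethylationExperiment-class]), \code{genotypes}
#'   ([GenotypeExperiment-class]), \code{covariates}, \code{labels},
#'   \code{leukocytes}, \code{batch}, \code{panel}, \code{weights} (the true
#'   SNP weight table) and \code{truth} (sample_id, latent_risk, status).
#'   The truth table is for recovery tests only and is never an input to the
#'   scoring pipeline.
#' @export
simulateCohort <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  nReq <- spec$nCases + spec$nControls
  nPool <- spec$poolFactor * nReq

  set.seed(substreamSeed(spec$seed, "genotypes"))
  g <- drawGenotypes(nPool, spec$alleleFreq, spec$ldBlocks)
  genRisk <- if (spec$nSnps > 0)
    colSums(g * spec$snpBeta) - sum(2 * spec$alleleFreq * spec$snpBeta)
  else rep(0, nPool)

  set.seed(substreamSeed(spec$seed, "environment"))
  env <- list(); envRisk <- rep(0, nPool)
  for (def in spec$envVariables) {
    x <- drawEnvVariable(def, nPool)
    env[[def$name]] <- x
    contrib <- envNumeric(def, x)
    envRisk <- envRisk + (contrib - mean(contrib))
  }

  latent <- genRisk + envRisk
  set.seed(substreamSeed(spec$seed, "status"))
  pCase <- stats::plogis(stats::qlogis(spec$baselineRisk) + latent)
  y <- stats::rbinom(nPool, 1, pCase)
  caseIdx <- which(y == 1); controlIdx <- which(y == 0)
  if (length(caseIdx) < spec$nCases || length(controlIdx) < spec$nControls)
    bcStop(paste0("pool of %d produced %d cases / %d controls; ",
                  "need %d / %d - increase poolFactor"),
           nPool, length(caseIdx), length(controlIdx),
           spec$nCases, spec$nControls)
  sel <- c(sample(caseIdx, spec$nCases), sample(controlIdx, spec$nControls))
  status <- c(rep("case", spec$nCases), rep("control", spec$nControls))
  ids <- sprintf("S%04d", seq_len(nReq))

  set.seed(substreamSeed(spec$seed, "followup"))
  ttd <- ifelse(status == "case", stats::runif(nReq, 0.02, 13.6), NA_real_)
  labels <- data.frame(sample_id = ids, status = status,
                       time_to_diagnosis_years = round(ttd, 3),
                       stringsAsFactors = FALSE)

  batch <- rep_len(seq_len(spec$nBatches), nReq)

  set.seed(substreamSeed(spec$seed, "methylation"))
  directions <- rep(c("hyper", "hypo"), length.out = max(spec$nCpgs, 1))
  cpgIds <- sprintf("cg%05d", seq_len(spec$nCpgs))
  baseline <- stats::qlogis(seq(0.2, 0.8, length.out = max(spec$nCpgs, 1)))
  beta <- matrix(NA_real_, nrow = spec$nCpgs, ncol = nReq,
                 dimnames = list(cpgIds, ids))
  dirSign <- ifelse(directions == "hyper", 1, -1)[seq_len(spec$nCpgs)]
  batchShift <- spec$batchEffect * (batch - (spec$nBatches + 1) / 2)
  isCase <- as.numeric(status == "case")
  for (j in seq_len(spec$nCpgs)) {
    mu <- baseline[j] + dirSign[j] * spec$cpgEffect * isCase + batchShift
    beta[j, ] <- stats::plogis(stats::rnorm(nReq, mu, spec$cpgSd))
  }

  set.seed(substreamSeed(spec$seed, "leukocytes"))
  leuko <- rdirichlet1(nReq, spec$leukocyteAlpha)
  colnames(leuko) <- names(spec$leukocyteAlpha)
  leukoDf <- data.frame(sample_id = ids, leuko, stringsAsFactors = FALSE)

  dos <- g[, sel, drop = FALSE] * 1.0
  if (spec$fractionalDosage && spec$nSnps > 0) {
    set.seed(substreamSeed(spec$seed, "dosage_jitter"))
    dos <- dos + matrix(stats::runif(length(dos), -0.15, 0.15), nrow(dos))
    dos <- pmin(pmax(dos, 0), 2)
  }
  snpIds <- sprintf("rs%06d", seq_len(spec$nSnps))
  dimnames(dos) <- list(snpIds, ids)
  # place SNPs on two chromosomes; LD-block members adjacent (10 kb apart),
  # others 1 Mb apart so window-based LD logic has something to chew on
  chrom <- rep(c("1", "2"), length.out = max(spec$nSnps, 1))[seq_len(spec$nSnps)]
  pos <- integer(spec$nSnps)
  for (cc in unique(chrom)) {
    j <- which(chrom == cc)
    pos[j] <- 1e6 * seq_along(j)
  }
  for (blk in spec$ldBlocks %||% list()) {
    snps <- sort(blk$snps)
    chrom[snps] <- chrom[snps[1]]
    pos[snps] <- pos[snps[1]] + 1e4 * (seq_along(snps) - 1)
  }
  alleles <- c("A", "C", "G", "T")
  set.seed(substreamSeed(spec$seed, "alleles"))
  ea <- sample(alleles, max(spec$nSnps, 1), replace = TRUE)[seq_len(spec$nSnps)]
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1), "")

  cov <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (def in spec$envVariables) cov[[def$name]] <- env[[def$name]][sel]

  set.seed(substreamSeed(spec$seed, "missingness"))
  addNa <- function(m, rate) {
    if (rate > 0) m[stats::runif(length(m)) < rate] <- NA
    m
  }
  beta <- addNa(beta, spec$missingRates$methylation %||% 0)
  dos <- addNa(dos, spec$missingRates$genotype %||% 0)
  covRate <- spec$missingRates$covariate %||% 0
  if (covRate > 0)
    for (def in spec$envVariables)
      if (isTRUE(def$missing))
        cov[[def$name]][stats::runif(nReq) < covRate] <- NA

  panel <- data.frame(cpg_id = cpgIds,
                      direction = directions[seq_len(spec$nCpgs)],
                      set_label = as.character(spec$nCpgs),
                      stringsAsFactors = FALSE)
  weights <- data.frame(snp_id = snpIds, chrom = chrom, pos = as.integer(pos),
                        effect_allele = ea, other_allele = oa,
                        beta = spec$snpBeta, stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = ids, latent_risk = latent[sel],
                      status = status, stringsAsFactors = FALSE)

  out <- list(methylation = MethylationExperiment(beta),
              genotypes = GenotypeExperiment(dos, chrom = chrom, pos = pos,
                                             effectAllele = ea,
                                             otherAllele = oa),
              covariates = cov, labels = labels, leukocytes = leukoDf,
              batch = data.frame(sample_id = ids, batch = batch,
                                 stringsAsFactors = FALSE),
              panel = asCpgPanel(panel), weights = asWeightTable(weights),
              truth = truth, spec = spec)
  class(out) <- "SyntheticCohort"
  out
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf("SyntheticCohort: %d cases / %d controls, %d CpGs, %d SNPs\n",
              sum(x$labels$status == "case"),
              sum(x$labels$status == "control"),
              nrow(x$methylation), nrow(x$genotypes)))
  invisible(x)
}

#' Write / read a synthetic cohort as a directory of TSV files
#'
#' Emits every table in the package's TSV dialects plus \code{truth.tsv}
#' (the planted latent risk, used only by recovery tests) and a JSON
#' manifest listing the pipeline input files; the truth file is deliberately
#' excluded from the manifest.
#'
#' @param cohort a \code{SyntheticCohort}.
#' @param dir output directory (created if needed).
#' @param overwrite allow writing over existing files.
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir, overwrite = FALSE) {
  stopifnot(inherits(cohort, "SyntheticCohort"))
  if (nrow(cohort$labels) == 0) bcStop("cannot write an empty cohort")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(beta = "beta.tsv", dosage = "dosage.tsv",
             covariates = "covariates.tsv", labels = "labels.tsv",
             leukocytes = "leukocytes.tsv", batch = "batch.tsv",
             panel = "panel.tsv", weights = "weights.tsv",
             truth = "truth.tsv")
  paths <- file.path(dir, files)
  if (!overwrite && any(file.exists(paths)))
    bcStop("output file(s) already exist in %s (use overwrite = TRUE)", dir)
  writeBetaMatrix(cohort$methylation, file.path(dir, "beta.tsv"))
  writeDosageMatrix(cohort$genotypes, file.path(dir, "dosage.tsv"))
  writeCovariates(cohort$covariates, file.path(dir, "covariates.tsv"))
  writeLabels(cohort$labels, file.path(dir, "labels.tsv"))
  writeTsv(cohort$leukocytes, file.path(dir, "leukocytes.tsv"))
  writeTsv(cohort$batch, file.path(dir, "batch.tsv"))
  writeCpgPanel(cohort$panel, file.path(dir, "panel.tsv"))
  writeWeightTable(cohort$weights, file.path(dir, "weights.tsv"))
  writeTsv(cohort$truth, file.path(dir, "truth.tsv"))
  manifest <- list(inputs = as.list(files[setdiff(names(files), "truth")]),
                   n_samples = nrow(cohort$labels),
                   n_cpgs = nrow(cohort$methylation),
                   n_snps = nrow(cohort$genotypes),
                   seed = cohort$spec$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  labels <- readLabels(file.path(dir, "labels.tsv"))
  weights <- readWeightTable(file.path(dir, "weights.tsv"))
  out <- list(
    methylation = readBetaMatrix(file.path(dir, "beta.tsv")),
    genotypes = readDosageMatrix(file.path(dir, "dosage.tsv"),
                                 weights = weights),
    covariates = readCovariates(file.path(dir, "covariates.tsv")),
    labels = labels,
    leukocytes = readTsv(file.path(dir, "leukocytes.tsv")),
    batch = readTsv(file.path(dir, "batch.tsv")),
    panel = readCpgPanel(file.path(dir, "panel.tsv")),
    weights = weights,
    truth = if (file.exists(file.path(dir, "truth.tsv")))
      readTsv(file.path(dir, "truth.tsv")) else NULL,
    spec = NULL)
  class(out) <- "SyntheticCohort"
  out
}
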