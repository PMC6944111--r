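# shared fixtures: tiny cohorts and matrices built in code

options(bcrisk.quiet = TRUE)

makeLabels <- function(nCase, nControl, ttd = NULL) {
  n <- nCase + nControl
  data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    status = c(rep("case", nCase), rep("control", nControl)),
    time_to_diagnosis_years = c(ttd %||% rep(NA_real_, nCase),
                                rep(NA_real_, nControl)),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

randomBeta <- function(nCpg, nSample, seed = 1) {
  set.seed(seed)
  matrix(runif(nCpg * nSample), nCpg, nSample,
         dimnames = list(sprintf("cg%03d", seq_len(nCpg)),
                         sprintf("s%03d", seq_len(nSample))))
}

# genotype matrix from per-sample haplotype pairs at two loci; haps is a
# 4-column probability vector over (AB, Ab, aB, ab)
genoFromHaps <- function(n, hapFreq, seed = 1) {
  set.seed(seed)
  h1 <- sample(1:4, n, replace = TRUE, prob = hapFreq)
  h2 <- sample(1:4, n, replace = TRUE, prob = hapFreq)
  aOf <- c(1, 1, 0, 0); bOf <- c(1, 0, 1, 0)
  rbind(A = aOf[h1] + aOf[h2], B = bOf[h1] + bOf[h2])
}

# small synthetic cohort for pipeline tests
smallCohort <- function(seed = 1, ...) {
  simulateCohort(simulationSpec(nCases = 40, nControls = 80, nCpgs = 12,
                                nSnps = 12, poolFactor = 8, seed = seed, ...))
}

# environmental variable definitions with every planted effect nulled
nullEnvVariables <- function() {
  lapply(defaultEnvironmentVariables(), function(def) {
    def$beta <- def$beta * 0
    def
  })
}

nullSpec <- function(seed, nCases = 75, nControls = 225, ...) {
  simulationSpec(nCases = nCases, nControls = nControls, nCpgs = 10,
                 nSnps = 10, cpgEffect = 0, snpBeta = 0,
                 envVariables = nullEnvVariables(), poolFactor = 5,
                 seed = seed, ...)
}

# closed-form oracles for the 2x2 saturated logistic model
crossProductOr <- function(a, b, c, d) (a * d) / (b * c)
waldCi <- function(a, b, c, d) {
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  exp(log(crossProductOr(a, b, c, d)) + c(-1.96, 1.96) * se)
}
expand2x2 <- function(a, b, c, d) {
  x <- c(rep(1, a + b), rep(0, c + d))
  y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  list(x = x, y = y)
}

# independent LD oracle: at the MLE the allele frequencies equal the
# observed allele counts, leaving one free parameter; grid-search p(AB) at
# 1e-5 against the full multinomial genotype likelihood
gridLdOracle <- function(cnt) {
  n <- sum(cnt)
  pA <- sum(cnt * matrix(0:2, 3, 3)) / (2 * n)
  pB <- sum(cnt * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  ll <- function(pAB) {
    p <- c(pAB, pA - pAB, pB - pAB, 1 - pA - pB + pAB)
    if (any(p < 0)) return(-Inf)
    gp <- matrix(0, 3, 3)
    gp[1, 1] <- p[4]^2;           gp[1, 2] <- 2 * p[4] * p[3]
    gp[1, 3] <- p[3]^2;           gp[2, 1] <- 2 * p[4] * p[2]
    gp[2, 2] <- 2 * (p[1] * p[4] + p[2] * p[3])
    gp[2, 3] <- 2 * p[1] * p[3];  gp[3, 1] <- p[2]^2
    gp[3, 2] <- 2 * p[1] * p[2];  gp[3, 3] <- p[1]^2
    sum(cnt[cnt > 0] * log(gp[cnt > 0]))
  }
  grid <- seq(max(0, pA + pB - 1), min(pA, pB), by = 1e-5)
  best <- grid[which.max(vapply(grid, ll, 0))]
  c(AB = best, Ab = pA - best, aB = pB - best, ab = 1 - pA - pB + best)
}

# exhaustive pair-count AUC oracle (ties count 1/2)
pairCountAuc <- function(score, y) {
  cs <- score[y == 1]; ct <- score[y == 0]
  tot <- 0
  for (a in cs) for (b in ct) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}
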