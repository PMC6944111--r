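# Genetic risk score: SNP QC filters, two-locus EM linkage disequilibrium,
# greedy LD pruning, surrogate-SNP search, and the weighted-allele linear
# form.

# effect-allele frequency and MAF over non-missing cells
alleleFreq <- function(d) mean(d, na.rm = TRUE) / 2
mafOf <- function(d) {
  f <- alleleFreq(d)
  min(f, 1 - f)
}

#' Filter SNPs on missingness and minor allele frequency
#'
#' A SNP is removed when missing in strictly more than \code{maxMissing} of
#' the samples, or when its minor allele frequency is strictly below
#' \code{mafMin}. MAF is computed as \code{min(f, 1 - f)} with \code{f} the
#' mean dosage over non-missing cells divided by 2.
#'
#' @param g a [GenotypeExperiment-class].
#' @param maxMissing maximum missing fraction (default 0.10).
#' @param mafMin minimum MAF (default 0.01); a SNP with MAF exactly equal to
#'   \code{mafMin} is retained.
#' @return filtered [GenotypeExperiment-class].
#' @export
filterSnps <- function(g, maxMissing = 0.10, mafMin = 0.01) {
  checkFraction(maxMissing, "maxMissing", hiOpen = TRUE)
  checkFraction(mafMin, "mafMin", hiOpen = TRUE)
  d <- dosages(g)
  missFrac <- rowMeans(is.na(d))
  maf <- apply(d, 1, mafOf)
  failMiss <- missFrac > maxMissing
  failMaf <- maf < mafMin
  keep <- !failMiss & !failMaf
  bcLog("SNP filter: %d in; %d fail missingness > %g; %d fail MAF < %g; %d retained",
        nrow(d), sum(failMiss), maxMissing, sum(failMaf), mafMin, sum(keep))
  if (!any(keep)) bcStop("all SNPs removed by QC filters")
  g[keep, ]
}

#' Two-locus linkage disequilibrium by EM
#'
#' Maximum-likelihood haplotype frequencies for a biallelic two-locus system
#' from unphased genotypes, via expectation-maximisation over the 3x3
#' genotype table (only the double heterozygote is phase-ambiguous).
#' Fractional dosages are rounded to hard genotypes first. Reports
#' \code{r2 = D^2 / (pA pa pB pb)} and \code{D' = |D| / Dmax}.
#'
#' @param gA,gB numeric dosage vectors over the same samples.
#' @param minSamples minimum number of jointly non-missing samples
#'   (default 20).
#' @param tol EM convergence: maximum haplotype-frequency change below
#'   \code{tol} (default 1e-10), cap \code{maxIter} iterations.
#' @param maxIter iteration cap (default 1000).
#' @return list (class \code{"LdStats"}): \code{r2}, \code{d_prime},
#'   \code{hap_freq} (AB, Ab, aB, ab), \code{em_iterations},
#'   \code{converged}, \code{monomorphic}, \code{log_lik}, \code{n}.
#' @export
ldEm <- function(gA, gB, minSamples = 20L, tol = 1e-10, maxIter = 1000L) {
  keep <- !is.na(gA) & !is.na(gB)
  if (sum(keep) < minSamples)
    bcStop("ldEm needs >= %d jointly non-missing samples, got %d",
           minSamples, sum(keep))
  a <- pmin(pmax(round(gA[keep]), 0), 2)
  b <- pmin(pmax(round(gB[keep]), 0), 2)
  n <- length(a)
  cnt <- matrix(0, 3, 3)
  for (i in seq_len(n)) cnt[a[i] + 1, b[i] + 1] <- cnt[a[i] + 1, b[i] + 1] + 1
  ldEmFromTable(cnt, tol = tol, maxIter = maxIter)
}

#' @rdname ldEm
#' @param counts 3x3 genotype count table; rows = dosage of A-locus effect
#'   allele (0,1,2), columns = dosage at the B locus.
#' @export
ldEmFromTable <- function(counts, tol = 1e-10, maxIter = 1000L) {
  stopifnot(all(dim(counts) == c(3, 3)), all(counts >= 0))
  n <- sum(counts)
  pA <- sum(counts * matrix(0:2, 3, 3)) / (2 * n)        # effect allele at A
  pB <- sum(counts * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  mono <- pA %in% c(0, 1) || pB %in% c(0, 1)
  if (mono)
    return(structure(list(r2 = 0, d_prime = 0,
                          hap_freq = c(AB = pA * pB, Ab = pA * (1 - pB),
                                       aB = (1 - pA) * pB,
                                       ab = (1 - pA) * (1 - pB)),
                          em_iterations = 0L, converged = TRUE,
                          monomorphic = TRUE, log_lik = NA_real_, n = n),
                     class = "LdStats"))
  # haplotype order: AB, Ab, aB, ab
  p <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  nDouble <- counts[2, 2]
  it <- 0L; converged <- FALSE
  repeat {
    it <- it + 1L
    # E step: split double heterozygotes between AB/ab and Ab/aB phases
    denom <- p[1] * p[4] + p[2] * p[3]
    w <- if (denom > 0) p[1] * p[4] / denom else 0.5
    # haplotype counts from unambiguous genotypes + expected split
    hAB <- 2 * counts[3, 3] + counts[3, 2] + counts[2, 3] + w * nDouble
    hAb <- 2 * counts[3, 1] + counts[3, 2] + counts[2, 1] + (1 - w) * nDouble
    haB <- 2 * counts[1, 3] + counts[1, 2] + counts[2, 3] + (1 - w) * nDouble
    hab <- 2 * counts[1, 1] + counts[1, 2] + counts[2, 1] + w * nDouble
    pNew <- c(hAB, hAb, haB, hab) / (2 * n)
    delta <- max(abs(pNew - p))
    p <- pNew
    if (delta < tol) { converged <- TRUE; break }
    if (it >= maxIter) break
  }
  D <- p[1] - pA * pB
  denomR2 <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- if (denomR2 > 0) D^2 / denomR2 else 0
  dMax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dPrime <- if (dMax > 0) abs(D) / dMax else 0
  structure(list(r2 = r2, d_prime = dPrime,
                 hap_freq = c(AB = p[1], Ab = p[2], aB = p[3], ab = p[4]),
                 em_iterations = it, converged = converged,
                 monomorphic = FALSE,
                 log_lik = ldTableLogLik(counts, p), n = n),
            class = "LdStats")
}

# multinomial log-likelihood of a 3x3 genotype table under haplotype
# frequencies p = (AB, Ab, aB, ab) with random mating
ldTableLogLik <- function(counts, p) {
  gp <- matrix(0, 3, 3)  # genotype probabilities, [dosA+1, dosB+1]
  gp[1, 1] <- p[4]^2
  gp[1, 2] <- 2 * p[4] * p[3]
  gp[1, 3] <- p[3]^2
  gp[2, 1] <- 2 * p[4] * p[2]
  gp[2, 2] <- 2 * (p[1] * p[4] + p[2] * p[3])
  gp[2, 3] <- 2 * p[1] * p[3]
  gp[3, 1] <- p[2]^2
  gp[3, 2] <- 2 * p[1] * p[2]
  gp[3, 3] <- p[1]^2
  use <- counts > 0
  sum(counts[use] * log(gp[use]))
}

#' Greedy LD pruning of a SNP panel
#'
#' Among same-chromosome SNP pairs within \code{windowBp} of each other
#' having BOTH D' >= \code{dprimeMin} AND r^2 > \code{r2Max}, the member
#' with the smaller absolute weight is dropped (preserving score variance);
#' on a tie the lexicographically larger snp id is dropped. Iterated until
#' no violating pair remains, so the result is idempotent.
#'
#' @param g a [GenotypeExperiment-class] with positions.
#' @param weights weight table supplying \code{beta} per SNP (SNPs without a
#'   weight are treated as weight 0).
#' @param r2Max,dprimeMin conjunctive LD thresholds (defaults 0.8, 0.95).
#' @param windowBp only pairs closer than this are tested (default 250000).
#' @return pruned [GenotypeExperiment-class].
#' @export
ldPrune <- function(g, weights, r2Max = 0.8, dprimeMin = 0.95,
                    windowBp = 250000L) {
  info <- snpInfo(g)
  if (any(is.na(info$pos))) bcStop("ldPrune requires SNP positions")
  absBeta <- abs(weights$beta[match(info$snp_id, weights$snp_id)])
  absBeta[is.na(absBeta)] <- 0
  names(absBeta) <- info$snp_id
  d <- dosages(g)
  keep <- info$snp_id
  repeat {
    dropped <- NULL
    sub <- info[info$snp_id %in% keep, , drop = FALSE]
    sub <- sub[order(sub$chrom, sub$pos, sub$snp_id), , drop = FALSE]
    for (i in seq_len(nrow(sub) - 1)) {
      if (!is.null(dropped)) break
      for (j in (i + 1):nrow(sub)) {
        if (sub$chrom[j] != sub$chrom[i]) break
        if (abs(sub$pos[j] - sub$pos[i]) >= windowBp) break
        ld <- ldEm(d[sub$snp_id[i], ], d[sub$snp_id[j], ])
        if (ld$d_prime >= dprimeMin && ld$r2 > r2Max) {
          a <- sub$snp_id[i]; b <- sub$snp_id[j]
          dropped <- if (absBeta[a] < absBeta[b]) a
                     else if (absBeta[b] < absBeta[a]) b
                     else max(a, b)  # tie: drop lexicographically larger id
          break
        }
      }
    }
    if (is.null(dropped)) break
    bcLog("LD prune: dropping %s", dropped)
    keep <- setdiff(keep, dropped)
  }
  bcLog("LD prune: %d SNP(s) in, %d retained", nrow(info), length(keep))
  g[keep, ]
}

#' Find a surrogate SNP in high LD with a target
#'
#' Searches a reference genotype set for the candidate with the highest r^2
#' to the target, among candidates on the same chromosome strictly closer
#' than \code{maxDistanceBp}, with MAF >= \code{mafMin} and missingness
#' strictly below \code{maxMissing}, subject to D' >= \code{dprimeMin} and
#' r^2 > \code{r2Min}. Ties on r^2 are broken by the lexicographically
#' smaller snp id.
#'
#' @param target snp id present in \code{reference}.
#' @param reference a [GenotypeExperiment-class] with positions.
#' @param dprimeMin,r2Min LD criteria (defaults 0.95, 0.8).
#' @param mafMin minimum candidate MAF (default 0.01, inclusive).
#' @param maxDistanceBp strict distance bound (default 250000).
#' @param maxMissing strict missing-fraction bound (default 0.10).
#' @return list: \code{surrogate} (snp id or \code{NA}), \code{r2},
#'   \code{d_prime}, \code{reason} when none found.
#' @export
findSurrogate <- function(target, reference, dprimeMin = 0.95, r2Min = 0.8,
                          mafMin = 0.01, maxDistanceBp = 250000L,
                          maxMissing = 0.10) {
  info <- snpInfo(reference)
  ti <- match(target, info$snp_id)
  if (is.na(ti)) bcStop("target SNP '%s' absent from reference", target)
  if (is.na(info$pos[ti])) bcStop("target SNP '%s' lacks a position", target)
  d <- dosages(reference)
  if (mafOf(d[ti, ]) == 0)
    return(list(surrogate = NA_character_, r2 = NA_real_,
                d_prime = NA_real_, reason = "target monomorphic"))
  cand <- info[-ti, , drop = FALSE]
  cand <- cand[cand$chrom == info$chrom[ti] &
               abs(cand$pos - info$pos[ti]) < maxDistanceBp, , drop = FALSE]
  if (nrow(cand)) {
    maf <- apply(d[cand$snp_id, , drop = FALSE], 1, mafOf)
    missFrac <- rowMeans(is.na(d[cand$snp_id, , drop = FALSE]))
    cand <- cand[maf >= mafMin & missFrac < maxMissing, , drop = FALSE]
  }
  best <- NULL
  for (s in sort(cand$snp_id)) {
    ld <- ldEm(d[target, ], d[s, ])
    if (ld$d_prime >= dprimeMin && ld$r2 > r2Min &&
        (is.null(best) || ld$r2 > best$r2))
      best <- list(surrogate = s, r2 = ld$r2, d_prime = ld$d_prime)
  }
  best %||% list(surrogate = NA_character_, r2 = NA_real_,
                 d_prime = NA_real_, reason = "no qualifying candidate")
}

#' Compute the weighted-allele genetic risk score
#'
#' GRS = sum over SNPs of beta_k * X_k, where beta_k is the published
#' per-allele log odds ratio and X_k the effect-allele dosage. The SNP set
#' is the intersection of the genotype matrix and the weight table (its size
#' is logged); sporadically missing dosages are replaced by the SNP's mean
#' dosage over non-missing samples, and the number of non-substituted SNPs
#' is recorded per sample.
#'
#' @param g a [GenotypeExperiment-class] (after QC, oriented to the weight
#'   table's effect alleles).
#' @param weights weight table (see [readWeightTable()]).
#' @return A [ScoreSet-class] of kind \code{"grs"}.
#' @export
computeGrs <- function(g, weights) {
  weights <- asWeightTable(weights)
  common <- intersect(rownames(g), weights$snp_id)
  bcLog("GRS: %d weight-table SNP(s), %d in matrix, %d used",
        nrow(weights), nrow(g), length(common))
  if (!length(common)) bcStop("no SNPs shared between matrix and weight table")
  d <- dosages(g)[common, , drop = FALSE]
  beta <- weights$beta[match(common, weights$snp_id)]
  used <- colSums(!is.na(d))
  snpMean <- rowMeans(d, na.rm = TRUE)
  na <- which(is.na(d), arr.ind = TRUE)
  if (nrow(na)) d[na] <- snpMean[na[, 1]]
  score <- as.numeric(crossprod(d, beta))
  ScoreSet(colnames(d), score, "grs", nFeaturesUsed = used,
           provenance = list(n_snps = length(common),
                             missing_rule = "mean dosage substitution"))
}
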