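# Methylation risk score: probe filtering, control-quartile thresholds,
# direction-aware counting, and the per-CpG association scan.

#' Remove CpG probes with excessive missingness
#'
#' @param m a [MethylationExperiment-class].
#' @param maxMissing maximum tolerated fraction of missing cells per probe
#'   (default 0.10); probes strictly above it are removed.
#' @return filtered [MethylationExperiment-class].
#' @export
filterProbes <- function(m, maxMissing = 0.10) {
  checkFraction(maxMissing, "maxMissing")
  b <- betaValues(m)
  frac <- rowMeans(is.na(b))
  keep <- frac <= maxMissing
  bcLog("probe filter (missing > %g): %d probe(s) in, %d retained",
        maxMissing, nrow(b), sum(keep))
  if (!any(keep)) bcStop("all probes removed by missingness filter")
  m[keep, ]
}

#' Control-distribution quartile thresholds per CpG
#'
#' Computes, for every CpG, the 25th and 75th percentile of the beta-value
#' distribution among controls only, excluding missing cells. These
#' thresholds anchor the quartile-counting methylation risk score. CpGs with
#' fewer than 4 non-missing control values are flagged unusable and excluded
#' from scoring with a warning.
#'
#' @param m a [MethylationExperiment-class].
#' @param labels cohort labels (see [asCohortLabels()]).
#' @param rule quantile type for [stats::quantile()] (default 7, linear
#'   interpolation between order statistics).
#' @return data.frame (cpg_id, q1, q3, n_controls_used, usable).
#' @export
controlQuartiles <- function(m, labels, rule = 7L) {
  labels <- asCohortLabels(labels)
  controls <- labels$sample_id[labels$status == "control"]
  missing <- setdiff(controls, sampleIds(m))
  if (length(missing))
    bcStop("control sample(s) absent from methylation matrix: %s",
           paste(utils::head(missing, 5), collapse = ", "))
  b <- betaValues(m)[, controls, drop = FALSE]
  nUsed <- rowSums(!is.na(b))
  q <- t(apply(b, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 4) return(c(NA_real_, NA_real_))
    stats::quantile(v, c(0.25, 0.75), type = rule, names = FALSE)
  }))
  usable <- nUsed >= 4
  if (any(!usable))
    warning(sprintf("%d CpG(s) with < 4 non-missing control values flagged unusable",
                    sum(!usable)))
  data.frame(cpg_id = rownames(b), q1 = q[, 1], q3 = q[, 2],
             n_controls_used = nUsed, usable = usable,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compute the quartile-counting methylation risk score
#'
#' The MRS of a sample is the number of panel CpGs whose beta value lies
#' beyond the control-quartile threshold in the direction previously
#' reported for disease: hypermethylated CpGs count when strictly above the
#' controls' 75th percentile, hypomethylated CpGs when strictly below the
#' 25th percentile. Ties do not count; missing cells are skipped and the
#' number of CpGs actually evaluated is recorded per sample.
#'
#' @param m a [MethylationExperiment-class] (already probe-filtered).
#' @param panel CpG panel (see [asCpgPanel()]); panel CpGs absent from the
#'   matrix are dropped with a logged count.
#' @param thresholds output of [controlQuartiles()].
#' @return A [ScoreSet-class] of kind \code{"mrs"}; integer-valued scores.
#' @export
computeMrs <- function(m, panel, thresholds) {
  panel <- asCpgPanel(panel)
  b <- betaValues(m)
  present <- panel$cpg_id %in% rownames(b)
  if (any(!present))
    bcLog("MRS panel: %d of %d CpG(s) absent from matrix, dropped",
          sum(!present), nrow(panel))
  panel <- panel[present, , drop = FALSE]
  thr <- thresholds[match(panel$cpg_id, thresholds$cpg_id), , drop = FALSE]
  ok <- !is.na(thr$cpg_id) & thr$usable
  if (any(!ok))
    bcLog("MRS panel: %d CpG(s) without usable thresholds, dropped", sum(!ok))
  panel <- panel[ok, , drop = FALSE]; thr <- thr[ok, , drop = FALSE]
  if (nrow(panel) == 0) bcStop("effective CpG panel is empty")
  bp <- b[panel$cpg_id, , drop = FALSE]
  hyper <- panel$direction == "hyper"
  hit <- matrix(FALSE, nrow(bp), ncol(bp))
  hit[hyper, ] <- sweep(bp[hyper, , drop = FALSE], 1, thr$q3[hyper], ">")
  hit[!hyper, ] <- sweep(bp[!hyper, , drop = FALSE], 1, thr$q1[!hyper], "<")
  hit[is.na(bp)] <- FALSE
  score <- colSums(hit)
  used <- colSums(!is.na(bp))
  if (any(used == 0))
    warning(sprintf("%d sample(s) with no non-missing panel CpGs (score 0, n_features_used 0)",
                    sum(used == 0)))
  ScoreSet(colnames(bp), score, "mrs", nFeaturesUsed = used,
           provenance = list(panel_set = unique(panel$set_label),
                             panel_size = nrow(panel),
                             tie_rule = "strict",
                             quantile_source = "controls"))
}

#' Per-CpG logistic association scan
#'
#' Fits one unconditional logistic regression per CpG (beta value as a
#' continuous exposure) with adjustment covariates (typically age, batch and
#' leukocyte fractions), and applies Benjamini-Hochberg step-up adjustment
#' across all CpGs that produced a p-value. Samples missing the CpG's beta
#' value are dropped per CpG (complete-case); non-convergent or separated
#' fits are reported with a status flag and excluded from the BH family.
#'
#' @param m a [MethylationExperiment-class].
#' @param labels cohort labels.
#' @param covariates data.frame of adjusters with \code{sample_id}; must be
#'   complete for scanned samples. \code{NULL} for crude fits.
#' @return data.frame (cpg_id, or, ci_low, ci_high, p, p_bh, status).
#' @export
cpgAssociationScan <- function(m, labels, covariates = NULL) {
  labels <- asCohortLabels(labels)
  m <- reindexSamples(m, labels$sample_id)
  y <- as.integer(labels$status == "case")
  X <- NULL
  if (!is.null(covariates)) {
    idx <- match(labels$sample_id, covariates$sample_id)
    if (any(is.na(idx))) bcStop("covariates missing for some samples")
    X <- covariates[idx, setdiff(names(covariates), "sample_id"),
                    drop = FALSE]
    if (anyNA(X)) bcStop("adjustment covariates must be complete")
  }
  b <- betaValues(m)
  out <- data.frame(cpg_id = rownames(b), or = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p = NA_real_, p_bh = NA_real_,
                    status = "ok", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(b))) {
    keep <- !is.na(b[i, ])
    df <- data.frame(y = y[keep], beta = b[i, keep])
    if (!is.null(X)) df <- cbind(df, X[keep, , drop = FALSE])
    if (length(unique(df$y)) < 2 || stats::sd(df$beta) == 0) {
      out$status[i] <- "degenerate"
      next
    }
    fit <- fitLogistic(stats::model.matrix(~., df[, -1, drop = FALSE]), df$y)
    if (!fit$converged) {
      out$status[i] <- "non_converged"
      next
    }
    j <- "beta"
    out$or[i] <- fit$or[j]; out$ci_low[i] <- fit$ci_low[j]
    out$ci_high[i] <- fit$ci_high[j]; out$p[i] <- fit$p[j]
  }
  hasP <- !is.na(out$p)
  out$p_bh[hasP] <- stats::p.adjust(out$p[hasP], method = "BH")
  out
}
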