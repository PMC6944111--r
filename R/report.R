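# End-to-end association/prediction report for a set of risk scores,
# mirroring the usual presentation in nested case-control studies: one
# quartile-OR block and OR-per-SD per score (Model I), mutually adjusted
# estimates (Model II), single-score and combined AUCs, cross-validated
# AUC of the full model, and its calibration.

# leukocyte fractions sum to one per sample, so one cell type must serve
# as the reference; the most abundant column is dropped
dropReferenceFraction <- function(frac) {
  num <- setdiff(names(frac), "sample_id")
  if (length(num) < 2) return(frac)
  sums <- rowSums(frac[, num, drop = FALSE])
  if (all(abs(sums - 1) < 1e-6)) {
    ref <- num[which.max(colMeans(frac[, num, drop = FALSE]))]
    bcLog("leukocyte fractions sum to 1; dropping '%s' as reference", ref)
    frac <- frac[, setdiff(names(frac), ref), drop = FALSE]
  }
  frac
}

#' Full association and prediction report for a set of risk scores
#'
#' For each score: control-quartile odds ratios, OR per SD and AUC, crudely
#' (Model I; methylation scores are additionally adjusted for leukocyte
#' composition) and mutually adjusted for the complementary scores plus
#' leukocyte composition (Model II). For the full combination: multivariable
#' fit, apparent and cross-validated AUC, and Hosmer-Lemeshow calibration.
#'
#' @param scores named list of [ScoreSet-class] objects.
#' @param labels cohort labels.
#' @param leukocytes optional data.frame of leukocyte fractions with
#'   \code{sample_id} (one fraction is dropped as reference when they sum
#'   to 1).
#' @param cvFolds,cvRepetitions,seed cross-validation layout for the
#'   combined model (\code{cvRepetitions = 0} skips it).
#' @return nested list of class \code{"RiskScoreReport"} with one block per
#'   score and a \code{combined} block.
#' @export
riskScoreReport <- function(scores, labels, leukocytes = NULL,
                            cvFolds = 10L, cvRepetitions = 100L, seed = 1L) {
  stopifnot(is.list(scores), !is.null(names(scores)))
  labels <- asCohortLabels(labels)
  leuk <- if (!is.null(leukocytes)) dropReferenceFraction(leukocytes)
  perScore <- list()
  for (nm in names(scores)) {
    s <- scores[[nm]]
    isMrs <- is(s, "ScoreSet") && scoreKind(s) == "mrs"
    adj1 <- if (isMrs) leuk else NULL
    others <- scores[setdiff(names(scores), nm)]
    adj2 <- data.frame(sample_id = labels$sample_id,
                       stringsAsFactors = FALSE)
    for (o in names(others))
      adj2[[o]] <- scoreValues(others[[o]])[labels$sample_id]
    if (!is.null(leuk))
      adj2 <- merge(adj2, leuk, by = "sample_id", sort = FALSE)
    adj2 <- adj2[stats::complete.cases(adj2), , drop = FALSE]
    keepLab <- labels[labels$sample_id %in% adj2$sample_id, , drop = FALSE]
    perScore[[nm]] <- list(
      quartiles_model1 = quartileOr(s, labels, adjust = adj1),
      or_per_sd_model1 = orPerSd(s, labels, adjust = adj1),
      quartiles_model2 = quartileOr(s, keepLab, adjust = adj2),
      or_per_sd_model2 = orPerSd(s, keepLab, adjust = adj2),
      auc = computeAuc(s, labels))
  }
  combined <- combineScores(scores, labels, adjust = leuk, cvFolds = cvFolds,
                            cvRepetitions = cvRepetitions, seed = seed)
  y <- as.integer(labels$status[match(names(combined$fitted),
                                      labels$sample_id)] == "case")
  hl <- tryCatch(hosmerLemeshow(as.numeric(combined$fitted), y),
                 error = function(e) NULL)
  corr <- if (length(scores) >= 2) scoreCorrelations(scores) else NULL
  out <- list(scores = perScore, combined = combined,
              hosmer_lemeshow = hl, correlations = corr)
  class(out) <- "RiskScoreReport"
  out
}

#' Serialise a report to JSON
#'
#' @param report a \code{RiskScoreReport}.
#' @param path output JSON path.
#' @export
writeReportJson <- function(report, path) {
  slim <- function(x) {
    if (inherits(x, "LogisticFit"))
      return(list(or = as.list(x$or), ci_low = as.list(x$ci_low),
                  ci_high = as.list(x$ci_high), p = as.list(x$p),
                  converged = x$converged, n = x$n))
    if (inherits(x, "QuartileOr"))
      return(list(edges = as.numeric(x$edges),
                  counts = apply(x$counts, 2, as.numeric, simplify = FALSE),
                  or = as.list(x$or), ci_low = as.list(x$ci_low),
                  ci_high = as.list(x$ci_high)))
    if (inherits(x, c("OrPerSd", "AucResult", "HosmerLemeshow")))
      return(x[setdiff(names(x), c("fit", "table"))])
    if (inherits(x, "CvResult"))
      return(x[c("mean_auc", "ci_low", "ci_high", "folds", "repetitions")])
    if (inherits(x, "CombinedScores"))
      return(list(fit = slim(x$fit), apparent_auc = slim(x$apparent_auc),
                  cv = if (!is.null(x$cv)) slim(x$cv)))
    if (is.list(x)) return(lapply(x, slim))
    x
  }
  jsonlite::write_json(slim(unclass(report)), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
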