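# Statistical evaluation of risk scores in a nested case-control sample:
# unconditional logistic models, control-quartile odds ratios with Wald
# intervals, OR per SD, AUC with DeLong intervals, repeated stratified
# k-fold cross-validation, Hosmer-Lemeshow calibration, Pearson score
# correlations and time-to-diagnosis subsetting.

#' Unconditional logistic regression with Wald intervals
#'
#' Maximum-likelihood fit by iteratively reweighted least squares (via
#' [stats::glm.fit()]) with a tight convergence tolerance. Complete or
#' quasi-complete separation is flagged (diverging coefficients or exploding
#' standard errors) and no odds ratios are reported for such fits.
#'
#' @param design numeric model matrix including an intercept column.
#' @param y 0/1 outcome vector (1 = case).
#' @return list of class \code{"LogisticFit"}: \code{coef}, \code{se},
#'   \code{or}, \code{ci_low}, \code{ci_high} (95\% Wald, exp(coef +/-
#'   1.96 se)), \code{p}, \code{log_lik}, \code{converged},
#'   \code{n_iterations}, \code{n}.
#' @export
fitLogistic <- function(design, y) {
  design <- as.matrix(design)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(design) == length(y))
  if (nrow(design) <= ncol(design))
    bcStop("need more observations (%d) than parameters (%d)",
           nrow(design), ncol(design))
  nm <- colnames(design)
  # aliased (linearly dependent) columns are dropped and reported NA
  qrd <- qr(design)
  aliased <- if (qrd$rank < ncol(design))
    qrd$pivot[(qrd$rank + 1):ncol(design)] else integer(0)
  keep <- setdiff(seq_len(ncol(design)), aliased)
  X <- design[, keep, drop = FALSE]
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  b <- fit$coefficients
  nIter <- fit$iter
  # Newton polish: IRLS stops on deviance change, which is quadratic in the
  # coefficient error; iterate until the step itself is tiny so closed-form
  # identities (2x2 cross-products) hold to ~1e-12
  vc <- NULL
  separated <- anyNA(b)
  if (!separated) {
    for (it in 1:25) {
      p <- stats::plogis(as.numeric(X %*% b))
      wts <- pmax(p * (1 - p), 1e-12)
      H <- crossprod(X * wts, X)
      vc <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
      if (is.null(vc)) { separated <- TRUE; break }
      step <- vc %*% crossprod(X, y - p)
      b <- b + as.numeric(step)
      nIter <- nIter + 1L
      if (max(abs(step)) < 1e-12) break
    }
  }
  separated <- separated || is.null(vc) || max(abs(b)) > 15 ||
    any(sqrt(diag(vc)) > 100)
  converged <- isTRUE(fit$converged) && !separated
  expand <- function(v) {
    full <- stats::setNames(rep(NA_real_, ncol(design)), nm)
    full[keep] <- v
    full
  }
  coef <- expand(b)
  se <- expand(if (is.null(vc)) rep(NA_real_, length(b)) else sqrt(diag(vc)))
  fitted <- stats::plogis(as.numeric(X %*% b))
  ll <- sum(y * log(fitted) + (1 - y) * log(1 - fitted))
  out <- list(coef = coef, se = se,
              or = if (converged) exp(coef) else stats::setNames(
                rep(NA_real_, length(coef)), nm),
              ci_low = if (converged) exp(coef - 1.96 * se) else
                stats::setNames(rep(NA_real_, length(coef)), nm),
              ci_high = if (converged) exp(coef + 1.96 * se) else
                stats::setNames(rep(NA_real_, length(coef)), nm),
              p = stats::setNames(
                2 * stats::pnorm(-abs(coef / se)), nm),
              log_lik = ll, converged = converged,
              n_iterations = nIter, n = length(y),
              fitted = fitted)
  class(out) <- "LogisticFit"
  out
}

#' @export
print.LogisticFit <- function(x, ...) {
  cat(sprintf("LogisticFit (n = %d, %s, %d iterations)\n", x$n,
              if (x$converged) "converged" else "NOT converged/separated",
              x$n_iterations))
  print(data.frame(coef = x$coef, se = x$se, OR = x$or,
                   ci_low = x$ci_low, ci_high = x$ci_high, p = x$p))
  invisible(x)
}

# align a ScoreSet (or named/plain numeric) to the labels' sample order;
# NA scores (e.g. samples excluded by an ERS inclusion predicate) are
# dropped together with their labels
alignScore <- function(score, labels) {
  labels <- asCohortLabels(labels)
  v <- if (is(score, "ScoreSet")) {
    sv <- scoreValues(score)
    missing <- setdiff(labels$sample_id, names(sv))
    if (length(missing))
      bcStop("score missing for sample(s): %s",
             paste(utils::head(missing, 5), collapse = ", "))
    sv[labels$sample_id]
  } else if (!is.null(names(score))) {
    score[labels$sample_id]
  } else {
    if (length(score) != nrow(labels))
      bcStop("unnamed score vector of wrong length")
    score
  }
  keep <- !is.na(v)
  if (any(!keep))
    bcLog("dropping %d sample(s) with NA score", sum(!keep))
  list(value = as.numeric(v[keep]), labels = labels[keep, , drop = FALSE])
}

adjustMatrix <- function(adjust, sampleId) {
  if (is.null(adjust)) return(NULL)
  idx <- match(sampleId, adjust$sample_id)
  if (anyNA(idx)) bcStop("adjustment covariates missing for some samples")
  X <- adjust[idx, setdiff(names(adjust), "sample_id"), drop = FALSE]
  if (anyNA(X)) bcStop("adjustment covariates must be complete")
  m <- stats::model.matrix(~ . - 1, data = X)
  m
}

#' Control-quartile odds ratios for a risk score
#'
#' Bin edges are the 25th/50th/75th percentiles of the score among CONTROLS
#' only; all samples are then assigned by the edges (Q1 closed on the right:
#' Q1 <= e1 < Q2 <= e2 < Q3 <= e3 < Q4) and case status is regressed on the
#' three upper-quartile indicators (plus any adjusters), the lowest quartile
#' being the reference. Unadjusted indicator ORs equal the per-bin
#' cross-product ratios.
#'
#' @param score a [ScoreSet-class] or numeric vector named by sample id.
#' @param labels cohort labels (need >= 8 controls).
#' @param adjust optional data.frame of adjustment covariates with
#'   \code{sample_id}.
#' @param rule quantile type (default 7).
#' @return list of class \code{"QuartileOr"}: \code{edges}, \code{counts}
#'   (bin x status), \code{or}, \code{ci_low}, \code{ci_high}, \code{p} per
#'   upper bin, \code{fit}, \code{bin} assignments.
#' @export
quartileOr <- function(score, labels, adjust = NULL, rule = 7L) {
  al <- alignScore(score, labels)
  v <- al$value; lab <- al$labels
  ctrl <- v[lab$status == "control"]
  if (length(ctrl) < 8) bcStop("need >= 8 controls for quartile binning")
  edges <- stats::quantile(ctrl, c(0.25, 0.5, 0.75), type = rule,
                           names = FALSE)
  if (edges[1] == edges[3])
    bcStop("degenerate quartile edges (score nearly constant among controls)")
  bin <- 1L + (v > edges[1]) + (v > edges[2]) + (v > edges[3])
  y <- as.integer(lab$status == "case")
  counts <- table(factor(bin, 1:4, labels = paste0("Q", 1:4)),
                  factor(y, 0:1, labels = c("control", "case")))
  empty <- rowSums(counts) == 0
  if (any(empty))
    warning(sprintf("empty quartile bin(s): %s - OR omitted",
                    paste(rownames(counts)[empty], collapse = ", ")))
  ind <- stats::model.matrix(~ factor(bin, levels = sort(unique(bin))))
  colnames(ind) <- c("(Intercept)",
                     paste0("Q", sort(unique(bin))[-1]))
  A <- adjustMatrix(adjust, lab$sample_id)
  design <- if (is.null(A)) ind else cbind(ind, A)
  fit <- fitLogistic(design, y)
  res <- stats::setNames(rep(NA_real_, 3), paste0("Q", 2:4))
  orv <- ciL <- ciH <- pv <- res
  for (q in paste0("Q", 2:4)) if (q %in% names(fit$or)) {
    orv[q] <- fit$or[q]; ciL[q] <- fit$ci_low[q]
    ciH[q] <- fit$ci_high[q]; pv[q] <- fit$p[q]
  }
  out <- list(edges = edges, counts = unclass(counts), or = orv,
              ci_low = ciL, ci_high = ciH, p = pv, fit = fit, bin = bin)
  class(out) <- "QuartileOr"
  out
}

#' @export
print.QuartileOr <- function(x, ...) {
  cat(sprintf("Control-quartile odds ratios (edges %s)\n",
              paste(signif(x$edges, 4), collapse = ", ")))
  df <- data.frame(cases = x$counts[, "case"],
                   controls = x$counts[, "control"],
                   OR = c(1, x$or), ci_low = c(NA, x$ci_low),
                   ci_high = c(NA, x$ci_high))
  rownames(df)[1] <- "Q1 (ref)"
  print(df)
  invisible(x)
}

#' Odds ratio per standard-deviation increase of a score
#'
#' The score is divided by its SD over the whole analysis sample (cases and
#' controls together, the default) or over controls only, and case status is
#' regressed on the standardized score plus any adjusters.
#'
#' @param score a [ScoreSet-class] or numeric vector.
#' @param labels cohort labels.
#' @param adjust optional adjustment covariate data.frame.
#' @param sdScope \code{"all"} (default) or \code{"controls"}.
#' @return list of class \code{"OrPerSd"}: \code{or}, \code{ci_low},
#'   \code{ci_high}, \code{p}, \code{sd}, \code{fit}.
#' @export
orPerSd <- function(score, labels, adjust = NULL, sdScope = c("all", "controls")) {
  sdScope <- match.arg(sdScope)
  al <- alignScore(score, labels)
  v <- al$value; lab <- al$labels
  s <- if (sdScope == "all") stats::sd(v)
       else stats::sd(v[lab$status == "control"])
  if (!is.finite(s) || s == 0) bcStop("score has zero SD")
  y <- as.integer(lab$status == "case")
  A <- adjustMatrix(adjust, lab$sample_id)
  design <- cbind("(Intercept)" = 1, score_sd = v / s)
  if (!is.null(A)) design <- cbind(design, A)
  fit <- fitLogistic(design, y)
  out <- list(or = unname(fit$or["score_sd"]),
              ci_low = unname(fit$ci_low["score_sd"]),
              ci_high = unname(fit$ci_high["score_sd"]),
              p = unname(fit$p["score_sd"]), sd = s, fit = fit)
  class(out) <- "OrPerSd"
  out
}

#' @export
print.OrPerSd <- function(x, ...) {
  cat(sprintf("OR per SD increase: %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$or, x$ci_low, x$ci_high, x$p))
  invisible(x)
}

#' Area under the ROC curve with DeLong confidence interval
#'
#' Mann-Whitney estimator (ties counted 1/2) with the DeLong variance for
#' the 95\% interval. A constant score yields AUC exactly 0.5 with a
#' degenerate interval.
#'
#' @param score a [ScoreSet-class], a numeric vector named by sample id, or
#'   fitted probabilities aligned to \code{labels}.
#' @param labels cohort labels (>= 1 case and >= 1 control).
#' @return list of class \code{"AucResult"}: \code{auc}, \code{ci_low},
#'   \code{ci_high}, \code{method}, \code{n_cases}, \code{n_controls}.
#' @export
computeAuc <- function(score, labels) {
  al <- alignScore(score, labels)
  v <- al$value; lab <- al$labels
  nCase <- sum(lab$status == "case"); nCtrl <- sum(lab$status == "control")
  if (nCase < 1 || nCtrl < 1) bcStop("need >= 1 case and >= 1 control")
  if (stats::sd(v) == 0) {
    out <- list(auc = 0.5, ci_low = 0.5, ci_high = 0.5, method = "delong",
                n_cases = nCase, n_controls = nCtrl)
    class(out) <- "AucResult"
    return(out)
  }
  r <- pROC::roc(response = lab$status, predictor = v,
                 levels = c("control", "case"), direction = "<",
                 quiet = TRUE)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  out <- list(auc = as.numeric(pROC::auc(r)),
              ci_low = max(0, ci[1]), ci_high = min(1, ci[3]),
              method = "delong", n_cases = nCase, n_controls = nCtrl)
  class(out) <- "AucResult"
  out
}

#' @export
print.AucResult <- function(x, ...) {
  cat(sprintf("AUC = %.3f (95%% CI %.3f-%.3f; %d cases, %d controls)\n",
              x$auc, x$ci_low, x$ci_high, x$n_cases, x$n_controls))
  invisible(x)
}

scoreFrame <- function(scores, labels) {
  if (is(scores, "ScoreSet")) scores <- list(scores)
  if (is.null(names(scores)) || any(names(scores) == ""))
    names(scores) <- vapply(seq_along(scores), function(i) {
      k <- if (is(scores[[i]], "ScoreSet")) scoreKind(scores[[i]]) else "score"
      paste0(k, i)
    }, "")
  labels <- asCohortLabels(labels)
  df <- data.frame(row.names = labels$sample_id)
  for (nm in names(scores)) {
    al <- alignScore(scores[[nm]], labels)
    v <- rep(NA_real_, nrow(labels))
    v[match(al$labels$sample_id, labels$sample_id)] <- al$value
    df[[nm]] <- v
  }
  keep <- stats::complete.cases(df)
  if (any(!keep)) bcLog("dropping %d sample(s) lacking some score", sum(!keep))
  list(df = df[keep, , drop = FALSE], labels = labels[keep, , drop = FALSE])
}

#' Multivariable combination of risk scores
#'
#' Fits one logistic model on all supplied scores (plus adjusters), reports
#' the apparent AUC of the fitted probabilities and, optionally, the
#' cross-validated AUC from repeated stratified k-fold cross-validation.
#' Strong collinearity between scores triggers a warning (condition-number
#' guard); the unpenalised fit is still attempted and separation rules
#' apply.
#'
#' @param scores named list of [ScoreSet-class] objects (or numeric vectors
#'   named by sample id).
#' @param labels cohort labels.
#' @param adjust optional adjustment covariate data.frame.
#' @param cvFolds,cvRepetitions,seed cross-validation layout; set
#'   \code{cvRepetitions = 0} to skip cross-validation.
#' @return list of class \code{"CombinedScores"}: \code{fit},
#'   \code{apparent_auc} ([computeAuc()] result), \code{cv}
#'   ([crossValidate()] result or NULL), \code{fitted} probabilities.
#' @export
combineScores <- function(scores, labels, adjust = NULL, cvFolds = 10L,
                          cvRepetitions = 50L, seed = 1L) {
  sf <- scoreFrame(scores, labels)
  y <- as.integer(sf$labels$status == "case")
  X <- as.matrix(sf$df)
  A <- adjustMatrix(adjust, sf$labels$sample_id)
  design <- cbind("(Intercept)" = 1, X)
  if (!is.null(A)) design <- cbind(design, A)
  k <- kappa(design, exact = TRUE)
  if (k > 1e8) warning(sprintf("near-collinear design (condition number %.3g)", k))
  fit <- fitLogistic(design, y)
  app <- computeAuc(stats::setNames(fit$fitted, sf$labels$sample_id),
                    sf$labels)
  cv <- if (cvRepetitions > 0)
    crossValidate(scores, labels, adjust = adjust, folds = cvFolds,
                  repetitions = cvRepetitions, seed = seed) else NULL
  out <- list(fit = fit, apparent_auc = app, cv = cv,
              fitted = stats::setNames(fit$fitted, sf$labels$sample_id))
  class(out) <- "CombinedScores"
  out
}

# stratified fold assignment preserving the case:control ratio
stratifiedFolds <- function(y, folds) {
  f <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

#' Repeated stratified k-fold cross-validated AUC
#'
#' Per repetition the sample is randomly partitioned into \code{folds}
#' stratified subsamples; each fold is predicted by a logistic model fitted
#' on the remaining folds, out-of-fold probabilities are pooled, and one AUC
#' is computed. The summary is the mean and empirical 2.5/97.5 percentiles
#' over repetitions. Deterministic given \code{seed}.
#'
#' @param scores named list of scores (see [combineScores()]).
#' @param labels cohort labels.
#' @param adjust optional adjustment covariates.
#' @param folds number of folds (>= 2; each fold must receive >= 1 case and
#'   >= 1 control, otherwise the partition is redrawn, up to 100 attempts).
#' @param repetitions number of repeated partitions.
#' @param seed integer seed.
#' @return list of class \code{"CvResult"}: \code{auc} (per repetition),
#'   \code{mean_auc}, \code{ci_low}, \code{ci_high} (empirical percentiles),
#'   \code{folds}, \code{repetitions}, \code{seed}.
#' @export
crossValidate <- function(scores, labels, adjust = NULL, folds = 10L,
                          repetitions = 100L, seed = 1L) {
  if (folds < 2) bcStop("folds must be >= 2")
  sf <- scoreFrame(scores, labels)
  y <- as.integer(sf$labels$status == "case")
  X <- as.matrix(sf$df)
  A <- adjustMatrix(adjust, sf$labels$sample_id)
  base <- cbind("(Intercept)" = 1, X)
  if (!is.null(A)) base <- cbind(base, A)
  set.seed(substreamSeed(seed, "cv"))
  aucs <- numeric(repetitions)
  for (r in seq_len(repetitions)) {
    ok <- FALSE
    for (attempt in 1:100) {
      f <- stratifiedFolds(y, folds)
      tab <- table(factor(f, seq_len(folds)), y)
      if (all(tab > 0)) { ok <- TRUE; break }
    }
    if (!ok) bcStop("could not build folds with >= 1 case and control each")
    p <- rep(NA_real_, length(y))
    for (k in seq_len(folds)) {
      test <- f == k
      fit <- suppressWarnings(
        stats::glm.fit(base[!test, , drop = FALSE], y[!test],
                       family = stats::binomial(),
                       control = stats::glm.control(epsilon = 1e-8,
                                                    maxit = 100)))
      eta <- base[test, , drop = FALSE] %*% fit$coefficients
      p[test] <- stats::plogis(as.numeric(eta))
    }
    aucs[r] <- mannWhitneyAuc(p, y)
  }
  out <- list(auc = aucs, mean_auc = mean(aucs),
              ci_low = as.numeric(stats::quantile(aucs, 0.025)),
              ci_high = as.numeric(stats::quantile(aucs, 0.975)),
              folds = as.integer(folds),
              repetitions = as.integer(repetitions), seed = as.integer(seed))
  class(out) <- "CvResult"
  out
}

#' @export
print.CvResult <- function(x, ...) {
  cat(sprintf("Cross-validated AUC: mean %.3f (2.5-97.5%%: %.3f-%.3f) over %d x %d-fold\n",
              x$mean_auc, x$ci_low, x$ci_high, x$repetitions, x$folds))
  invisible(x)
}

# fast Mann-Whitney AUC (ties counted 1/2)
mannWhitneyAuc <- function(pred, y) {
  r <- rank(pred)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hosmer-Lemeshow calibration test
#'
#' Samples are ordered by fitted probability (ties broken by stable sample
#' order) and split into \code{groups} near-equal groups; the statistic is
#' the sum over groups of (O - E)^2 / (E (1 - E / n_g)) for the event class,
#' referred to a chi-square with \code{groups - 2} degrees of freedom.
#' Groups with expected count 0 are merged downward with a warning.
#'
#' @param p fitted probabilities.
#' @param y 0/1 outcomes.
#' @param groups number of probability groups (default 10; must be >= 3 and
#'   \code{length(y) >= 5 * groups}).
#' @return list of class \code{"HosmerLemeshow"}: \code{statistic},
#'   \code{df}, \code{p_value}, \code{table} (per group n, observed,
#'   expected).
#' @export
hosmerLemeshow <- function(p, y, groups = 10L) {
  stopifnot(length(p) == length(y), all(y %in% c(0, 1)),
            all(p >= 0 & p <= 1))
  if (groups < 3) bcStop("groups must be >= 3 (df = groups - 2 > 0)")
  n <- length(y)
  if (n < 5 * groups) bcStop("need n >= 5 * groups (%d < %d)", n, 5 * groups)
  ord <- order(p, seq_along(p))
  sizes <- rep(n %/% groups, groups) + c(rep(1, n %% groups),
                                         rep(0, groups - n %% groups))
  g <- rep(seq_len(groups), sizes)[order(ord)]
  O <- tapply(y, g, sum)
  E <- tapply(p, g, sum)
  Ng <- tapply(rep(1, n), g, sum)
  # merge groups with zero expected events downward
  while (any(E == 0) && length(E) > 3) {
    i <- which(E == 0)[1]
    j <- if (i == 1) 2 else i - 1
    warning("merging a probability group with expected count 0")
    O[j] <- O[j] + O[i]; E[j] <- E[j] + E[i]; Ng[j] <- Ng[j] + Ng[i]
    O <- O[-i]; E <- E[-i]; Ng <- Ng[-i]
  }
  stat <- sum((O - E)^2 / (E * (1 - E / Ng)))
  df <- length(E) - 2
  out <- list(statistic = stat, df = df,
              p_value = stats::pchisq(stat, df, lower.tail = FALSE),
              table = data.frame(n = as.numeric(Ng), observed = as.numeric(O),
                                 expected = as.numeric(E)))
  class(out) <- "HosmerLemeshow"
  out
}

#' @export
print.HosmerLemeshow <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow: chi2 = %.3f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Pairwise Pearson correlations between risk scores
#'
#' @param scores named list of [ScoreSet-class] objects covering the same
#'   samples; each score must be non-constant.
#' @return list: \code{r} (symmetric correlation matrix, unit diagonal) and
#'   \code{p} (two-sided p-values, NA on the diagonal).
#' @export
scoreCorrelations <- function(scores) {
  stopifnot(length(scores) >= 2)
  ids <- Reduce(intersect, lapply(scores, sampleIds))
  if (length(ids) < 3) bcStop("fewer than 3 shared samples")
  m <- sapply(scores, function(s) scoreValues(s)[ids])
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  if (any(apply(m, 2, stats::sd) == 0)) bcStop("constant score supplied")
  k <- ncol(m)
  r <- diag(1, k); p <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(p) <- list(colnames(m), colnames(m))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ct <- stats::cor.test(m[, i], m[, j], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p, n = nrow(m))
}

#' Restrict cases by time to diagnosis
#'
#' Keeps cases whose time between recruitment and diagnosis is at most
#' (\code{side = "le"}, inclusive) or strictly greater than
#' (\code{side = "gt"}) the cutoff; all controls are retained.
#'
#' @param labels cohort labels; cases must carry
#'   \code{time_to_diagnosis_years}.
#' @param cutoffYears cutoff (default 7).
#' @param side \code{"le"} or \code{"gt"}.
#' @return filtered labels data.frame.
#' @export
subsetByFollowup <- function(labels, cutoffYears = 7, side = c("le", "gt")) {
  side <- match.arg(side)
  labels <- asCohortLabels(labels)
  isCase <- labels$status == "case"
  t <- labels$time_to_diagnosis_years
  if (any(isCase & is.na(t)))
    bcStop("all cases must carry time_to_diagnosis_years")
  keep <- !isCase | (if (side == "le") t <= cutoffYears else t > cutoffYears)
  labels[keep, , drop = FALSE]
}
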