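# Environmental risk score engine: published coefficient tables are
# expressed as ErsCoefficientSpec documents (YAML) and applied as linear
# predictors over categorized covariates, with within-group mean imputation
# for incomplete baseline variables.

#' Within-group mean imputation of baseline variables
#'
#' Missing values of the listed variables are replaced by the mean of the
#' observed values within the sample's case/control group, the convention
#' used for incomplete baseline questionnaire variables in nested
#' case-control analyses. Variables not listed are left untouched. Means are
#' not rounded before downstream categorization.
#'
#' @param covariates covariate data.frame with \code{sample_id}.
#' @param labels cohort labels.
#' @param variables character vector of (numeric or ordinal-coded) variable
#'   names to impute.
#' @return covariate data.frame with an \code{"imputation_log"} attribute
#'   (variable, group, n_imputed, fill_value).
#' @export
imputeWithinGroup <- function(covariates, labels, variables) {
  labels <- asCohortLabels(labels)
  idx <- match(covariates$sample_id, labels$sample_id)
  if (any(is.na(idx))) bcStop("covariate sample(s) absent from labels")
  grp <- labels$status[idx]
  log <- list()
  for (v in variables) {
    if (!v %in% names(covariates)) bcStop("unknown variable '%s'", v)
    x <- covariates[[v]]
    if (!is.numeric(x)) bcStop("variable '%s' is not numeric; recode before imputation", v)
    for (g in c("case", "control")) {
      inG <- grp == g
      obs <- x[inG & !is.na(x)]
      nMiss <- sum(inG & is.na(x))
      if (nMiss > 0 && length(obs) == 0)
        bcStop("no observed values of '%s' among %ss to impute from", v, g)
      if (nMiss > 0) {
        fill <- mean(obs)
        x[inG & is.na(x)] <- fill
        log[[length(log) + 1]] <- data.frame(
          variable = v, group = g, n_imputed = nMiss, fill_value = fill,
          stringsAsFactors = FALSE)
        bcLog("imputed %d %s value(s) of '%s' with group mean %.4g",
              nMiss, g, v, fill)
      }
    }
    covariates[[v]] <- x
  }
  attr(covariates, "imputation_log") <-
    if (length(log)) do.call(rbind, log) else NULL
  covariates
}

#' Read an environmental risk score coefficient specification
#'
#' A coefficient spec names the score and lists one rule per variable:
#' continuous rules carry \code{beta} (per unit) and an optional
#' \code{center}; categorical rules carry either sorted \code{breaks}
#' defining half-open intervals (lower bound inclusive) with one
#' \code{beta} per interval, or a \code{levels} map from level label to
#' beta. Exactly one beta per categorical rule must be 0 (the reference).
#' An optional \code{inclusion} block restricts scoring to samples with a
#' given level of one categorical variable (e.g. postmenopausal women only),
#' and \code{unavailable} lists variables the score was published with but
#' that are dropped here.
#'
#' @param path YAML path.
#' @return list of class \code{"ErsCoefficientSpec"}.
#' @export
readErsSpec <- function(path) {
  spec <- yaml::read_yaml(path)
  class(spec) <- "ErsCoefficientSpec"
  spec
}

#' @rdname readErsSpec
#' @param spec an \code{ErsCoefficientSpec}
#' @export
writeErsSpec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' Validate an ERS coefficient spec against a covariate table
#'
#' Checks that every rule references a declared covariate, that interval
#' rules have strictly increasing breakpoints (no gaps or overlaps by
#' construction) with one beta per interval, that each categorical rule has
#' a reference beta of 0, and reports the variables declared unavailable.
#'
#' @param spec an \code{ErsCoefficientSpec}.
#' @param covariates covariate data.frame.
#' @return invisible list \code{(ok, unavailable, n_rules)}; errors on an
#'   invalid spec.
#' @export
validateErsSpec <- function(spec, covariates) {
  if (is.null(spec$score_name)) bcStop("ERS spec: missing score_name")
  if (!length(spec$variables)) bcStop("ERS spec: no variable rules")
  for (rule in spec$variables) {
    v <- rule$name
    if (is.null(v)) bcStop("ERS spec: rule without a variable name")
    if (!v %in% names(covariates))
      bcStop("ERS spec: rule for undeclared variable '%s'", v)
    if (identical(rule$type, "continuous")) {
      if (!is.numeric(rule$beta) || length(rule$beta) != 1)
        bcStop("ERS spec: continuous rule '%s' needs a single beta", v)
    } else if (identical(rule$type, "categorical")) {
      if (!is.null(rule$breaks)) {
        br <- as.numeric(rule$breaks)
        if (is.unsorted(br, strictly = TRUE))
          bcStop("ERS spec: breaks of '%s' must be strictly increasing (overlapping or gapped intervals)", v)
        if (length(rule$betas) != length(br) - 1)
          bcStop("ERS spec: '%s' needs one beta per interval (%d intervals, %d betas)",
                 v, length(br) - 1, length(rule$betas))
        if (!any(rule$betas == 0))
          bcStop("ERS spec: '%s' lacks a reference interval with beta 0", v)
      } else if (!is.null(rule$levels)) {
        if (!any(unlist(rule$levels) == 0))
          bcStop("ERS spec: '%s' lacks a reference level with beta 0", v)
      } else bcStop("ERS spec: categorical rule '%s' needs breaks or levels", v)
    } else bcStop("ERS spec: rule '%s' has unknown type '%s'", v,
                  rule$type %||% "<none>")
  }
  if (!is.null(spec$inclusion) &&
      !spec$inclusion$variable %in% names(covariates))
    bcStop("ERS spec: inclusion variable '%s' not declared",
           spec$inclusion$variable)
  unavailable <- unlist(spec$unavailable) %||% character(0)
  if (length(unavailable))
    bcLog("ERS '%s': built without unavailable variable(s): %s",
          spec$score_name, paste(unavailable, collapse = ", "))
  invisible(list(ok = TRUE, unavailable = unavailable,
                 n_rules = length(spec$variables)))
}

ersRuleValue <- function(rule, x, sampleId) {
  v <- rule$name
  if (anyNA(x))
    bcStop("missing value of '%s' (sample %s): run imputeWithinGroup first",
           v, paste(utils::head(sampleId[is.na(x)], 3), collapse = ", "))
  if (identical(rule$type, "continuous")) {
    center <- rule$center %||% 0
    return(rule$beta * (as.numeric(x) - center))
  }
  if (!is.null(rule$breaks)) {
    br <- as.numeric(rule$breaks)
    xn <- as.numeric(x)
    # half-open intervals [br[i], br[i+1]), lower bound inclusive
    bin <- findInterval(xn, br, rightmost.closed = FALSE, left.open = FALSE)
    out <- xn < br[1] | xn >= br[length(br)]
    if (any(out))
      bcStop("value of '%s' outside every interval (sample %s, value %g)",
             v, sampleId[which(out)[1]], xn[which(out)[1]])
    return(as.numeric(rule$betas)[bin])
  }
  lv <- rule$levels
  hit <- match(as.character(x), names(lv))
  if (anyNA(hit))
    bcStop("level '%s' of '%s' (sample %s) not in spec",
           as.character(x)[which(is.na(hit))[1]], v,
           sampleId[which(is.na(hit))[1]])
  unlist(lv)[hit]
}

#' Compute a coefficient-table environmental risk score
#'
#' Per sample, the score is the sum over rules of beta * value (continuous)
#' or the beta of the matched interval/level (categorical). Samples excluded
#' by the spec's inclusion predicate receive \code{NA} and are flagged.
#'
#' @param covariates covariate data.frame (complete for all spec variables;
#'   see [imputeWithinGroup()]).
#' @param spec an \code{ErsCoefficientSpec} (validated against
#'   \code{covariates}).
#' @return A [ScoreSet-class] of kind \code{"ers"}.
#' @export
computeLinearErs <- function(covariates, spec) {
  validateErsSpec(spec, covariates)
  ids <- as.character(covariates$sample_id)
  include <- rep(TRUE, nrow(covariates))
  if (!is.null(spec$inclusion)) {
    incl <- spec$inclusion
    include <- as.character(covariates[[incl$variable]]) ==
      as.character(incl$level)
    include[is.na(include)] <- FALSE
    bcLog("ERS '%s': inclusion %s == %s keeps %d of %d samples",
          spec$score_name, incl$variable, incl$level, sum(include),
          length(include))
  }
  score <- rep(NA_real_, nrow(covariates))
  inc <- which(include)
  vals <- rep(0, length(inc))
  for (rule in spec$variables)
    vals <- vals + ersRuleValue(rule, covariates[[rule$name]][inc], ids[inc])
  score[inc] <- vals
  ScoreSet(ids, score, "ers",
           nFeaturesUsed = ifelse(include, length(spec$variables), 0L),
           provenance = list(score_name = spec$score_name,
                             unavailable = unlist(spec$unavailable) %||%
                               character(0)))
}
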