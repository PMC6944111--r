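# Tabular readers/writers. All tables are tab-separated UTF-8 with one header
# row; matrices are stored on disk as samples x features (the orientation in
# which cohort files are usually shipped) and transposed to features x samples
# in memory. Missing cells are written "NA"; both "NA" and the empty string
# are accepted on read.

readTsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", na.strings = c("NA", ""),
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = NA, fileEncoding = "UTF-8")
}

writeTsv <- function(df, path) {
  # %.17g keeps short decimals short while making every double round-trip
  # bit-exactly through its decimal representation
  for (j in seq_along(df))
    if (is.double(df[[j]])) {
      v <- sprintf("%.17g", df[[j]])
      v[is.na(df[[j]])] <- NA_character_
      df[[j]] <- v
    }
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# read a samples-x-features numeric TSV (first column = sample_id),
# return features x samples matrix
readSampleMatrix <- function(path) {
  df <- readTsv(path)
  if (ncol(df) < 2) bcStop("matrix file %s needs sample_id plus >=1 column", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    bcStop("duplicated sample id(s) in %s: %s", path,
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  t(m)
}

writeSampleMatrix <- function(mat, path) {
  df <- data.frame(sample_id = colnames(mat), t(mat),
                   check.names = FALSE, stringsAsFactors = FALSE)
  writeTsv(df, path)
}

#' Read a methylation beta-value matrix
#'
#' Reads a samples x CpGs table of beta values (fraction methylated, in
#' \[0, 1\]). If a matching detection p-value matrix is supplied, cells whose
#' detection p exceeds \code{detectionPMax} are set to missing, mirroring the
#' standard array QC rule that unreliable signals are excluded.
#'
#' @param path TSV path; first column \code{sample_id}, remaining columns one
#'   CpG each.
#' @param detectionPPath optional TSV of identical layout with detection
#'   p-values.
#' @param detectionPMax detection p-value above which a cell is masked
#'   (default 0.01).
#' @return A [MethylationExperiment-class].
#' @export
readBetaMatrix <- function(path, detectionPPath = NULL, detectionPMax = 0.01) {
  b <- readSampleMatrix(path)
  bad <- which(!is.na(b) & (b < 0 | b > 1), arr.ind = TRUE)
  if (nrow(bad))
    bcStop("beta value outside [0,1]: sample '%s', CpG '%s' (value %g)",
           colnames(b)[bad[1, 2]], rownames(b)[bad[1, 1]],
           b[bad[1, 1], bad[1, 2]])
  if (!is.null(detectionPPath)) {
    p <- readSampleMatrix(detectionPPath)
    if (!identical(dim(p), dim(b)) ||
        !identical(dimnames(p), dimnames(b)))
      bcStop("detection-p matrix does not match beta matrix dimensions/names")
    masked <- !is.na(p) & p > detectionPMax
    b[masked] <- NA_real_
    bcLog("detection-p mask: %d cell(s) set missing", sum(masked))
  }
  MethylationExperiment(b)
}

#' @rdname readBetaMatrix
#' @param x a [MethylationExperiment-class]
#' @export
writeBetaMatrix <- function(x, path) writeSampleMatrix(betaValues(x), path)

#' Read cohort case/control labels
#'
#' @param path TSV with columns \code{sample_id}, \code{status} (\code{case}
#'   or \code{control}) and optional \code{time_to_diagnosis_years}
#'   (nonnegative; cases only).
#' @return data.frame with those columns, validated.
#' @export
readLabels <- function(path) {
  df <- readTsv(path)
  asCohortLabels(df)
}

#' Validate a cohort-labels data frame
#'
#' @param df data.frame with \code{sample_id}, \code{status} and optionally
#'   \code{time_to_diagnosis_years}.
#' @return the validated data.frame (ids as character, status as character).
#' @export
asCohortLabels <- function(df) {
  need <- c("sample_id", "status")
  miss <- setdiff(need, names(df))
  if (length(miss)) bcStop("labels: missing column(s) %s",
                           paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$status <- as.character(df$status)
  if (anyDuplicated(df$sample_id))
    bcStop("labels: duplicated sample id(s): %s",
           paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!all(df$status %in% c("case", "control")))
    bcStop("labels: status must be 'case' or 'control'")
  if (!"time_to_diagnosis_years" %in% names(df))
    df$time_to_diagnosis_years <- NA_real_
  df$time_to_diagnosis_years <- as.numeric(df$time_to_diagnosis_years)
  t <- df$time_to_diagnosis_years
  if (any(!is.na(t) & t < 0))
    bcStop("labels: negative time_to_diagnosis_years")
  if (any(!is.na(t) & df$status == "control"))
    bcStop("labels: controls must not carry a time_to_diagnosis")
  df[, c("sample_id", "status", "time_to_diagnosis_years")]
}

#' @rdname readLabels
#' @param labels validated labels data.frame
#' @export
writeLabels <- function(labels, path) writeTsv(asCohortLabels(labels), path)

#' Read a CpG panel
#'
#' A CpG panel lists previously reported disease-associated CpGs together
#' with the direction of the reported association: \code{hyper} (methylation
#' higher in cases) or \code{hypo} (lower in cases). Panels drive the
#' quartile-counting methylation risk score.
#'
#' @param path TSV with columns \code{cpg_id}, \code{direction}
#'   (\code{hyper}/\code{hypo}) and optional \code{set_label}.
#' @return validated data.frame; extra columns are preserved.
#' @export
readCpgPanel <- function(path) asCpgPanel(readTsv(path))

#' @rdname readCpgPanel
#' @param df data.frame to validate as a panel
#' @export
asCpgPanel <- function(df) {
  miss <- setdiff(c("cpg_id", "direction"), names(df))
  if (length(miss)) bcStop("panel: missing column(s) %s",
                           paste(miss, collapse = ", "))
  df$cpg_id <- as.character(df$cpg_id)
  df$direction <- as.character(df$direction)
  if (!"set_label" %in% names(df)) df$set_label <- "panel"
  if (anyDuplicated(df[, c("cpg_id", "set_label")]))
    bcStop("panel: duplicated cpg id(s) within a set")
  if (!all(df$direction %in% c("hyper", "hypo")))
    bcStop("panel: direction must be 'hyper' or 'hypo', got: %s",
           paste(setdiff(unique(df$direction), c("hyper", "hypo")),
                 collapse = ", "))
  df
}

#' @rdname readCpgPanel
#' @param panel validated panel data.frame
#' @export
writeCpgPanel <- function(panel, path) writeTsv(panel, path)

#' Read a SNP weight table
#'
#' Per-allele log odds ratios taken from a published genome-wide association
#' study, one row per SNP, defining the genetic risk score linear form.
#'
#' @param path TSV with columns \code{snp_id}, \code{beta} and optional
#'   \code{chrom}, \code{pos}, \code{effect_allele}, \code{other_allele}.
#' @return validated data.frame; extra columns preserved.
#' @export
readWeightTable <- function(path) asWeightTable(readTsv(path))

#' @rdname readWeightTable
#' @param df data.frame to validate
#' @export
asWeightTable <- function(df) {
  miss <- setdiff(c("snp_id", "beta"), names(df))
  if (length(miss)) bcStop("weights: missing column(s) %s",
                           paste(miss, collapse = ", "))
  df$snp_id <- as.character(df$snp_id)
  if (anyDuplicated(df$snp_id))
    bcStop("weights: duplicated snp id(s): %s",
           paste(unique(df$snp_id[duplicated(df$snp_id)]), collapse = ", "))
  df$beta <- as.numeric(df$beta)
  if (any(!is.finite(df$beta))) bcStop("weights: non-finite beta")
  for (col in c("chrom", "effect_allele", "other_allele"))
    if (col %in% names(df)) df[[col]] <- as.character(df[[col]])
  if ("pos" %in% names(df)) df$pos <- as.integer(df$pos)
  df
}

#' @rdname readWeightTable
#' @param weights validated weight table
#' @export
writeWeightTable <- function(weights, path) writeTsv(weights, path)

#' Read an environmental covariate table
#'
#' @param path TSV with \code{sample_id} plus one column per variable.
#'   Numeric columns are read as numeric; other columns stay character.
#' @return data.frame with character sample_id, missing cells as NA.
#' @export
readCovariates <- function(path) {
  df <- readTsv(path)
  if (!"sample_id" %in% names(df)) bcStop("covariates: missing sample_id")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) bcStop("covariates: duplicated sample ids")
  df
}

#' @rdname readCovariates
#' @param covariates covariate data.frame
#' @export
writeCovariates <- function(covariates, path) writeTsv(covariates, path)

#' Read a dosage matrix from TSV or VCF
#'
#' Dosages are expected counts of the effect allele per individual, in
#' \[0, 2\] (fractional after imputation). When a weight table with allele
#' columns is supplied, each SNP's orientation is resolved against it: if the
#' stated effect allele is the file's other allele the dosage is flipped
#' \code{d -> 2 - d}; if the allele pair matches neither orientation the SNP
#' is dropped with a warning. Multi-allelic VCF records are rejected.
#'
#' @param path TSV (samples x SNPs, first column \code{sample_id}) or VCF
#'   (detected by a \code{.vcf}/\code{.vcf.gz} extension).
#' @param weights optional weight table (see [readWeightTable()]) used for
#'   allele orientation and, for TSV input, SNP annotation.
#' @param snpInfo optional data.frame (\code{snp_id}, \code{chrom},
#'   \code{pos}, \code{effect_allele}, \code{other_allele}) annotating TSV
#'   input; ignored for VCF.
#' @return A [GenotypeExperiment-class] with dosages oriented to the weight
#'   table's effect alleles where resolvable.
#' @export
readDosageMatrix <- function(path, weights = NULL, snpInfo = NULL) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
    return(readDosageVcf(path, weights))
  d <- readSampleMatrix(path)
  bad <- which(!is.na(d) & (d < 0 | d > 2), arr.ind = TRUE)
  if (nrow(bad))
    bcStop("dosage outside [0,2]: sample '%s', SNP '%s' (value %g)",
           colnames(d)[bad[1, 2]], rownames(d)[bad[1, 1]],
           d[bad[1, 1], bad[1, 2]])
  ann <- snpInfo %||% weights
  chrom <- pos <- ea <- oa <- rep(NA, nrow(d))
  if (!is.null(ann)) {
    idx <- match(rownames(d), ann$snp_id)
    pick <- function(col) if (col %in% names(ann)) ann[[col]][idx] else rep(NA, nrow(d))
    chrom <- pick("chrom"); pos <- pick("pos")
    ea <- pick("effect_allele"); oa <- pick("other_allele")
  }
  ge <- GenotypeExperiment(d, chrom = chrom, pos = pos,
                           effectAllele = ea, otherAllele = oa)
  orientToWeights(ge, weights)
}

# flip/drop SNPs so dosages count the weight table's effect allele
orientToWeights <- function(ge, weights) {
  if (is.null(weights) ||
      !all(c("effect_allele", "other_allele") %in% names(weights)))
    return(ge)
  info <- snpInfo(ge)
  idx <- match(info$snp_id, weights$snp_id)
  keep <- rep(TRUE, nrow(info))
  d <- dosages(ge)
  for (i in seq_len(nrow(info))) {
    if (is.na(idx[i]) || is.na(info$effect_allele[i])) next
    wEa <- weights$effect_allele[idx[i]]; wOa <- weights$other_allele[idx[i]]
    gEa <- info$effect_allele[i]; gOa <- info$other_allele[i]
    if (identical(gEa, wEa) && identical(gOa, wOa)) {
      # already oriented
    } else if (identical(gEa, wOa) && identical(gOa, wEa)) {
      d[i, ] <- 2 - d[i, ]
      info$effect_allele[i] <- wEa
      info$other_allele[i] <- wOa
    } else {
      keep[i] <- FALSE
    }
  }
  if (any(!keep)) {
    warning(sprintf("dropping %d SNP(s) whose alleles match neither orientation of the weight table: %s",
                    sum(!keep), paste(info$snp_id[!keep], collapse = ", ")))
    bcLog("allele orientation: %d SNP(s) in, %d retained", nrow(info), sum(keep))
  }
  GenotypeExperiment(d[keep, , drop = FALSE],
                     chrom = info$chrom[keep], pos = info$pos[keep],
                     effectAllele = info$effect_allele[keep],
                     otherAllele = info$other_allele[keep])
}

# VCF 4.2 reader: prefers a per-sample DS field, falls back to counting ALT
# alleles from GT; half-calls are treated as missing.
readDosageVcf <- function(path, weights = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(vcf)),
                dimnames = list(NULL, colnames(vcfR::getFIX(vcf))))
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt)))
    bcStop("multi-allelic VCF record(s) not supported: %s",
           paste(fix[grepl(",", alt), "ID"], collapse = ", "))
  ids <- fix[, "ID"]
  noId <- is.na(ids) | ids == "."
  ids[noId] <- paste0(fix[noId, "CHROM"], ":", fix[noId, "POS"])
  fmt <- vcf@gt[, 1]
  hasDS <- all(grepl("(^|:)DS(:|$)", fmt))
  if (hasDS) {
    d <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    countAlt <- function(g) {
      if (is.na(g)) return(NA_real_)
      a <- strsplit(g, "[/|]")[[1]]
      if (any(a == "." | a == "")) return(NA_real_)  # half/no-calls missing
      sum(a != "0")
    }
    d <- apply(gt, c(1, 2), countAlt)
  }
  rownames(d) <- ids
  bad <- which(!is.na(d) & (d < 0 | d > 2), arr.ind = TRUE)
  if (nrow(bad))
    bcStop("VCF dosage outside [0,2] at SNP '%s', sample '%s'",
           rownames(d)[bad[1, 1]], colnames(d)[bad[1, 2]])
  ge <- GenotypeExperiment(d, chrom = fix[, "CHROM"],
                           pos = as.integer(fix[, "POS"]),
                           effectAllele = alt, otherAllele = fix[, "REF"])
  orientToWeights(ge, weights)
}

#' @rdname readDosageMatrix
#' @param x a [GenotypeExperiment-class]
#' @export
writeDosageMatrix <- function(x, path) writeSampleMatrix(dosages(x), path)

#' Run configuration
#'
#' Bundles the master seed, quantile convention, cross-validation layout and
#' every filter threshold used by the pipeline, so that a run is fully
#' described by one YAML document.
#'
#' @param seed master integer seed for all substreams.
#' @param quantile_rule quantile type passed to [stats::quantile()]
#'   (default 7, linear interpolation between order statistics).
#' @param cv_folds,cv_repetitions cross-validation layout.
#' @param probe_max_missing,snp_max_missing maximum missing fraction per
#'   CpG probe / SNP.
#' @param maf_min minimum minor allele frequency.
#' @param ld_r2_max,ld_dprime_min LD-pruning thresholds (pairs with BOTH
#'   D' >= \code{ld_dprime_min} AND r^2 > \code{ld_r2_max} are pruned).
#' @param detection_p_max detection p-value mask threshold.
#' @param surrogate list of surrogate-search criteria: \code{r2_min},
#'   \code{dprime_min}, \code{maf_min}, \code{max_distance_bp},
#'   \code{max_missing}.
#' @param paths named list of input-file paths (opaque).
#' @return list of class \code{"RunConfig"}.
#' @export
runConfig <- function(seed = 1L, quantile_rule = 7L, cv_folds = 10L,
                      cv_repetitions = 1000L, probe_max_missing = 0.10,
                      snp_max_missing = 0.10, maf_min = 0.01,
                      ld_r2_max = 0.8, ld_dprime_min = 0.95,
                      detection_p_max = 0.01,
                      surrogate = list(r2_min = 0.8, dprime_min = 0.95,
                                       maf_min = 0.01,
                                       max_distance_bp = 250000L,
                                       max_missing = 0.10),
                      paths = list()) {
  cfg <- list(seed = as.integer(seed), quantile_rule = as.integer(quantile_rule),
              cv_folds = as.integer(cv_folds),
              cv_repetitions = as.integer(cv_repetitions),
              probe_max_missing = probe_max_missing,
              snp_max_missing = snp_max_missing, maf_min = maf_min,
              ld_r2_max = ld_r2_max, ld_dprime_min = ld_dprime_min,
              detection_p_max = detection_p_max, surrogate = surrogate,
              paths = paths)
  validateRunConfig(cfg)
}

validateRunConfig <- function(cfg) {
  if (cfg$cv_folds < 2) bcStop("cv_folds must be >= 2")
  if (cfg$cv_repetitions < 1) bcStop("cv_repetitions must be >= 1")
  for (f in c("probe_max_missing", "snp_max_missing", "maf_min",
              "ld_r2_max", "detection_p_max"))
    checkFraction(cfg[[f]], f)
  checkFraction(cfg$ld_dprime_min, "ld_dprime_min")
  class(cfg) <- "RunConfig"
  cfg
}

#' @rdname runConfig
#' @param path YAML path
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname runConfig
#' @param cfg a RunConfig (for write) / ignored (for read)
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(runConfig, raw[setdiff(names(raw), character(0))])
  cfg
}

#' Write a ScoreSet to TSV
#'
#' @param x a [ScoreSet-class]
#' @param path output TSV (columns sample_id, score, n_features_used).
#' @export
writeScoreSet <- function(x, path) {
  writeTsv(data.frame(sample_id = x@sampleId, score = x@value,
                      n_features_used = x@nFeaturesUsed,
                      stringsAsFactors = FALSE), path)
}

#' Read a ScoreSet written by [writeScoreSet()]
#' @param path TSV path
#' @param scoreKind kind tag to attach ("mrs", "grs", "ers", "combined").
#' @return A [ScoreSet-class].
#' @export
readScoreSet <- function(path, scoreKind = "combined") {
  df <- readTsv(path)
  ScoreSet(df$sample_id, df$score, scoreKind,
           df$n_features_used %||% rep(NA_integer_, nrow(df)))
}
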