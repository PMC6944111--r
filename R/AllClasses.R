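#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' MethylationExperiment: beta values for a nested case-control sample
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding a
#' single \code{"beta"} assay (CpGs in rows, samples in columns). Beta values
#' are methylation fractions in \[0, 1\]; missing measurements (failed
#' detection, masked cells) are stored as \code{NA}.
#'
#' @slot .Data see \code{SummarizedExperiment}
#' @export
setClass("MethylationExperiment", contains = "SummarizedExperiment")

setValidity("MethylationExperiment", function(object) {
  if (!"beta" %in% names(assays(object)))
    return("assay 'beta' is required")
  b <- assay(object, "beta")
  bad <- which(!is.na(b) & (b < 0 | b > 1))
  if (length(bad))
    return(sprintf("beta values outside [0,1] at %d cell(s)", length(bad)))
  if (anyDuplicated(colnames(object)))
    return("duplicated sample ids")
  if (anyDuplicated(rownames(object)))
    return("duplicated CpG ids")
  TRUE
})

#' Construct a MethylationExperiment
#'
#' @param beta numeric matrix of beta values, CpGs x samples, with dimnames.
#'   \code{NA} marks missing cells.
#' @return A [MethylationExperiment-class] object.
#' @examples
#' b <- matrix(runif(6), 2, 3,
#'             dimnames = list(c("cg01", "cg02"), paste0("s", 1:3)))
#' MethylationExperiment(b)
#' @export
MethylationExperiment <- function(beta) {
  beta <- as.matrix(beta)
  storage.mode(beta) <- "double"
  se <- SummarizedExperiment(assays = list(beta = beta))
  new("MethylationExperiment", se)
}

#' GenotypeExperiment: effect-allele dosages with SNP annotation
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one \code{"dosage"}
#' assay (SNPs in rows, samples in columns; values in \[0, 2\], fractional
#' after imputation, \code{NA} = missing) and per-SNP \code{rowData} columns
#' \code{chrom}, \code{pos}, \code{effect_allele}, \code{other_allele}.
#'
#' @export
setClass("GenotypeExperiment", contains = "SummarizedExperiment")

setValidity("GenotypeExperiment", function(object) {
  if (!"dosage" %in% names(assays(object)))
    return("assay 'dosage' is required")
  d <- assay(object, "dosage")
  bad <- which(!is.na(d) & (d < 0 | d > 2))
  if (length(bad))
    return(sprintf("dosages outside [0,2] at %d cell(s)", length(bad)))
  rd <- rowData(object)
  need <- c("chrom", "pos", "effect_allele", "other_allele")
  miss <- setdiff(need, colnames(rd))
  if (length(miss))
    return(paste("missing rowData column(s):", paste(miss, collapse = ", ")))
  if (any(!is.na(rd$pos) & rd$pos < 0))
    return("negative SNP positions")
  if (anyDuplicated(rownames(object)))
    return("duplicated SNP ids")
  if (anyDuplicated(colnames(object)))
    return("duplicated sample ids")
  TRUE
})

#' Construct a GenotypeExperiment
#'
#' @param dosage numeric matrix, SNPs x samples, values in \[0, 2\].
#' @param chrom,pos,effectAllele,otherAllele per-SNP annotation vectors
#'   (recycled NA when unknown).
#' @return A [GenotypeExperiment-class] object.
#' @export
GenotypeExperiment <- function(dosage, chrom = NA, pos = NA,
                               effectAllele = NA, otherAllele = NA) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  n <- nrow(dosage)
  rd <- DataFrame(
    chrom = rep_len(as.character(chrom), n),
    pos = rep_len(as.integer(pos), n),
    effect_allele = rep_len(as.character(effectAllele), n),
    other_allele = rep_len(as.character(otherAllele), n),
    row.names = rownames(dosage)
  )
  se <- SummarizedExperiment(assays = list(dosage = dosage), rowData = rd)
  new("GenotypeExperiment", se)
}

#' ScoreSet: per-sample values of one risk score
#'
#' Holds one risk score per sample together with the number of features that
#' actually contributed (non-missing panel CpGs, non-substituted SNPs) and a
#' provenance list recording how the score was built.
#'
#' @slot sampleId character vector of sample ids.
#' @slot value numeric score per sample.
#' @slot scoreKind one of \code{"mrs"}, \code{"grs"}, \code{"ers"},
#'   \code{"combined"}.
#' @slot nFeaturesUsed integer, features contributing per sample.
#' @slot provenance named list of free-form metadata.
#' @export
setClass("ScoreSet",
  representation(sampleId = "character", value = "numeric",
                 scoreKind = "character", nFeaturesUsed = "integer",
                 provenance = "list"))

setValidity("ScoreSet", function(object) {
  n <- length(object@sampleId)
  if (length(object@value) != n)
    return("value and sampleId lengths differ")
  if (length(object@nFeaturesUsed) != n)
    return("nFeaturesUsed and sampleId lengths differ")
  if (anyDuplicated(object@sampleId))
    return("duplicated sample ids")
  if (!object@scoreKind %in% c("mrs", "grs", "ers", "combined"))
    return("scoreKind must be one of mrs, grs, ers, combined")
  TRUE
})

#' Construct a ScoreSet
#'
#' @param sampleId character sample ids.
#' @param value numeric score values, one per sample.
#' @param scoreKind \code{"mrs"}, \code{"grs"}, \code{"ers"} or
#'   \code{"combined"}.
#' @param nFeaturesUsed integer vector, number of features contributing to
#'   each sample's value (defaults to \code{NA}).
#' @param provenance named list of metadata carried along with the score.
#' @return A [ScoreSet-class].
#' @export
ScoreSet <- function(sampleId, value, scoreKind,
                     nFeaturesUsed = rep(NA_integer_, length(sampleId)),
                     provenance = list()) {
  new("ScoreSet", sampleId = as.character(sampleId),
      value = as.numeric(value), scoreKind = scoreKind,
      nFeaturesUsed = as.integer(nFeaturesUsed), provenance = provenance)
}

setMethod("show", "ScoreSet", function(object) {
  cat(sprintf("ScoreSet of kind '%s' with %d samples\n",
              object@scoreKind, length(object@sampleId)))
  v <- object@value
  cat(sprintf("  value: min %.4g, median %.4g, max %.4g\n",
              min(v), stats::median(v), max(v)))
  if (length(object@provenance))
    cat("  provenance:", paste(names(object@provenance), collapse = ", "), "\n")
})

#' @describeIn ScoreSet score values, named by sample id
#' @param x,object a \code{ScoreSet}
#' @export
scoreValues <- function(x) stats::setNames(x@value, x@sampleId)

#' @describeIn ScoreSet kind of score ("mrs", "grs", "ers", "combined")
#' @export
scoreKind <- function(x) x@scoreKind

#' @describeIn ScoreSet per-sample count of contributing features
#' @export
nFeaturesUsed <- function(x) stats::setNames(x@nFeaturesUsed, x@sampleId)

#' @describeIn ScoreSet provenance metadata list
#' @export
scoreProvenance <- function(x) x@provenance

#' Sample identifiers of a bcrisk object
#'
#' @param x a MethylationExperiment, GenotypeExperiment, ScoreSet or
#'   cohort-labels data frame.
#' @return character vector of sample ids in storage order.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "SummarizedExperiment", function(x) colnames(x))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "ScoreSet", function(x) x@sampleId)

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "data.frame", function(x) as.character(x$sample_id))

#' Beta-value matrix of a MethylationExperiment
#' @param x a [MethylationExperiment-class]
#' @return numeric matrix (CpGs x samples), NA = missing.
#' @export
betaValues <- function(x) assay(x, "beta")

#' Dosage matrix of a GenotypeExperiment
#' @param x a [GenotypeExperiment-class]
#' @return numeric matrix (SNPs x samples), NA = missing.
#' @export
dosages <- function(x) assay(x, "dosage")

#' Per-SNP annotation of a GenotypeExperiment
#' @param x a [GenotypeExperiment-class]
#' @return data.frame with snp_id, chrom, pos, effect_allele, other_allele.
#' @export
snpInfo <- function(x) {
  rd <- as.data.frame(rowData(x))
  data.frame(snp_id = rownames(x), rd, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Restrict and reorder samples to a reference ordering
#'
#' All pipeline inputs are re-indexed to the sample order of the cohort
#' labels, giving one canonical ordering and removing join ambiguity.
#'
#' @param x a MethylationExperiment, GenotypeExperiment or ScoreSet.
#' @param sampleId character vector of sample ids (e.g.
#'   \code{labels$sample_id}); every id must be present in \code{x}.
#' @return object of the same class with columns/entries reordered.
#' @export
reindexSamples <- function(x, sampleId) {
  sampleId <- as.character(sampleId)
  missing <- setdiff(sampleId, sampleIds(x))
  if (length(missing))
    stop("sample id(s) absent from object: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (is(x, "ScoreSet")) {
    idx <- match(sampleId, x@sampleId)
    return(ScoreSet(sampleId, x@value[idx], x@scoreKind,
                    x@nFeaturesUsed[idx], x@provenance))
  }
  x[, sampleId]
}
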