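#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Matrix dgCMatrix
NULL

#' AnnotationTrack: a named set of genomic intervals
#'
#' Holds one annotation track (exons, TSS, enhancers, TFBS peaks, open
#' chromatin, histone marks, ...) as a [GenomicRanges::GRanges] indexed for
#' overlap queries. Strand is stored but ignored by overlap; element overlap
#' with variants is strand-agnostic.
#'
#' @slot name single track identifier, e.g. `"enhancer"`.
#' @slot ranges intervals as a `GRanges` (1-based, closed).
#' @exportClass AnnotationTrack
setClass("AnnotationTrack",
  slots = c(name = "character", ranges = "GRanges"))

setValidity("AnnotationTrack", function(object) {
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    return("'name' must be a single non-empty string")
  if (length(object@ranges) && any(GenomicRanges::width(object@ranges) < 1L))
    return("all intervals must have width >= 1")
  TRUE
})

#' ConservationTrack: per-position conservation scores
#'
#' Sparse lookup of a conservation score (phastCons- or phyloP-style) keyed by
#' (chromosome, 1-based position). A position absent from the track is
#' *missing*, never 0; a stored score of 0 is a real value.
#'
#' @slot name score name, e.g. `"phastcons46"`.
#' @slot chrom,pos,score parallel vectors defining the score map.
#' @exportClass ConservationTrack
setClass("ConservationTrack",
  slots = c(name = "character", chrom = "character",
            pos = "integer", score = "numeric"))

setValidity("ConservationTrack", function(object) {
  n <- length(object@pos)
  if (length(object@name) != 1L) return("'name' must be a single string")
  if (length(object@chrom) != n || length(object@score) != n)
    return("chrom, pos and score must have equal length")
  if (n && any(!is.finite(object@score))) return("scores must be finite")
  if (anyDuplicated(paste0(object@chrom, ":", object@pos)))
    return("duplicate (chrom, pos) entries")
  TRUE
})

#' PopulationFrequencyTable: subpopulation allele frequencies and sample sizes
#'
#' One row per locus; for each of `s >= 2` subpopulations it stores the
#' observed alternate-allele frequency `p_i` in `[0, 1]` and the per-population
#' sample size `n_i` (number of sampled allele copies, i.e. haploid counts).
#' These feed the unbiased F_ST estimator, the dispersion score, the
#' differentiation categories and the population-preference calls.
#'
#' @slot populations ordered labels of the `s` subpopulations.
#' @slot p numeric matrix, loci x populations, frequencies in `[0, 1]`.
#' @slot n integer vector of per-population sample sizes (allele copies).
#' @slot chrom,pos optional per-locus coordinates (length 0 or nrow(p)).
#' @exportClass PopulationFrequencyTable
setClass("PopulationFrequencyTable",
  slots = c(populations = "character", p = "matrix", n = "integer",
            chrom = "character", pos = "integer"))

setValidity("PopulationFrequencyTable", function(object) {
  s <- length(object@populations)
  if (s < 2L) return("at least two populations are required")
  if (ncol(object@p) != s) return("ncol(p) must equal number of populations")
  if (length(object@n) != s) return("length(n) must equal number of populations")
  if (any(object@n < 1L)) return("all sample sizes must be >= 1")
  if (nrow(object@p) && (min(object@p) < 0 || max(object@p) > 1))
    return("all frequencies must lie in [0, 1]")
  nl <- nrow(object@p)
  if (length(object@chrom) && length(object@chrom) != nl)
    return("chrom must have length 0 or nrow(p)")
  if (length(object@pos) && length(object@pos) != nl)
    return("pos must have length 0 or nrow(p)")
  TRUE
})

#' FeatureRegistry: stable feature-name to index mapping
#'
#' Features get fixed, unique, contiguous 1-based indices on first
#' registration and are never reassigned, so that sparse matrices and trained
#' models remain aligned across a run. Each feature carries a group tag:
#' `"population"`, `"conservation"` or `"annotation"`.
#'
#' Backed by an environment: registration mutates the registry in place,
#' mirroring how the index must stay shared between feature sources.
#'
#' @slot env environment holding `index` (named integer) and `group`
#'   (named character).
#' @exportClass FeatureRegistry
setClass("FeatureRegistry", slots = c(env = "environment"))

#' FeatureMatrix: sparse variant-by-feature matrix
#'
#' Rows follow variant input order, columns follow registry indices. A stored
#' entry is an observed value; an absent entry means *missing* (no overlap /
#' not in the resource), which the sparse decision function treats as
#' contributing 0 to the dot product.
#'
#' @slot matrix `dgCMatrix`, variants x features.
#' @slot featureNames,featureGroups column metadata in registry order.
#' @slot variantKeys `chrom:pos:ref:alt` keys in row order.
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  slots = c(matrix = "dgCMatrix", featureNames = "character",
            featureGroups = "character", variantKeys = "character"))

setValidity("FeatureMatrix", function(object) {
  if (ncol(object@matrix) != length(object@featureNames))
    return("featureNames must match matrix columns")
  if (length(object@featureGroups) != length(object@featureNames))
    return("featureGroups must match featureNames")
  if (nrow(object@matrix) != length(object@variantKeys))
    return("variantKeys must match matrix rows")
  if (length(object@matrix@x) && any(!is.finite(object@matrix@x)))
    return("stored feature values must be finite")
  TRUE
})

#' SparseLogisticModel: trained L1-regularized logistic regression
#'
#' The decision value of a row x is `intercept + sum_i w_i x_i` over stored
#' entries (absent features contribute 0); the probability score is the
#' logistic sigmoid of the decision value, in (0, 1).
#'
#' @slot weights numeric weight vector, one per registry feature.
#' @slot intercept scalar intercept.
#' @slot featureNames feature names the model was fit against (the registry
#'   fingerprint used to reject mismatched matrices at scoring time).
#' @slot cost regularization strength C (larger C = weaker penalty).
#' @slot tol convergence tolerance passed to the solver.
#' @exportClass SparseLogisticModel
setClass("SparseLogisticModel",
  slots = c(weights = "numeric", intercept = "numeric",
            featureNames = "character", cost = "numeric", tol = "numeric"))

setValidity("SparseLogisticModel", function(object) {
  if (length(object@weights) != length(object@featureNames))
    return("weights must match featureNames")
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    return("intercept must be a finite scalar")
  if (object@cost <= 0) return("C must be > 0")
  TRUE
})

#' GeneElementMap: gene-wise annotated elements
#'
#' Each element is an interval tagged with its gene symbol and element type
#' (exon, tss, utr3, utr5, enhancer, tfbs_peakseq, tfbs_spp, open_chromatin).
#' Elements are deduplicated by (gene, type, interval) at construction so a
#' region annotated through several transcripts is counted once.
#'
#' @slot elements `GRanges` with metadata columns `gene` and `type`.
#' @exportClass GeneElementMap
setClass("GeneElementMap", slots = c(elements = "GRanges"))

setValidity("GeneElementMap", function(object) {
  mc <- S4Vectors::mcols(object@elements)
  if (!all(c("gene", "type") %in% colnames(mc)))
    return("elements must carry 'gene' and 'type' metadata columns")
  if (length(object@elements)) {
    if (any(is.na(mc$gene)) || any(!nzchar(mc$gene)))
      return("gene symbols must be non-empty")
    if (any(is.na(mc$type)) || any(!nzchar(mc$type)))
      return("element types must be non-empty")
  }
  TRUE
})

#' WeightScheme: per-element-type weights for the gene score
#'
#' Maps element types to the weight W_T in (0, 1] used by the gene-centric
#' disease score. Defaults follow the platform convention: exon and TSS 1.0,
#' 3'-UTR and 5'-UTR 0.5, enhancer 0.3, TFBS (PeakSeq and SPP) 0.2, open
#' chromatin 0.1. The type set can be extended by supplying an explicit
#' weight for a new type.
#'
#' @slot weights named numeric vector, values in (0, 1].
#' @exportClass WeightScheme
setClass("WeightScheme", slots = c(weights = "numeric"))

setValidity("WeightScheme", function(object) {
  w <- object@weights
  if (is.null(names(w)) || any(!nzchar(names(w)))) return("weights must be named")
  if (anyDuplicated(names(w))) return("duplicate element types")
  if (any(!is.finite(w)) || any(w <= 0) || any(w > 1))
    return("all weights must lie in (0, 1]")
  TRUE
})

#' PathwayDB: named gene sets for enrichment analysis
#'
#' @slot pathways named list of character vectors of gene symbols.
#' @slot source free-text provenance tag.
#' @exportClass PathwayDB
setClass("PathwayDB", slots = c(pathways = "list", source = "character"))

setValidity("PathwayDB", function(object) {
  pw <- object@pathways
  if (length(pw)) {
    if (is.null(names(pw)) || any(!nzchar(names(pw))))
      return("pathways must be named")
    if (anyDuplicated(names(pw))) return("duplicate pathway names")
    if (any(vapply(pw, length, 1L) == 0L)) return("empty pathway")
    ok <- vapply(pw, function(g) is.character(g) && all(nzchar(g)), TRUE)
    if (!all(ok)) return("gene symbols must be non-empty strings")
  }
  TRUE
})
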