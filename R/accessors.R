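# Constructors, accessors and show() methods for the core classes.

#' Build an AnnotationTrack
#'
#' @param name track identifier.
#' @param ranges a `GRanges` of intervals (1-based, closed). Seqnames are
#'   normalized by stripping a leading `"chr"`.
#' @return an [AnnotationTrack-class] object.
#' @export
AnnotationTrack <- function(name, ranges) {
  ranges <- normalizeSeqnames(ranges)
  new("AnnotationTrack", name = name, ranges = ranges)
}

#' @describeIn AnnotationTrack track identifier.
#' @param x an `AnnotationTrack`.
#' @export
trackName <- function(x) x@name

#' @describeIn AnnotationTrack interval set as a `GRanges`.
#' @export
trackRanges <- function(x) x@ranges

setMethod("show", "AnnotationTrack", function(object) {
  cat("AnnotationTrack \"", object@name, "\": ", length(object@ranges),
      " intervals\n", sep = "")
})

#' Build a ConservationTrack
#'
#' @param name score name (e.g. `"phastcons46"`).
#' @param chrom,pos,score parallel vectors: chromosome, 1-based position,
#'   score value. Chromosome names are normalized (leading `"chr"` stripped).
#' @return a [ConservationTrack-class] object.
#' @export
ConservationTrack <- function(name, chrom, pos, score) {
  new("ConservationTrack", name = name, chrom = normChrom(as.character(chrom)),
      pos = as.integer(pos), score = as.numeric(score))
}

#' Look up conservation scores at variant positions
#'
#' @param track a `ConservationTrack`.
#' @param chrom,pos vectors of chromosome and 1-based position.
#' @return numeric vector of scores; `NA` where the position is absent from
#'   the track (missing, which is distinct from a stored 0).
#' @export
conservationAt <- function(track, chrom, pos) {
  idx <- match(paste0(normChrom(as.character(chrom)), ":", as.integer(pos)),
               paste0(track@chrom, ":", track@pos))
  track@score[idx]
}

setMethod("show", "ConservationTrack", function(object) {
  cat("ConservationTrack \"", object@name, "\": ", length(object@pos),
      " positions\n", sep = "")
})

#' Build a PopulationFrequencyTable
#'
#' @param p numeric matrix of observed alternate-allele frequencies,
#'   loci x populations.
#' @param n per-population sample sizes (allele copies).
#' @param populations population labels; defaults to `colnames(p)`.
#' @param chrom,pos optional per-locus coordinates.
#' @return a [PopulationFrequencyTable-class] object.
#' @export
PopulationFrequencyTable <- function(p, n, populations = colnames(p),
                                     chrom = character(), pos = integer()) {
  p <- as.matrix(p)
  if (is.null(populations))
    populations <- paste0("pop", seq_len(ncol(p)))
  colnames(p) <- populations
  new("PopulationFrequencyTable", populations = populations, p = p,
      n = as.integer(n), chrom = normChrom(as.character(chrom)),
      pos = as.integer(pos))
}

#' @describeIn PopulationFrequencyTable population labels.
#' @param x a `PopulationFrequencyTable`.
#' @export
populationLabels <- function(x) x@populations

#' @describeIn PopulationFrequencyTable frequency matrix (loci x populations).
#' @export
alleleFrequencies <- function(x) x@p

#' @describeIn PopulationFrequencyTable per-population sample sizes.
#' @export
sampleSizes <- function(x) x@n

#' @describeIn PopulationFrequencyTable number of loci.
#' @export
nLoci <- function(x) nrow(x@p)

#' @describeIn PopulationFrequencyTable per-locus `chrom:pos` keys (or `NULL`
#'   when the table carries no coordinates).
#' @export
lociKeys <- function(x) {
  if (!length(x@chrom)) return(NULL)
  paste0(x@chrom, ":", x@pos)
}

#' Subset a frequency table to selected loci
#'
#' @param x a `PopulationFrequencyTable`.
#' @param i row (locus) index.
#' @return a `PopulationFrequencyTable` with the selected loci.
#' @export
subsetLoci <- function(x, i) {
  PopulationFrequencyTable(x@p[i, , drop = FALSE], x@n, x@populations,
    chrom = if (length(x@chrom)) x@chrom[i] else character(),
    pos = if (length(x@pos)) x@pos[i] else integer())
}

setMethod("show", "PopulationFrequencyTable", function(object) {
  cat("PopulationFrequencyTable: ", nrow(object@p), " loci x ",
      length(object@populations), " populations (",
      paste(object@populations, collapse = ", "), ")\n", sep = "")
  cat("  sample sizes: ", paste(object@n, collapse = ", "),
      " allele copies\n", sep = "")
})

#' @describeIn FeatureMatrix the underlying sparse `dgCMatrix`
#'   (absent entries mean missing, which scores as 0).
#' @param x a `FeatureMatrix`.
#' @export
featureMatrix <- function(x) x@matrix

#' @describeIn FeatureMatrix feature names in column (registry) order.
#' @export
featureNames <- function(x) x@featureNames

#' @describeIn FeatureMatrix feature group tags in column order.
#' @export
featureGroups <- function(x) x@featureGroups

#' @describeIn FeatureMatrix `chrom:pos:ref:alt` row keys.
#' @export
matrixVariantKeys <- function(x) x@variantKeys

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix: ", nrow(object@matrix), " variants x ",
      ncol(object@matrix), " features; ",
      length(object@matrix@x), " stored values\n", sep = "")
  grp <- table(object@featureGroups)
  if (length(grp))
    cat("  groups: ", paste(names(grp), grp, sep = "=", collapse = ", "),
        "\n", sep = "")
})

#' @describeIn SparseLogisticModel weight vector (one entry per feature).
#' @param x a `SparseLogisticModel`.
#' @export
modelWeights <- function(x) x@weights

#' @describeIn SparseLogisticModel scalar intercept.
#' @export
modelIntercept <- function(x) x@intercept

setMethod("show", "SparseLogisticModel", function(object) {
  cat("SparseLogisticModel: ", sum(object@weights != 0), "/",
      length(object@weights), " nonzero weights, intercept ",
      signif(object@intercept, 4), ", C = ", object@cost, "\n", sep = "")
})

#' Build a GeneElementMap
#'
#' @param chrom,start,end element intervals (1-based, closed); `start`/`end`
#'   may also be supplied through `ranges`.
#' @param gene gene symbol per element.
#' @param type element type per element (exon, tss, utr3, utr5, enhancer,
#'   tfbs_peakseq, tfbs_spp, open_chromatin; extensible through the
#'   [WeightScheme()]).
#' @param ranges alternatively, a ready `GRanges` with `gene`/`type` columns.
#' @return a [GeneElementMap-class]; duplicated (gene, type, interval)
#'   entries, e.g. from multiple transcripts, are collapsed.
#' @export
GeneElementMap <- function(chrom = NULL, start = NULL, end = NULL,
                           gene = NULL, type = NULL, ranges = NULL) {
  if (is.null(ranges)) {
    ranges <- GenomicRanges::GRanges(
      normChrom(as.character(chrom)),
      IRanges::IRanges(as.integer(start), as.integer(end)),
      gene = as.character(gene), type = as.character(type))
  } else {
    ranges <- normalizeSeqnames(ranges)
  }
  key <- paste(as.character(GenomicRanges::seqnames(ranges)),
               GenomicRanges::start(ranges), GenomicRanges::end(ranges),
               S4Vectors::mcols(ranges)$gene, S4Vectors::mcols(ranges)$type)
  new("GeneElementMap", elements = ranges[!duplicated(key)])
}

#' @describeIn GeneElementMap elements as a `GRanges` with `gene` and `type`.
#' @param x a `GeneElementMap`.
#' @export
geneElements <- function(x) x@elements

setMethod("show", "GeneElementMap", function(object) {
  cat("GeneElementMap: ", length(object@elements), " elements, ",
      length(unique(S4Vectors::mcols(object@elements)$gene)), " genes\n",
      sep = "")
})

#' Build a WeightScheme
#'
#' @param weights named numeric vector of element-type weights in (0, 1];
#'   entries override or extend the defaults (exon/tss 1.0, utr3/utr5 0.5,
#'   enhancer 0.3, tfbs_peakseq/tfbs_spp 0.2, open_chromatin 0.1).
#' @return a [WeightScheme-class] object.
#' @export
WeightScheme <- function(weights = numeric()) {
  w <- defaultElementWeights()
  if (length(weights)) w[names(weights)] <- weights
  new("WeightScheme", weights = w)
}

defaultElementWeights <- function() {
  c(exon = 1.0, tss = 1.0, utr3 = 0.5, utr5 = 0.5, enhancer = 0.3,
    tfbs_peakseq = 0.2, tfbs_spp = 0.2, open_chromatin = 0.1)
}

#' @describeIn WeightScheme named weight vector.
#' @param x a `WeightScheme`.
#' @export
elementWeights <- function(x) x@weights

setMethod("show", "WeightScheme", function(object) {
  cat("WeightScheme:", paste(names(object@weights), object@weights,
      sep = "=", collapse = ", "), "\n")
})

#' Build a PathwayDB
#'
#' @param pathways named list of gene-symbol character vectors.
#' @param source provenance tag.
#' @return a [PathwayDB-class] object.
#' @export
PathwayDB <- function(pathways, source = "user") {
  new("PathwayDB", pathways = lapply(pathways, unique), source = source)
}

#' @describeIn PathwayDB named list of gene sets.
#' @param x a `PathwayDB`.
#' @export
pathwayList <- function(x) x@pathways

setMethod("show", "PathwayDB", function(object) {
  sz <- vapply(object@pathways, length, 1L)
  cat("PathwayDB (", object@source, "): ", length(sz), " pathways, ",
      if (length(sz)) paste0(min(sz), "-", max(sz)) else "0",
      " genes each\n", sep = "")
})
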