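# Gene-centric functional annotation: map variants to annotated elements and
# compute the weighted gene-disease score
#
#   score = sum_i S_i,   S_i = s_i * min(1, sum_j (L_o_ij / L_e_j) * W_T(j))
#
# over the m genes the variant touches, where s_i is the gene's occurrence
# count in the configured gene-disease tables, L_e_j the length of the gene's
# j-th element, L_o_ij the overlap between the variant footprint and that
# element, and W_T the per-element-type weight. The min(1, .) cap wraps the
# whole weighted sum, which keeps S_i <= s_i.

#' Map variants to annotated gene elements
#'
#' Exhaustive list of (gene, element) overlaps for each variant, with exact
#' overlap and element lengths; equals a brute-force linear scan. Elements
#' are already deduplicated by (gene, type, interval) on the map.
#'
#' @param v variant `GRanges`.
#' @param gmap a [GeneElementMap-class].
#' @return data.frame with one row per overlap: `variant` (row index),
#'   `key`, `gene`, `type`, `overlap_length`, `element_length`.
#' @export
mapVariantToElements <- function(v, gmap) {
  el <- gmap@elements
  hits <- .quiet_seqlevels(
    GenomicRanges::findOverlaps(v, el, ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- .quiet_seqlevels(GenomicRanges::width(GenomicRanges::pintersect(
    v[qi], el[si], ignore.strand = TRUE)))
  data.frame(variant = qi, key = variantKeys(v)[qi],
             gene = S4Vectors::mcols(el)$gene[si],
             type = S4Vectors::mcols(el)$type[si],
             overlap_length = ov,
             element_length = GenomicRanges::width(el)[si],
             stringsAsFactors = FALSE)
}

#' Gene-centric weighted disease score
#'
#' For each variant, computes the per-gene score
#' `S_i = s_i * min(1, sum_j (L_o_ij / L_e_j) * W_T)` over the gene's
#' overlapped elements and sums across genes. Genes absent from the count
#' table get `s_i = 0`; genes with no overlap contribute nothing. An element
#' type without a configured weight is an error.
#'
#' @param v variant `GRanges`.
#' @param gmap a [GeneElementMap-class].
#' @param weights a [WeightScheme-class]; default [WeightScheme()].
#' @param diseaseCounts named numeric vector of per-gene occurrence counts
#'   `s_i` (see [readDiseaseCounts()]).
#' @return data.frame with one row per variant: `key`, `score` (the total
#'   across genes), plus the per-gene breakdown as attribute `"genes"`
#'   (data.frame `variant`, `gene`, `s_i`, `weighted_overlap`, `S_i`).
#' @export
geneDiseaseScore <- function(v, gmap, weights = WeightScheme(),
                             diseaseCounts = numeric()) {
  hits <- mapVariantToElements(v, gmap)
  w <- weights@weights
  unknown <- setdiff(unique(hits$type), names(w))
  if (length(unknown))
    stop("unknown element type(s): ", paste(unknown, collapse = ", "),
         "; extend the WeightScheme to score them")
  total <- stats::setNames(numeric(length(v)), variantKeys(v))
  genes <- data.frame(variant = integer(), gene = character(),
                      s_i = numeric(), weighted_overlap = numeric(),
                      S_i = numeric(), stringsAsFactors = FALSE)
  if (nrow(hits)) {
    hits$contrib <- hits$overlap_length / hits$element_length * w[hits$type]
    agg <- stats::aggregate(contrib ~ variant + gene, data = hits, FUN = sum)
    s_i <- diseaseCounts[agg$gene]
    s_i[is.na(s_i)] <- 0
    agg$s_i <- as.numeric(s_i)
    agg$S_i <- agg$s_i * pmin(1, agg$contrib)
    pt <- tapply(agg$S_i, agg$variant, sum)
    total[as.integer(names(pt))] <- as.numeric(pt)
    genes <- data.frame(variant = agg$variant, gene = agg$gene,
                        s_i = agg$s_i, weighted_overlap = agg$contrib,
                        S_i = agg$S_i, stringsAsFactors = FALSE)
    genes <- genes[order(genes$variant, genes$gene), , drop = FALSE]
    rownames(genes) <- NULL
  }
  out <- data.frame(key = variantKeys(v), score = unname(total),
                    stringsAsFactors = FALSE)
  attr(out, "genes") <- genes
  out
}
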