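# Variant Set Enrichment Analysis: map test and background variant sets to
# the genes whose annotated elements they overlap, then test each pathway
# for over-representation of test genes with a one-sided Fisher's exact
# test, adjusting across pathways with Benjamini-Hochberg. Counting is at
# the gene level (a variant-level table would double-count genes hit by
# several variants).

#' Genes reached by a variant set
#'
#' Union of the genes whose annotated elements the variants overlap, via
#' [mapVariantToElements()]; deduplicated, in first-hit order.
#'
#' @param v variant `GRanges`.
#' @param gmap a [GeneElementMap-class].
#' @return character vector of gene symbols.
#' @export
variantsToGenes <- function(v, gmap) {
  unique(mapVariantToElements(v, gmap)$gene)
}

#' Pathway enrichment of a test gene set against a background
#'
#' For each pathway P builds the 2x2 table a = |test ∩ P|, b = |test \\ P|,
#' c = |background ∩ P|, d = |background \\ P| and computes Fisher's exact
#' p-value (one-sided "greater" by default, i.e. the hypergeometric upper
#' tail), the sample odds ratio `(a d) / (b c)`, and Benjamini-Hochberg
#' adjusted p-values across pathways. Test genes missing from the background
#' are added to it with a warning, so the margins stay consistent.
#'
#' @param testGenes character vector of test gene symbols (non-empty).
#' @param backgroundGenes character vector of background gene symbols.
#' @param db a [PathwayDB-class].
#' @param alternative `"greater"` (enrichment, default), `"less"` or
#'   `"two.sided"`.
#' @param adjust multiple-testing method for [stats::p.adjust()];
#'   default `"BH"`.
#' @return data.frame with one row per pathway: `pathway`, `a`, `b`, `c`,
#'   `d`, `odds_ratio`, `p`, `p_adj`, in database order.
#' @export
vseaEnrich <- function(testGenes, backgroundGenes, db,
                       alternative = c("greater", "less", "two.sided"),
                       adjust = "BH") {
  alternative <- match.arg(alternative)
  testGenes <- unique(testGenes)
  backgroundGenes <- unique(backgroundGenes)
  if (!length(testGenes)) stop("empty test gene set")
  stray <- setdiff(testGenes, backgroundGenes)
  if (length(stray)) {
    warning(length(stray),
            " test gene(s) absent from the background; added to it")
    backgroundGenes <- c(backgroundGenes, stray)
  }
  res <- lapply(names(db@pathways), function(nm) {
    pw <- db@pathways[[nm]]
    a <- sum(testGenes %in% pw); b <- length(testGenes) - a
    c_ <- sum(backgroundGenes %in% pw); d <- length(backgroundGenes) - c_
    p <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2L, byrow = TRUE),
                            alternative = alternative)$p.value
    data.frame(pathway = nm, a = a, b = b, c = c_, d = d,
               odds_ratio = (a * d) / (b * c_), p = min(p, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out
}
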