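# Seeded generators for every input the toolkit consumes: subpopulation
# frequency tables under the Balding-Nichols model, planted-signal training
# cohorts (variants + annotation tracks + conservation + frequencies), and
# pathway worlds with a planted enriched pathway. All generators are pure
# functions of their arguments (seed included): a fixed seed reproduces
# bit-identical output.

#' Simulate a subpopulation frequency table (Balding-Nichols)
#'
#' Per locus, an ancestral frequency `p0` is drawn uniformly from `p0Range`;
#' each subpopulation frequency is drawn from
#' `Beta(p0 (1-F)/F, (1-p0)(1-F)/F)`, whose mean is `p0` and whose
#' variance corresponds to a differentiation level `F`; the *observed*
#' frequency is a binomial draw at the population's sample size, so the
#' finite-sample corrections of the F_ST estimator are actually exercised.
#'
#' @param nLoci number of loci.
#' @param populations subpopulation labels (default the five continental
#'   superpopulations).
#' @param sampleSizes per-population sample sizes in allele copies.
#' @param F planted differentiation parameter in (0, 1).
#' @param p0Range range of the ancestral frequency.
#' @param seed integer seed.
#' @param chrom chromosome name for the synthetic loci.
#' @param posStart first locus position; loci are spaced 10 bp apart.
#' @return list with `table` (a [PopulationFrequencyTable-class] carrying
#'   locus coordinates), `trueF`, `p0` (ancestral frequencies) and `latent`
#'   (the pre-sampling subpopulation frequencies).
#' @export
simulateFrequencyTable <- function(nLoci = 5000L,
                                   populations = c("AFR", "AMR", "EAS", "EUR", "SAS"),
                                   sampleSizes = rep(500L, 5L),
                                   F = 0.1, p0Range = c(0.05, 0.95),
                                   seed = 1, chrom = "1", posStart = 1L) {
  stopifnot(nLoci >= 1L, F > 0, F < 1, length(populations) >= 2L,
            length(sampleSizes) == length(populations))
  s <- length(populations)
  out <- .with_seed(seed, {
    p0 <- stats::runif(nLoci, p0Range[1L], p0Range[2L])
    lat <- matrix(stats::rbeta(nLoci * s,
                               rep(p0, s) * (1 - F) / F,
                               rep(1 - p0, s) * (1 - F) / F),
                  nrow = nLoci)
    obs <- matrix(stats::rbinom(nLoci * s,
                                size = rep(sampleSizes, each = nLoci),
                                prob = lat),
                  nrow = nLoci) / rep(sampleSizes, each = nLoci)
    list(p0 = p0, lat = lat, obs = obs)
  })
  tab <- PopulationFrequencyTable(out$obs, sampleSizes, populations,
                                  chrom = rep(chrom, nLoci),
                                  pos = posStart + 10L * (seq_len(nLoci) - 1L))
  list(table = tab, trueF = F, p0 = out$p0, latent = out$lat)
}

#' Simulate a planted-signal training cohort
#'
#' Generates labeled variants with every input the feature-assembly and
#' classifier stages consume. Functional variants preferentially overlap the
#' informative annotation tracks (probability `0.5 + effectSize/2` versus
#' `0.5 - effectSize/2` for controls), carry elevated conservation scores,
#' and draw their allele-frequency loci from a high-differentiation
#' Balding-Nichols regime; controls show the opposite pattern. Noise tracks
#' overlap both classes at the same rate. With `effectSize = 0` every
#' feature is uninformative (the null cohort).
#'
#' @param nVariants cohort size (half functional, half control).
#' @param nInformative number of informative annotation tracks.
#' @param nNoise number of pure-noise annotation tracks.
#' @param effectSize planted effect in `[0, 1]`.
#' @param noiseOverlap overlap probability of noise tracks; default 0.15.
#' @param consCoverage fraction of variants covered by each conservation
#'   track; default 0.9 (the rest are missing).
#' @param populations,sampleSizes as in [simulateFrequencyTable()].
#' @param seed integer seed.
#' @return list with `variants` (labeled `GRanges`), `labels` (+1
#'   functional / -1 control), `tracks` (informative then noise
#'   [AnnotationTrack-class]s), `conservation` (two
#'   [ConservationTrack-class]s), `freq` (a [PopulationFrequencyTable-class]
#'   aligned to variant positions) and `effectSize`.
#' @export
simulateTrainingCohort <- function(nVariants = 2000L, nInformative = 10L,
                                   nNoise = 200L, effectSize = 0.8,
                                   noiseOverlap = 0.15, consCoverage = 0.9,
                                   populations = c("AFR", "AMR", "EAS", "EUR", "SAS"),
                                   sampleSizes = rep(500L, 5L), seed = 1) {
  stopifnot(nVariants >= 2L, effectSize >= 0, effectSize <= 1)
  n <- 2L * (nVariants %/% 2L)
  lab <- rep(c(1, -1), each = n / 2L)
  pos <- 1000L + 10L * (seq_len(n) - 1L)
  s <- length(populations)
  sim <- .with_seed(seed, {
    fun <- lab > 0
    pOv <- ifelse(fun, 0.5 + effectSize / 2, 0.5 - effectSize / 2)
    trackHit <- matrix(stats::rbinom(n * nInformative, 1L, rep(pOv, nInformative)),
                       nrow = n)
    noiseHit <- matrix(stats::rbinom(n * nNoise, 1L, noiseOverlap), nrow = n)
    shp <- 2 + 6 * effectSize
    consA <- ifelse(fun, stats::rbeta(n, shp, 2), stats::rbeta(n, 2, shp))
    consB <- ifelse(fun, stats::rbeta(n, shp, 2), stats::rbeta(n, 2, shp))
    covA <- stats::rbinom(n, 1L, consCoverage) == 1L
    covB <- stats::rbinom(n, 1L, consCoverage) == 1L
    # per-variant locus under Balding-Nichols; differentiation depends on label
    Fv <- ifelse(fun, 0.01 + 0.24 * effectSize, 0.01)
    p0 <- stats::runif(n, 0.05, 0.95)
    lat <- matrix(stats::rbeta(n * s, rep(p0, s) * (1 - rep(Fv, s)) / rep(Fv, s),
                               rep(1 - p0, s) * (1 - rep(Fv, s)) / rep(Fv, s)),
                  nrow = n)
    obs <- matrix(stats::rbinom(n * s, size = rep(sampleSizes, each = n),
                                prob = lat), nrow = n) /
      rep(sampleSizes, each = n)
    list(trackHit = trackHit, noiseHit = noiseHit, consA = consA,
         consB = consB, covA = covA, covB = covB, obs = obs)
  })
  v <- makeVariants(rep("1", n), pos, rep("A", n), rep("G", n),
                    label = ifelse(lab > 0, "functional", "control"))
  mkTrack <- function(hits, nm)
    AnnotationTrack(nm, GenomicRanges::GRanges(
      rep("1", sum(hits)), IRanges::IRanges(pos[hits == 1L], width = 1L)))
  tracks <- c(
    lapply(seq_len(nInformative), function(k)
      mkTrack(sim$trackHit[, k], sprintf("informative_%02d", k))),
    lapply(seq_len(nNoise), function(k)
      mkTrack(sim$noiseHit[, k], sprintf("noise_%03d", k))))
  conservation <- list(
    ConservationTrack("phastcons", rep("1", sum(sim$covA)), pos[sim$covA],
                      sim$consA[sim$covA]),
    ConservationTrack("phylop", rep("1", sum(sim$covB)), pos[sim$covB],
                      sim$consB[sim$covB]))
  freq <- PopulationFrequencyTable(sim$obs, sampleSizes, populations,
                                   chrom = rep("1", n), pos = pos)
  list(variants = v, labels = lab, tracks = tracks,
       conservation = conservation, freq = freq, effectSize = effectSize)
}

#' Simulate a pathway world with (optionally) a planted enriched pathway
#'
#' Builds a synthetic gene universe partitioned into overlapping pathways, a
#' gene element map (one element per gene, types rotating through the weight
#' scheme's element types), a gene-disease count table, and test/background
#' variant sets positioned inside the elements of the selected genes. With
#' `planted = TRUE`, a fraction of the test genes is drawn from the first
#' pathway, which should then attain the smallest adjusted p-value; with
#' `planted = FALSE` test genes are drawn uniformly (the null used for
#' type-I calibration).
#'
#' The background gene set is a superset of the test genes (the uploaded
#' background variant set normally contains the test variants) and is kept
#' much larger than the test set: Fisher's exact test on discrete tables is
#' conservative, and wide margins keep its type-I behaviour near nominal.
#'
#' @param nGenes size of the gene universe.
#' @param nPathways,pathwaySize number and size of the gene sets.
#' @param nTestGenes number of test genes.
#' @param nBackgroundGenes number of *additional* background genes beyond
#'   the test genes.
#' @param plantedFraction fraction of test genes drawn from the planted
#'   pathway when `planted = TRUE`.
#' @param planted whether to plant an enrichment signal.
#' @param seed integer seed.
#' @return list with `db` (a [PathwayDB-class]), `planted` (pathway name or
#'   `NA`), `gmap` (a [GeneElementMap-class]), `diseaseCounts`,
#'   `testVariants`, `backgroundVariants`, `testGenes`, `backgroundGenes`.
#' @export
simulatePathways <- function(nGenes = 6000L, nPathways = 20L,
                             pathwaySize = 1200L, nTestGenes = 150L,
                             nBackgroundGenes = 4000L,
                             plantedFraction = 0.5, planted = TRUE,
                             seed = 1) {
  stopifnot(nGenes >= nTestGenes + nBackgroundGenes, pathwaySize <= nGenes)
  genes <- sprintf("G%05d", seq_len(nGenes))
  types <- names(defaultElementWeights())
  out <- .with_seed(seed, {
    pws <- lapply(seq_len(nPathways), function(i) sample(genes, pathwaySize))
    names(pws) <- sprintf("PW%03d", seq_len(nPathways))
    counts <- stats::setNames(sample(0:5, nGenes, replace = TRUE), genes)
    if (planted) {
      nPl <- round(plantedFraction * nTestGenes)
      tg <- c(sample(pws[[1L]], min(nPl, pathwaySize)),
              sample(setdiff(genes, pws[[1L]]), nTestGenes - min(nPl, pathwaySize)))
      tg <- unique(tg)
    } else {
      tg <- sample(genes, nTestGenes)
    }
    bg <- c(tg, sample(setdiff(genes, tg), nBackgroundGenes))
    list(pws = pws, counts = counts, tg = tg, bg = bg)
  })
  gmap <- GeneElementMap(chrom = rep("1", nGenes),
                         start = 2000L * (seq_len(nGenes) - 1L) + 1L,
                         end = 2000L * (seq_len(nGenes) - 1L) + 1000L,
                         gene = genes,
                         type = rep_len(types, nGenes))
  geneStart <- stats::setNames(2000L * (seq_len(nGenes) - 1L) + 1L, genes)
  mkv <- function(g) makeVariants(rep("1", length(g)), geneStart[g] + 500L,
                                  rep("A", length(g)), rep("G", length(g)))
  list(db = PathwayDB(out$pws, source = "synthetic"),
       planted = if (planted) "PW001" else NA_character_,
       gmap = gmap, diseaseCounts = out$counts,
       testVariants = mkv(out$tg), backgroundVariants = mkv(out$bg),
       testGenes = out$tg, backgroundGenes = out$bg)
}
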