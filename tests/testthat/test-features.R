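test_that("registry indices are unique, contiguous and never reassigned", {
  reg <- FeatureRegistry()
  i1 <- registerFeature(reg, "exon", "annotation")
  i2 <- registerFeature(reg, "phastcons", "conservation")
  expect_equal(c(i1, i2), c(1L, 2L))
  expect_equal(registerFeature(reg, "exon", "annotation"), 1L)
  expect_error(registerFeature(reg, "exon", "population"), "already registered")
  i3 <- registerFeature(reg, "fst", "population")
  expect_equal(i3, 3L)
  ent <- registryEntries(reg)
  expect_equal(ent$index, 1:3)
  expect_true(is.na(featureIndex(reg, "absent")))
})

test_that("annotation features are binary presence flags, missing when no overlap", {
  v <- makeVariants(c("1", "1"), c(150L, 900L), c("A", "A"), c("G", "G"))
  tracks <- list(simple_track("exon", "1", 100L, 200L),
                 simple_track("enhancer", "1", 300L, 400L),
                 simple_track("tss", "2", 100L, 200L),
                 simple_track("utr3", "1", 140L, 160L),
                 simple_track("open_chromatin", "1", 1000L, 1100L))
  reg <- FeatureRegistry()
  fv <- annotationFeatures(v, tracks, reg)
  expect_equal(fv[[1]]$index, c(1L, 4L))     # exon + utr3 only
  expect_equal(fv[[1]]$value, c(1, 1))
  expect_equal(nrow(fv[[2]]), 0L)            # overlaps nothing -> all missing
  expect_equal(registrySize(reg), 5L)
})

test_that("annotation feature matrix equals the brute-force overlap scan", {
  withr::local_seed(17)
  nv <- 200L; nt <- 8L
  v <- makeVariants(rep("1", nv), sample(1:5000, nv), rep("A", nv), rep("G", nv))
  tracks <- lapply(seq_len(nt), function(k) {
    st <- sample(1:5000, 30)
    simple_track(paste0("tr", k), rep("1", 30), st, st + sample(0:50, 30, TRUE))
  })
  reg <- FeatureRegistry()
  fm <- assembleFeatureMatrix(v, reg, tracks = tracks)
  m <- featureMatrix(fm)
  for (k in seq_len(nt)) {
    want <- oracle_overlaps(rep("1", nv), GenomicRanges::start(v),
                            GenomicRanges::start(v),
                            rep("1", 30), GenomicRanges::start(trackRanges(tracks[[k]])),
                            GenomicRanges::end(trackRanges(tracks[[k]])))
    expect_equal(which(m[, k] == 1), sort(unique(want$variant)),
                 ignore_attr = TRUE)
  }
})

test_that("TSS distance is 0 inside, start distance outside, missing off-chrom", {
  reg <- FeatureRegistry()
  tss <- simple_track("tss", c("1", "1"), c(150L, 200L), c(160L, 210L))
  v <- makeVariants(c("1", "1", "2"), c(155L, 100L, 50L),
                    rep("A", 3), rep("G", 3))
  fv <- tssDistanceFeature(v, tss, reg)
  expect_equal(fv[[1]]$value, 0)        # inside the first TSS interval
  expect_equal(fv[[2]]$value, 50)       # nearest start is 150
  expect_equal(nrow(fv[[3]]), 0L)       # no TSS on chromosome 2
})

test_that("conservation lookups keep zero distinct from missing", {
  reg <- FeatureRegistry()
  trA <- ConservationTrack("c46", c("1", "1"), c(10L, 20L), c(0.0, 0.7))
  trB <- ConservationTrack("c100", "1", 20L, 0.9)
  v <- makeVariants(c("1", "1", "1"), c(10L, 20L, 30L), rep("A", 3), rep("G", 3))
  fv <- conservationFeatures(v, list(trA, trB), reg)
  expect_equal(fv[[1]]$value, 0.0)           # stored zero, one track only
  expect_equal(nrow(fv[[1]]), 1L)
  expect_equal(nrow(fv[[2]]), 2L)            # both tracks cover pos 20
  expect_equal(nrow(fv[[3]]), 0L)            # absent everywhere -> missing
})

test_that("population features agree with the popdiff module outputs", {
  freq <- PopulationFrequencyTable(
    matrix(c(0.1, 0.3, 0.9, 0.35, 0.5, 0.32, 0.2, 0.31, 0.7, 0.33), 2),
    rep(100L, 5), paste0("P", 1:5), chrom = c("1", "1"), pos = c(10L, 20L))
  v <- makeVariants(c("1", "1"), c(10L, 99L), c("A", "A"), c("G", "G"))
  reg <- FeatureRegistry()
  fv <- populationFeatures(v, freq, reg)
  expect_equal(nrow(fv[[1]]), 7L)  # 5 allele frequencies + fst + ds
  expect_equal(nrow(fv[[2]]), 0L)  # not in the resource
  sub <- subsetLoci(freq, 1L)
  comp <- fstUnbiased(sub, clampNonnegative = TRUE)
  ent <- registryEntries(reg)
  expect_equal(fv[[1]]$value[match(featureIndex(reg, "fst"), fv[[1]]$index)],
               comp$fst)
  expect_equal(fv[[1]]$value[match(featureIndex(reg, "ds"), fv[[1]]$index)],
               dispersionScore(sub))
  expect_equal(fv[[1]]$value[match(featureIndex(reg, "af_P1"), fv[[1]]$index)],
               0.1)
})

test_that("monomorphic loci store an explicit zero F_ST and are counted", {
  freq <- PopulationFrequencyTable(matrix(0, 1, 2), c(10L, 10L),
                                   c("A", "B"), chrom = "1", pos = 10L)
  v <- makeVariants("1", 10L, "A", "G")
  reg <- FeatureRegistry()
  fm <- assembleFeatureMatrix(v, reg, freq = freq)
  expect_equal(attr(fm, "monomorphic"), 1L)
  j <- featureIndex(reg, "fst")
  expect_equal(featureMatrix(fm)[1, j], 0)
})

test_that("assembled rows are unions of per-source vectors; registry is stable", {
  v <- makeVariants(c("1", "1", "1"), c(10L, 20L, 30L), rep("A", 3), rep("G", 3))
  tracks <- list(simple_track("exon", "1", 9L, 11L))
  cons <- list(ConservationTrack("c46", "1", 20L, 0.5))
  reg <- FeatureRegistry()
  fm <- assembleFeatureMatrix(v, reg, tracks = tracks, conservation = cons)
  m <- featureMatrix(fm)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(m[1, ], c(exon = 1, c46 = 0), ignore_attr = TRUE)
  expect_equal(m[2, 2], 0.5)
  expect_equal(sum(m[3, ] != 0), 0L)
  before <- registryEntries(reg)
  v2 <- makeVariants("1", 40L, "A", "G")
  fm2 <- assembleFeatureMatrix(v2, reg, tracks = tracks, conservation = cons)
  expect_identical(registryEntries(reg), before)

  # empty variant list: zero rows, registry untouched
  fm0 <- assembleFeatureMatrix(v[0], reg, tracks = tracks, conservation = cons)
  expect_equal(nrow(featureMatrix(fm0)), 0L)
  expect_identical(registryEntries(reg), before)
})

test_that("identical inputs produce bit-identical matrices", {
  co <- simulateTrainingCohort(nVariants = 100L, nInformative = 3L,
                               nNoise = 5L, seed = 9)
  build <- function() {
    reg <- FeatureRegistry()
    assembleFeatureMatrix(co$variants, reg, tracks = co$tracks,
                          conservation = co$conservation, freq = co$freq)
  }
  a <- build(); b <- build()
  expect_identical(featureMatrix(a), featureMatrix(b))
})

test_that("svmlight serialization round-trips all stored triples", {
  co <- simulateTrainingCohort(nVariants = 60L, nInformative = 3L,
                               nNoise = 4L, seed = 4)
  reg <- FeatureRegistry()
  fm <- assembleFeatureMatrix(co$variants, reg, tracks = co$tracks,
                              conservation = co$conservation, freq = co$freq)
  p <- tempfile(fileext = ".svmlight")
  writeFeatureMatrix(fm, p, labels = co$labels)
  back <- readFeatureMatrix(p)
  expect_equal(back$labels, co$labels)
  expect_identical(featureNames(back$matrix), featureNames(fm))
  expect_equal(as.matrix(featureMatrix(back$matrix)),
               as.matrix(featureMatrix(fm)), tolerance = 1e-15)
  expect_identical(matrixVariantKeys(back$matrix), matrixVariantKeys(fm))
})
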