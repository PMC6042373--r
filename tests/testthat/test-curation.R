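test_that("conflicting records stay functional and leave the control side", {
  pathogenic <- makeVariants(rep("1", 2), c(10L, 20L), c("A", "A"), c("G", "G"))
  benign <- makeVariants(rep("1", 2), c(20L, 30L), c("A", "A"), c("G", "G"))
  rc <- resolveConflicts(pathogenic, benign)
  expect_equal(variantKeys(rc$functional), c("1:10:A:G", "1:20:A:G"))
  expect_equal(variantKeys(rc$control), "1:30:A:G")
  expect_equal(rc$conflicts, "1:20:A:G")

  # disjoint inputs pass through; duplicates collapse
  rc2 <- resolveConflicts(
    makeVariants(c("1", "1", "1"), c(1L, 1L, 2L), rep("A", 3), rep("G", 3)),
    makeVariants("1", 9L, "A", "G"))
  expect_length(rc2$functional, 2L)
  expect_length(rc2$control, 1L)
  expect_length(rc2$conflicts, 0L)
})

test_that("cSNP selection applies the p-value and element-overlap filters", {
  gwas <- makeVariants(rep("1", 5), c(10L, 20L, 30L, 40L, 50L),
                       rep("A", 5), rep("G", 5),
                       pvalue = c(1e-9, 1e-9, 1e-7, 1e-10, 1e-9))
  # the 1e-7 variant and one significant variant (pos 40) overlap nothing
  track <- simple_track("el", rep("1", 3), c(10L, 20L, 50L), c(10L, 30L, 50L))
  keep <- selectCsnps(gwas, list(track))
  expect_equal(GenomicRanges::start(keep), c(10L, 20L, 50L))

  expect_length(selectCsnps(gwas, list(track), alpha = 1), 4L)
  expect_length(selectCsnps(gwas, list()), 0L)
  S4Vectors::mcols(gwas)$pvalue[2] <- NA
  expect_error(selectCsnps(gwas, list(track)), "record 2")
})

test_that("candidate sampling respects the F_ST bound, exclusions and seed", {
  n <- 30L
  pos <- seq(10L, by = 10L, length.out = n)
  kg <- makeVariants(rep("1", n), pos, rep("A", n), rep("G", n))
  p <- matrix(0.5, n, 2); p[1:5, 2] <- 0.95  # first five highly differentiated
  freq <- PopulationFrequencyTable(p, c(100L, 100L), c("x", "y"),
                                   chrom = rep("1", n), pos = pos)
  got <- selectControlCandidates(kg, freq, exclusions = "1:60:A:G",
                                 fstMax = 0.01, k = 1000L, seed = 3)
  expect_false(any(GenomicRanges::start(got) %in% pos[1:5]))
  expect_false("1:60:A:G" %in% variantKeys(got))
  expect_length(got, n - 5L - 1L)  # everything eligible fits under k

  small1 <- selectControlCandidates(kg, freq, k = 10L, seed = 3)
  small2 <- selectControlCandidates(kg, freq, k = 10L, seed = 3)
  small3 <- selectControlCandidates(kg, freq, k = 10L, seed = 4)
  expect_identical(variantKeys(small1), variantKeys(small2))
  expect_false(identical(variantKeys(small1), variantKeys(small3)))
})

test_that("inverse ranking recovers planted anti-pattern candidates", {
  withr::local_seed(41)
  ncs <- 40L; nc <- 100L
  csnp_pos <- seq(100L, by = 10L, length.out = ncs)
  cand_pos <- seq(5000L, by = 10L, length.out = nc)
  csnps <- makeVariants(rep("1", ncs), csnp_pos, rep("A", ncs), rep("G", ncs))
  cands <- makeVariants(rep("1", nc), cand_pos, rep("A", nc), rep("G", nc))
  # candidates 1..50 mimic the cSNP pattern; 51..100 are anti-pattern
  like <- 1:50; anti <- 51:100
  track <- simple_track("el", rep("1", ncs + 50L),
                        c(csnp_pos, cand_pos[like]), c(csnp_pos, cand_pos[like]))
  cons <- ConservationTrack("cons", rep("1", ncs + nc),
                            c(csnp_pos, cand_pos),
                            c(runif(ncs, 0.8, 1), runif(50, 0.75, 0.95),
                              runif(50, 0, 0.1)))
  reg <- FeatureRegistry()
  cX <- assembleFeatureMatrix(csnps, reg, tracks = list(track),
                              conservation = list(cons))
  aX <- assembleFeatureMatrix(cands, reg, tracks = list(track),
                              conservation = list(cons))
  rk <- rankInverseControls(cands, cX, aX, m = 50L)
  expect_equal(sort(match(variantKeys(rk$selected), variantKeys(cands))), anti)
  expect_true(all(rk$decision < 0))
  expect_equal(rk$shortfall, 0L)

  # asking for more controls than negative-scoring candidates reports shortfall
  rk2 <- rankInverseControls(cands, cX, aX, m = 1000L)
  expect_gt(rk2$shortfall, 0L)
  expect_equal(length(rk2$selected) + rk2$shortfall, 1000L)

  # determinism
  rk3 <- rankInverseControls(cands, cX, aX, m = 50L)
  expect_identical(variantKeys(rk3$selected), variantKeys(rk$selected))

  # registry mismatch
  reg2 <- FeatureRegistry()
  oX <- assembleFeatureMatrix(cands, reg2, conservation = list(cons))
  expect_error(rankInverseControls(cands, cX, oX, m = 5L), "registry mismatch")
})

test_that("adjacent-variant simulation stays inside the window and is seeded", {
  anchors <- makeVariants(rep("1", 100L), seq(1000L, by = 1000L, length.out = 100L),
                          rep("A", 100L), rep("G", 100L))
  sim <- simulateAdjacentVariants(anchors, window = 50L, perAnchor = 10L,
                                  seed = 8)
  expect_lte(length(sim), 1000L)
  apos <- GenomicRanges::start(anchors)
  spos <- GenomicRanges::start(sim)
  d <- vapply(spos, function(x) min(abs(x - apos)), 1)
  expect_true(all(d >= 1 & d <= 50))
  sim2 <- simulateAdjacentVariants(anchors, window = 50L, perAnchor = 10L,
                                   seed = 8)
  expect_identical(variantKeys(sim), variantKeys(sim2))
  # exclusions are honoured
  sim3 <- simulateAdjacentVariants(anchors, window = 50L, perAnchor = 10L,
                                   exclusions = variantKeys(sim)[1:5], seed = 8)
  expect_false(any(variantKeys(sim)[1:5] %in% variantKeys(sim3)))
})

test_that("recurrence needs observations in at least two distinct donors", {
  v <- makeVariants(rep("1", 5), c(10L, 10L, 20L, 20L, 30L),
                    rep("A", 5), rep("G", 5),
                    donor = c("D1", "D2", "D1", "D1", "D3"))
  flag <- labelRecurrent(v)
  expect_equal(flag, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(labelRecurrent(v, minDonors = 1L),
               c(TRUE, TRUE, TRUE, TRUE, TRUE))
})

test_that("the toy training-set build matches every hand-computed stage count", {
  sets <- suppressWarnings(buildTrainingSets(toy_curation_config()))
  prov <- sets$provenance
  g <- function(stage, source)
    prov$count[prov$stage == stage & prov$source == source]
  expect_equal(g("input", "pathogenic"), 13L)          # one duplicate inside
  expect_equal(g("resolve_conflicts", "functional_kept"), 12L)
  expect_equal(g("resolve_conflicts", "control_kept"), 2L)
  expect_equal(g("resolve_conflicts", "conflicts_removed"), 2L)
  expect_equal(g("select_csnps", "survivors"), 6L)
  expect_equal(g("select_control_candidates", "sampled"), 40L)
  expect_equal(g("rank_inverse_controls", "selected"), 20L)
  expect_equal(g("rank_inverse_controls", "shortfall"), 0L)
  expect_equal(g("union", "functional"), 18L)          # 12 + 6
  expect_equal(g("union", "control"), 22L)             # 2 + 20
  expect_equal(g("balance", "functional"), 18L)
  expect_equal(g("balance", "control"), 18L)
  expect_length(sets$functional, 18L)
  expect_length(sets$control, 18L)
  expect_length(intersect(variantKeys(sets$functional),
                          variantKeys(sets$control)), 0L)
  # the ranked controls are exactly the anti-pattern pool (positions 6000+)
  pos <- GenomicRanges::start(sets$control)
  expect_true(all(pos >= 6000 | pos < 3000))
})

test_that("toy build is deterministic and balancing keeps sets disjoint", {
  a <- suppressWarnings(buildTrainingSets(toy_curation_config()))
  b <- suppressWarnings(buildTrainingSets(toy_curation_config()))
  expect_identical(variantKeys(a$functional), variantKeys(b$functional))
  expect_identical(variantKeys(a$control), variantKeys(b$control))
  c2 <- suppressWarnings(buildTrainingSets(toy_curation_config(seed = 7L)))
  expect_length(intersect(variantKeys(c2$functional), variantKeys(c2$control)),
                0L)
})

test_that("simulated adjacent controls enter the control side when enabled", {
  sets <- suppressWarnings(
    buildTrainingSets(toy_curation_config(perAnchor = 1L, balance = FALSE)))
  prov <- sets$provenance
  nsim <- prov$count[prov$stage == "simulate_adjacent"]
  expect_gt(nsim, 0L)
  expect_equal(prov$count[prov$stage == "union" & prov$source == "control"],
               22L + nsim)
  expect_true(any(S4Vectors::mcols(sets$control)$ref == "N") ||
                nsim == 0L)
})
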