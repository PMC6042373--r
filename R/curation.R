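# Construction of labeled functional/control training sets via the
# filtration pipeline: conflict removal, significant-cSNP selection with an
# element-overlap filter, low-F_ST candidate sampling, preliminary-model
# ranking of inversely associated controls, adjacent-variant simulation, and
# balanced assembly. Every filter is monotone (output is a subset of input,
# except the simulator which only creates novel keys), and survivor counts
# are recorded at every stage.

.dedup_variants <- function(v) v[!duplicated(variantKeys(v))]

#' Resolve pathogenic/benign label conflicts
#'
#' Variants present in both inputs (by `chrom:pos:ref:alt` key) are removed
#' from the benign side but kept on the pathogenic side — the interpretation
#' being that such variants may still contribute to disease in some contexts.
#' Each side is deduplicated by key.
#'
#' @param pathogenic,benign variant `GRanges`.
#' @return list with `functional`, `control` (the retained sides) and
#'   `conflicts` (the conflicting keys).
#' @export
resolveConflicts <- function(pathogenic, benign) {
  pathogenic <- .dedup_variants(pathogenic)
  benign <- .dedup_variants(benign)
  conflict <- intersect(variantKeys(pathogenic), variantKeys(benign))
  list(functional = pathogenic,
       control = benign[!variantKeys(benign) %in% conflict],
       conflicts = conflict)
}

#' Select significant, element-overlapping cSNPs
#'
#' Keeps GWAS variants with association p-value `<= alpha` that overlap at
#' least one interval of any element track; input order is preserved.
#'
#' @param gwas variant `GRanges` carrying a `pvalue` metadata column.
#' @param elementTracks list of [AnnotationTrack-class] objects.
#' @param alpha significance threshold; default `1e-8`.
#' @return the surviving variants.
#' @export
selectCsnps <- function(gwas, elementTracks, alpha = 1e-8) {
  p <- S4Vectors::mcols(gwas)$pvalue
  if (is.null(p) || any(is.na(p)))
    stop("missing p-value for record ",
         if (is.null(p)) 1L else which(is.na(p))[1L])
  sig <- p <= alpha
  anyov <- rep(FALSE, length(gwas))
  for (tr in elementTracks)
    anyov <- anyov | .quiet_seqlevels(
      IRanges::overlapsAny(gwas, trackRanges(tr), ignore.strand = TRUE))
  gwas[sig & anyov]
}

#' Sample low-F_ST control candidates
#'
#' Draws a seeded uniform sample of size `min(k, eligible)` from variants
#' whose F_ST (looked up in `freq` by `chrom:pos`) is defined and below
#' `fstMax`, excluding the given keys (e.g. records redundant with the GWAS
#' source). Output is deduplicated.
#'
#' @param kg variant `GRanges` (the common-variant pool).
#' @param freq a [PopulationFrequencyTable-class] with per-locus coordinates.
#' @param exclusions character vector of `chrom:pos:ref:alt` keys to drop.
#' @param fstMax strict upper bound on F_ST; default 0.01.
#' @param k target sample size; default 100000.
#' @param seed integer seed.
#' @param msgDenominator passed to [fstUnbiased()].
#' @return the sampled candidate variants.
#' @export
selectControlCandidates <- function(kg, freq, exclusions = character(),
                                    fstMax = 0.01, k = 100000L, seed = 1,
                                    msgDenominator = "printed") {
  if (k < 1L) stop("k must be >= 1")
  kg <- .dedup_variants(kg)
  lk <- lociKeys(freq)
  if (is.null(lk)) stop("frequency table must carry per-locus coordinates")
  row <- match(paste0(as.character(GenomicRanges::seqnames(kg)), ":",
                      GenomicRanges::start(kg)), lk)
  fst <- rep(NA_real_, length(kg))
  hasfreq <- which(!is.na(row))
  if (length(hasfreq)) {
    comp <- fstUnbiased(subsetLoci(freq, row[hasfreq]),
                        msgDenominator = msgDenominator)
    fst[hasfreq] <- ifelse(comp$defined, comp$fst, NA_real_)
  }
  eligible <- which(!is.na(fst) & fst < fstMax &
                    !variantKeys(kg) %in% exclusions)
  take <- .with_seed(seed, sample(eligible, min(k, length(eligible))))
  kg[sort(take)]
}

#' Rank inversely associated control variants
#'
#' Trains a preliminary L1-logistic model with the cSNPs as positives and the
#' candidate pool itself as negatives, scores every candidate, and returns
#' the `m` candidates with the most negative decision values — negative
#' meaning inversely associated with the cSNP feature pattern. Only
#' negative-scoring candidates are returned; if fewer than `m` score
#' negative, the shortfall is reported. Equal decision values are ordered by
#' `chrom:pos:ref:alt` key for reproducibility.
#'
#' @param candidates candidate variant `GRanges` (rows of
#'   `candidateMatrix`).
#' @param csnpMatrix,candidateMatrix [FeatureMatrix-class] objects built on a
#'   shared registry.
#' @param m number of controls to select (>= 1).
#' @param C,tol preliminary-model solver settings.
#' @return list with `selected` (variants), `decision` (their decision
#'   values) and `shortfall` (how many of the requested `m` could not be
#'   served by negative-scoring candidates).
#' @export
rankInverseControls <- function(candidates, csnpMatrix, candidateMatrix,
                                m, C = 1, tol = 1e-9) {
  if (m < 1L) stop("m must be >= 1")
  if (!identical(csnpMatrix@featureNames, candidateMatrix@featureNames))
    stop("feature registry mismatch between cSNP and candidate matrices")
  X <- rbind(csnpMatrix@matrix, candidateMatrix@matrix)
  y <- c(rep(1, nrow(csnpMatrix@matrix)), rep(-1, nrow(candidateMatrix@matrix)))
  fit <- trainL1Logistic(X, y, C = C, tol = tol)
  dec <- as.numeric(candidateMatrix@matrix %*% fit@weights) + fit@intercept
  ord <- order(dec, variantKeys(candidates))
  neg <- ord[dec[ord] < 0]
  take <- utils::head(neg, m)
  list(selected = candidates[take], decision = dec[take],
       shortfall = max(0L, m - length(neg)))
}

#' Simulate variants adjacent to anchor variants
#'
#' For each anchor, draws `perAnchor` positions uniformly from the window
#' `[pos - window, pos + window]` excluding the anchor position itself,
#' assigns reference placeholder `"N"` and a random ACGT alternate allele,
#' drops excluded keys, and deduplicates.
#'
#' @param anchors anchor variant `GRanges`.
#' @param window half-width in bp; default 50.
#' @param perAnchor simulated variants per anchor; default 1.
#' @param exclusions `chrom:pos:ref:alt` keys never to emit.
#' @param seed integer seed.
#' @return simulated variant `GRanges` (label `"control"`, source
#'   `"simulated_adjacent"`).
#' @export
simulateAdjacentVariants <- function(anchors, window = 50L, perAnchor = 1L,
                                     exclusions = character(), seed = 1) {
  if (window < 1L) stop("window must be >= 1")
  if (perAnchor < 1L) stop("perAnchor must be >= 1")
  chrom <- as.character(GenomicRanges::seqnames(anchors))
  pos <- GenomicRanges::start(anchors)
  sim <- .with_seed(seed, {
    off <- setdiff(-window:window, 0L)
    do.call(rbind, lapply(seq_along(anchors), function(i) {
      npos <- pmax(1L, pos[i] + sample(off, perAnchor, replace = TRUE))
      data.frame(chrom = chrom[i], pos = npos,
                 alt = sample(c("A", "C", "G", "T"), perAnchor, replace = TRUE))
    }))
  })
  v <- makeVariants(sim$chrom, sim$pos, rep("N", nrow(sim)), sim$alt,
                    label = "control", source = "simulated_adjacent")
  v <- .dedup_variants(v)
  v[!variantKeys(v) %in% exclusions]
}

#' Flag recurrent variants
#'
#' A variant is recurrent when it was observed in at least `minDonors`
#' *distinct* donors (repeated observations in one donor do not count).
#'
#' @param v variant `GRanges` with a `donor` metadata column; one row per
#'   observation.
#' @param minDonors distinct-donor threshold; default 2.
#' @return logical vector, one flag per row of `v` (all observations of a
#'   variant share the flag).
#' @export
labelRecurrent <- function(v, minDonors = 2L) {
  donor <- S4Vectors::mcols(v)$donor
  if (is.null(donor)) stop("variants must carry a 'donor' metadata column")
  key <- variantKeys(v)
  cnt <- vapply(split(donor, key), function(d)
    length(unique(d[!is.na(d)])), 1L)
  unname(cnt[key] >= minDonors)
}

#' Build balanced functional/control training sets
#'
#' Runs the full filtration pipeline:
#' \enumerate{
#'   \item conflict resolution between pathogenic and benign input
#'     ([resolveConflicts()]);
#'   \item significant cSNP selection with the element-overlap filter
#'     ([selectCsnps()]);
#'   \item seeded sampling of low-F_ST control candidates
#'     ([selectControlCandidates()]);
#'   \item preliminary-model ranking of inversely associated controls
#'     ([rankInverseControls()]), features assembled from the configured
#'     tracks/conservation/frequency sources on a fresh registry;
#'   \item optional simulation of rare benign variants adjacent to the
#'     functional set ([simulateAdjacentVariants()]);
#'   \item union, disjointness enforcement and seeded downsampling of the
#'     larger side to balance class sizes.
#' }
#'
#' @param config a list (or YAML file read into one) with entries:
#'   `pathogenic`, `benign`, `gwas`, `kg` (variant TSV paths or `GRanges`),
#'   `tracks` (list of BED paths or `AnnotationTrack`s), `conservation`
#'   (list of TSV paths or `ConservationTrack`s), `freq` (frequency TSV path
#'   or `PopulationFrequencyTable`), and thresholds `alpha` (1e-8), `fstMax`
#'   (0.01), `k` (100000), `m` (required), `window` (50), `perAnchor`
#'   (0 = no simulated controls), `C` (1), `seed` (1), `balance` (TRUE).
#' @return list with `functional`, `control` (disjoint, deduplicated variant
#'   `GRanges` labeled accordingly), `provenance` (data.frame of stage,
#'   source, count) and `shortfall` from the ranking stage.
#' @export
buildTrainingSets <- function(config) {
  cfg <- config
  get_def <- function(nm, def) if (is.null(cfg[[nm]])) def else cfg[[nm]]
  alpha <- get_def("alpha", 1e-8); fstMax <- get_def("fstMax", 0.01)
  k <- get_def("k", 100000L); m <- cfg$m
  if (is.null(m)) stop("config must set 'm' (number of ranked controls)")
  window <- get_def("window", 50L); perAnchor <- get_def("perAnchor", 0L)
  C <- get_def("C", 1); seed <- get_def("seed", 1)
  balance <- get_def("balance", TRUE)

  as_variants <- function(x) if (is.character(x)) readVariants(x) else x
  as_track <- function(x, nm) if (is.character(x)) readBed(x, nm) else x
  as_cons <- function(x) if (is.character(x)) readConservation(x) else x
  as_freq <- function(x) if (is.character(x)) readFrequencyTable(x) else x

  pathogenic <- as_variants(cfg$pathogenic)
  benign <- as_variants(cfg$benign)
  gwas <- as_variants(cfg$gwas)
  kg <- as_variants(cfg$kg)
  tracks <- cfg$tracks %||% list()
  if (length(tracks))
    tracks <- lapply(seq_along(tracks), function(i)
      as_track(tracks[[i]], names(tracks)[i] %||% paste0("track", i)))
  conservation <- lapply(cfg$conservation %||% list(), as_cons)
  freq <- if (is.null(cfg$freq)) NULL else as_freq(cfg$freq)

  prov <- list()
  note <- function(stage, source, count)
    prov[[length(prov) + 1L]] <<- data.frame(stage = stage, source = source,
                                             count = count)
  note("input", "pathogenic", length(pathogenic))
  note("input", "benign", length(benign))
  note("input", "gwas", length(gwas))
  note("input", "kg", length(kg))

  rc <- resolveConflicts(pathogenic, benign)
  note("resolve_conflicts", "functional_kept", length(rc$functional))
  note("resolve_conflicts", "control_kept", length(rc$control))
  note("resolve_conflicts", "conflicts_removed", length(rc$conflicts))

  csnps <- selectCsnps(gwas, tracks, alpha = alpha)
  note("select_csnps", "survivors", length(csnps))

  if (is.null(freq)) stop("config must provide 'freq' for candidate selection")
  cand <- selectControlCandidates(kg, freq, exclusions = variantKeys(gwas),
                                  fstMax = fstMax, k = k,
                                  seed = .child_seed(seed, "candidates"))
  note("select_control_candidates", "sampled", length(cand))

  reg <- FeatureRegistry()
  csnpX <- assembleFeatureMatrix(csnps, reg, tracks = tracks,
                                 conservation = conservation, freq = freq)
  candX <- assembleFeatureMatrix(cand, reg, tracks = tracks,
                                 conservation = conservation, freq = freq)
  # column counts can differ if a later source registered new features;
  # re-assemble the earlier matrix against the final registry
  if (ncol(csnpX@matrix) != ncol(candX@matrix))
    csnpX <- assembleFeatureMatrix(csnps, reg, tracks = tracks,
                                   conservation = conservation, freq = freq)
  rk <- rankInverseControls(cand, csnpX, candX, m = m, C = C)
  note("rank_inverse_controls", "selected", length(rk$selected))
  note("rank_inverse_controls", "shortfall", rk$shortfall)

  functional <- .dedup_variants(c(.strip_mcols(rc$functional),
                                  .strip_mcols(csnps)))
  control_parts <- list(.strip_mcols(rc$control), .strip_mcols(rk$selected))
  if (perAnchor >= 1L) {
    sim <- simulateAdjacentVariants(functional, window = window,
                                    perAnchor = perAnchor,
                                    exclusions = variantKeys(functional),
                                    seed = .child_seed(seed, "adjacent"))
    note("simulate_adjacent", "generated", length(sim))
    control_parts <- c(control_parts, list(.strip_mcols(sim)))
  }
  control <- .dedup_variants(do.call(c, control_parts))
  control <- control[!variantKeys(control) %in% variantKeys(functional)]
  note("union", "functional", length(functional))
  note("union", "control", length(control))
  if (!length(functional) || !length(control))
    stop("empty functional or control set after filtering")

  if (balance) {
    nmin <- min(length(functional), length(control))
    down <- function(v, tag) {
      if (length(v) == nmin) return(v)
      keep <- .with_seed(.child_seed(seed, tag), sample(length(v), nmin))
      v[sort(keep)]
    }
    functional <- down(functional, "balance_functional")
    control <- down(control, "balance_control")
    note("balance", "functional", length(functional))
    note("balance", "control", length(control))
  }
  S4Vectors::mcols(functional)$label <- "functional"
  S4Vectors::mcols(control)$label <- "control"
  list(functional = functional, control = control,
       provenance = do.call(rbind, prov), shortfall = rk$shortfall)
}

.strip_mcols <- function(v) {
  mc <- S4Vectors::mcols(v)
  S4Vectors::mcols(v) <- mc[, c("ref", "alt"), drop = FALSE]
  v
}
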