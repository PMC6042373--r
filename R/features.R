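# Assembly of the sparse variant x feature matrix from the three feature
# classes: population metrics, evolutionary conservation, and genomic
# annotations. Missing (no overlap / not in the resource) is encoded by the
# *absence* of an entry, never by a stored 0 — the only documented exception
# is the monomorphic-F_ST substitution, which stores an explicit 0.

#' Create an empty feature registry
#'
#' @return a [FeatureRegistry-class] with no features.
#' @export
FeatureRegistry <- function() {
  env <- new.env(parent = emptyenv())
  env$index <- stats::setNames(integer(), character())
  env$group <- stats::setNames(character(), character())
  new("FeatureRegistry", env = env)
}

#' Register (or look up) a feature
#'
#' The first registration of a name fixes its index forever; re-registration
#' returns the existing index, and a conflicting group tag is an error.
#'
#' @param registry a [FeatureRegistry-class].
#' @param name feature name(s).
#' @param group group tag(s): `"population"`, `"conservation"` or
#'   `"annotation"` (recycled to `length(name)`).
#' @return integer index (1-based, stable) for each name.
#' @export
registerFeature <- function(registry, name, group) {
  group <- rep_len(match.arg(group, c("population", "conservation", "annotation"),
                             several.ok = TRUE), length(name))
  env <- registry@env
  out <- integer(length(name))
  for (i in seq_along(name)) {
    nm <- name[i]
    if (!is.na(idx <- env$index[nm])) {
      if (env$group[[nm]] != group[i])
        stop("feature '", nm, "' already registered with group '",
             env$group[[nm]], "'")
      out[i] <- idx
    } else {
      idx <- length(env$index) + 1L
      env$index[nm] <- idx
      env$group[nm] <- group[i]
      out[i] <- idx
    }
  }
  out
}

#' @describeIn registerFeature index of an already-registered feature
#'   (`NA` if absent).
#' @export
featureIndex <- function(registry, name) {
  unname(registry@env$index[name])
}

#' @describeIn registerFeature number of registered features.
#' @export
registrySize <- function(registry) length(registry@env$index)

#' @describeIn registerFeature the registry as a data.frame
#'   (`index`, `name`, `group`) in index order.
#' @export
registryEntries <- function(registry) {
  env <- registry@env
  ord <- order(env$index)
  data.frame(index = unname(env$index)[ord], name = names(env$index)[ord],
             group = unname(env$group)[ord], stringsAsFactors = FALSE)
}

setMethod("show", "FeatureRegistry", function(object) {
  cat("FeatureRegistry:", registrySize(object), "features\n")
})

# A sparse feature vector is a data.frame(index, value); helpers below return
# one vector per variant as a list for the exported per-variant operations,
# while assembleFeatureMatrix uses the vectorized triplet internals directly.

.fv <- function(index = integer(), value = numeric()) {
  data.frame(index = as.integer(index), value = as.numeric(value))
}

# triplets: data.frame(variant, index, value) over all variants
.annotation_triplets <- function(v, tracks, registry, mode = "binary") {
  out <- vector("list", length(tracks))
  for (k in seq_along(tracks)) {
    tr <- tracks[[k]]
    j <- registerFeature(registry, trackName(tr), "annotation")
    hits <- overlapsTrack(tr, v)
    if (!nrow(hits)) next
    if (mode == "binary") {
      rows <- unique(hits$variant)
      out[[k]] <- data.frame(variant = rows, index = j, value = 1.0)
    } else {  # overlap fraction of the variant footprint
      cov <- tapply(hits$overlap_length, hits$variant, sum)
      rows <- as.integer(names(cov))
      frac <- pmin(1, as.numeric(cov) / GenomicRanges::width(v)[rows])
      out[[k]] <- data.frame(variant = rows, index = j, value = frac)
    }
  }
  do.call(rbind, c(out, list(.fv0())))
}

.fv0 <- function() data.frame(variant = integer(), index = integer(),
                              value = numeric())

.tss_triplets <- function(v, tssTrack, registry) {
  j <- registerFeature(registry, "tss_distance", "annotation")
  tss <- trackRanges(tssTrack)
  if (!length(tss)) return(.fv0())
  vchr <- as.character(GenomicRanges::seqnames(v))
  tchr <- as.character(GenomicRanges::seqnames(tss))
  tstart <- GenomicRanges::start(tss)
  inside <- .quiet_seqlevels(IRanges::overlapsAny(v, tss, ignore.strand = TRUE))
  pos <- GenomicRanges::start(v)
  d <- rep(NA_real_, length(v))
  for (i in seq_along(v)) {
    same <- tchr == vchr[i]
    if (!any(same)) next
    d[i] <- if (inside[i]) 0 else min(abs(tstart[same] - pos[i]))
  }
  keep <- which(!is.na(d))
  data.frame(variant = keep, index = j, value = d[keep])
}

.conservation_triplets <- function(v, tracks, registry) {
  out <- vector("list", length(tracks))
  chrom <- as.character(GenomicRanges::seqnames(v))
  pos <- GenomicRanges::start(v)
  for (k in seq_along(tracks)) {
    tr <- tracks[[k]]
    j <- registerFeature(registry, tr@name, "conservation")
    sc <- conservationAt(tr, chrom, pos)
    keep <- which(!is.na(sc))
    if (length(keep))
      out[[k]] <- data.frame(variant = keep, index = j, value = sc[keep])
  }
  do.call(rbind, c(out, list(.fv0())))
}

.population_triplets <- function(v, freq, registry,
                                 msgDenominator = "printed") {
  pops <- freq@populations
  jp <- registerFeature(registry, paste0("af_", pops), rep("population", length(pops)))
  jf <- registerFeature(registry, "fst", "population")
  jd <- registerFeature(registry, "ds", "population")
  lk <- lociKeys(freq)
  if (is.null(lk)) stop("frequency table must carry per-locus coordinates")
  vk <- paste0(as.character(GenomicRanges::seqnames(v)), ":",
               GenomicRanges::start(v))
  row <- match(vk, lk)
  keep <- which(!is.na(row))
  if (!length(keep)) return(list(triplets = .fv0(), monomorphic = 0L))
  sub <- subsetLoci(freq, row[keep])
  comp <- fstUnbiased(sub, msgDenominator = msgDenominator,
                      clampNonnegative = TRUE)
  # monomorphic loci carry no differentiation signal: substitute 0, count them
  mono <- sum(!comp$defined)
  fst <- ifelse(comp$defined, comp$fst, 0)
  ds <- dispersionScore(sub)
  trip <- rbind(
    data.frame(variant = rep(keep, length(pops)),
               index = rep(jp, each = length(keep)),
               value = as.numeric(sub@p)),
    data.frame(variant = keep, index = jf, value = fst),
    data.frame(variant = keep, index = jd, value = ds))
  list(triplets = trip, monomorphic = mono)
}

#' Per-variant annotation-overlap features
#'
#' One binary feature per track: value 1.0 when the variant overlaps at least
#' one interval of the track; tracks without overlap emit nothing (missing).
#' `mode = "fraction"` instead emits the overlapped fraction of the variant
#' footprint.
#'
#' @param v variant `GRanges`.
#' @param tracks list of [AnnotationTrack-class] objects.
#' @param registry shared [FeatureRegistry-class] (mutated on first use).
#' @param mode `"binary"` (default) or `"fraction"`.
#' @return list of sparse feature vectors (data.frame `index`, `value`),
#'   one per variant.
#' @export
annotationFeatures <- function(v, tracks, registry, mode = c("binary", "fraction")) {
  mode <- match.arg(mode)
  trip <- .annotation_triplets(v, tracks, registry, mode)
  .split_triplets(trip, length(v))
}

#' Distance-to-nearest-TSS feature
#'
#' Absolute bp distance from the variant position to the nearest TSS interval
#' start on the same chromosome; 0 when the variant lies inside a TSS
#' interval; missing when the chromosome carries no TSS.
#'
#' @inheritParams annotationFeatures
#' @param tssTrack TSS [AnnotationTrack-class].
#' @param transform `"bp"` (raw distance) or `"log10"` for `log10(1 + d)`.
#' @return list of sparse feature vectors, one per variant.
#' @export
tssDistanceFeature <- function(v, tssTrack, registry, transform = c("bp", "log10")) {
  transform <- match.arg(transform)
  trip <- .tss_triplets(v, tssTrack, registry)
  if (transform == "log10") trip$value <- log10(1 + trip$value)
  .split_triplets(trip, length(v))
}

#' Per-variant conservation-score features
#'
#' One numeric feature per conservation track, valued at the variant
#' position; positions absent from a track are missing (a stored score of 0
#' is a real value and is kept).
#'
#' @inheritParams annotationFeatures
#' @param tracks list of [ConservationTrack-class] objects.
#' @return list of sparse feature vectors, one per variant.
#' @export
conservationFeatures <- function(v, tracks, registry) {
  .split_triplets(.conservation_triplets(v, tracks, registry), length(v))
}

#' Per-variant population features
#'
#' For variants found in the frequency resource (matched by `chrom:pos`):
#' one feature per subpopulation allele frequency, plus the F_ST estimate
#' (clamped to nonnegative; monomorphic loci substitute 0) and the dispersion
#' score. Variants absent from the resource emit nothing.
#'
#' @inheritParams annotationFeatures
#' @param freq a [PopulationFrequencyTable-class] with per-locus coordinates,
#'   or `NULL` (all population features missing).
#' @return list of sparse feature vectors, one per variant.
#' @export
populationFeatures <- function(v, freq, registry) {
  if (is.null(freq)) return(rep(list(.fv()), length(v)))
  .split_triplets(.population_triplets(v, freq, registry)$triplets, length(v))
}

.split_triplets <- function(trip, n) {
  out <- rep(list(.fv()), n)
  if (nrow(trip)) {
    sp <- split(trip[c("index", "value")], factor(trip$variant, levels = seq_len(n)))
    out <- lapply(sp, function(d) {
      d <- d[order(d$index), , drop = FALSE]
      rownames(d) <- NULL
      d
    })
  }
  out
}

#' Assemble the sparse feature matrix
#'
#' Runs all configured feature sources over the variants and unions their
#' sparse vectors into one matrix aligned to variant order. The registry is
#' shared across sources, so indices are collision-free and stable: adding
#' variants later never changes existing feature indices.
#'
#' @param v variant `GRanges`.
#' @param registry shared [FeatureRegistry-class].
#' @param tracks list of [AnnotationTrack-class] (binary overlap features).
#' @param conservation list of [ConservationTrack-class].
#' @param freq a [PopulationFrequencyTable-class] with coordinates, or `NULL`.
#' @param tssTrack optional TSS [AnnotationTrack-class] for the distance
#'   feature.
#' @param annotationMode `"binary"` or `"fraction"` per-track overlap values.
#' @param tssTransform `"bp"` or `"log10"`.
#' @return a [FeatureMatrix-class]; the number of monomorphic-F_ST
#'   substitutions performed is reported as `attr(, "monomorphic")`.
#' @export
assembleFeatureMatrix <- function(v, registry, tracks = list(),
                                  conservation = list(), freq = NULL,
                                  tssTrack = NULL,
                                  annotationMode = c("binary", "fraction"),
                                  tssTransform = c("bp", "log10")) {
  annotationMode <- match.arg(annotationMode)
  tssTransform <- match.arg(tssTransform)
  parts <- list(.annotation_triplets(v, tracks, registry, annotationMode))
  if (!is.null(tssTrack)) {
    tt <- .tss_triplets(v, tssTrack, registry)
    if (tssTransform == "log10") tt$value <- log10(1 + tt$value)
    parts <- c(parts, list(tt))
  }
  parts <- c(parts, list(.conservation_triplets(v, conservation, registry)))
  mono <- 0L
  if (!is.null(freq)) {
    pt <- .population_triplets(v, freq, registry)
    mono <- pt$monomorphic
    parts <- c(parts, list(pt$triplets))
  }
  trip <- do.call(rbind, parts)
  ent <- registryEntries(registry)
  m <- Matrix::sparseMatrix(i = trip$variant, j = trip$index, x = trip$value,
                            dims = c(length(v), nrow(ent)))
  fm <- new("FeatureMatrix", matrix = methods::as(m, "CsparseMatrix"),
            featureNames = ent$name, featureGroups = ent$group,
            variantKeys = variantKeys(v))
  attr(fm, "monomorphic") <- mono
  fm
}

#' Write a feature matrix in svmlight/libsvm sparse text format
#'
#' One line per variant: `label index:value ...` (indices 1-based,
#' ascending), plus a sidecar `<path>.features.tsv` mapping index to feature
#' name and group, and `<path>.variants.tsv` with the row keys.
#'
#' @param fm a [FeatureMatrix-class].
#' @param path output file.
#' @param labels numeric labels per row (default 0).
#' @return `path`, invisibly.
#' @export
writeFeatureMatrix <- function(fm, path, labels = rep(0, nrow(fm@matrix))) {
  m <- methods::as(fm@matrix, "TsparseMatrix")
  ord <- order(m@i, m@j)
  i <- m@i[ord] + 1L; j <- m@j[ord] + 1L; x <- m@x[ord]
  pair <- paste0(j, ":", format(x, digits = 17, trim = TRUE, scientific = FALSE))
  body <- vapply(seq_len(nrow(m)), function(r) {
    sel <- i == r
    paste(c(format(labels[r], digits = 17, trim = TRUE), pair[sel]),
          collapse = " ")
  }, "")
  writeLines(body, path)
  utils::write.table(
    data.frame(index = seq_along(fm@featureNames), name = fm@featureNames,
               group = fm@featureGroups),
    paste0(path, ".features.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(key = fm@variantKeys),
    paste0(path, ".variants.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [writeFeatureMatrix()]
#'
#' @param path svmlight file with its `.features.tsv` / `.variants.tsv`
#'   sidecars.
#' @return list with `matrix` (a [FeatureMatrix-class]) and `labels`.
#' @export
readFeatureMatrix <- function(path) {
  feat <- utils::read.delim(paste0(path, ".features.tsv"))
  keys <- utils::read.delim(paste0(path, ".variants.tsv"),
                            colClasses = "character")$key
  lines <- readLines(path)
  toks <- strsplit(lines, " ", fixed = TRUE)
  labels <- vapply(toks, function(t) as.numeric(t[1L]), 1)
  trip <- lapply(seq_along(toks), function(r) {
    t <- toks[[r]][-1L]
    if (!length(t)) return(.fv0())
    kv <- strsplit(t, ":", fixed = TRUE)
    data.frame(variant = r, index = as.integer(vapply(kv, `[`, "", 1L)),
               value = as.numeric(vapply(kv, `[`, "", 2L)))
  })
  trip <- do.call(rbind, trip)
  m <- Matrix::sparseMatrix(i = trip$variant, j = trip$index, x = trip$value,
                            dims = c(length(lines), nrow(feat)))
  fm <- new("FeatureMatrix", matrix = methods::as(m, "CsparseMatrix"),
            featureNames = as.character(feat$name),
            featureGroups = as.character(feat$group), variantKeys = keys)
  list(matrix = fm, labels = labels)
}
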