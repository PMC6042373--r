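# End-to-end pipeline: simulate -> curate -> featurize -> train -> score ->
# annotate -> vsea -> eval, each stage writing its artifacts (TSV with a
# single header row) and logging a count line to stderr. All randomness
# derives from the global seed, so a rerun with the same configuration
# produces byte-identical artifacts.

.known_config <- list(
  top = c("seed", "logLevel", "simulation", "curation", "features", "model",
          "annotation", "vsea", "io"),
  simulation = c("nVariants", "nInformative", "nNoise", "effectSize",
                 "noiseOverlap", "consCoverage", "nGenes", "nPathways",
                 "pathwaySize", "nTestGenes", "nBackgroundGenes",
                 "plantedFraction", "planted"),
  curation = c("pathogenic", "benign", "gwas", "kg", "alpha", "fstMax", "k",
               "m", "window", "perAnchor", "C", "balance"),
  features = c("annotationMode", "tssTransform"),
  model = c("C", "grid", "folds", "tol"),
  annotation = c("weights"),
  vsea = c("alternative", "adjust"),
  io = c())

#' Validate a pipeline run configuration
#'
#' Checks the section structure of a pipeline configuration (a nested list,
#' e.g. read from YAML) and rejects unknown keys.
#'
#' @param config nested list of settings.
#' @return the config, invisibly, or an error naming the offending key.
#' @export
validateRunConfig <- function(config) {
  bad <- setdiff(names(config), .known_config$top)
  if (length(bad)) stop("unknown config key: ", bad[1L])
  for (sec in intersect(names(config), names(.known_config))) {
    if (sec == "top") next
    bad <- setdiff(names(config[[sec]]), .known_config[[sec]])
    if (length(bad)) stop("unknown config key: ", sec, ".", bad[1L])
  }
  invisible(config)
}

.log <- function(level, ...) {
  if (level != "quiet") message("[pafa] ", ...)
}

.need_file <- function(path, stage) {
  if (is.character(path) && !file.exists(path))
    stop("stage ", stage, ": missing input file: ", path)
  path
}

#' Run the full pipeline
#'
#' Simulates a study (training cohort + pathway world), curates balanced
#' training sets, assembles the feature matrix, trains the sparse logistic
#' model, scores all cohort variants, computes gene-centric annotation
#' scores for the test variant set, runs the pathway enrichment, and
#' evaluates the model by stratified cross-validation and a rank-sum test.
#' Every stage writes tab-separated artifacts into `outDir` and logs its
#' counts; a failure aborts with the stage name.
#'
#' @param config nested configuration list, or the path of a YAML file
#'   holding one (see [validateRunConfig()] for the sections). All
#'   thresholds default to the package defaults (alpha `1e-8`, fstMax 0.01,
#'   window 50, C 1, ...).
#' @param outDir output directory (created if needed).
#' @param seed global integer seed; overrides `config$seed`.
#' @return invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(config = list(), outDir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validateRunConfig(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  lvl <- config$logLevel %||% "info"
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  g <- function(sec, nm, def) config[[sec]][[nm]] %||% def
  wtsv <- function(df, nm) {
    utils::write.table(df, file.path(outDir, nm), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  ## -- simulate ------------------------------------------------------------
  cohort <- simulateTrainingCohort(
    nVariants = g("simulation", "nVariants", 400L),
    nInformative = g("simulation", "nInformative", 5L),
    nNoise = g("simulation", "nNoise", 20L),
    effectSize = g("simulation", "effectSize", 0.8),
    noiseOverlap = g("simulation", "noiseOverlap", 0.15),
    consCoverage = g("simulation", "consCoverage", 0.9),
    seed = .child_seed(seed, "cohort"))
  world <- simulatePathways(
    nGenes = g("simulation", "nGenes", 600L),
    nPathways = g("simulation", "nPathways", 10L),
    pathwaySize = g("simulation", "pathwaySize", 40L),
    nTestGenes = g("simulation", "nTestGenes", 80L),
    nBackgroundGenes = g("simulation", "nBackgroundGenes", 240L),
    plantedFraction = g("simulation", "plantedFraction", 0.3),
    planted = g("simulation", "planted", TRUE),
    seed = .child_seed(seed, "pathways"))
  writeVariants(cohort$variants, file.path(outDir, "variants.tsv"))
  writeFrequencyTable(cohort$freq, file.path(outDir, "freq.tsv"))
  .log(lvl, "stage simulate: ", length(cohort$variants), " variants, ",
       length(cohort$tracks), " tracks, ",
       length(pathwayList(world$db)), " pathways")

  ## -- curate --------------------------------------------------------------
  v <- cohort$variants
  fun <- v[cohort$labels > 0]; ctl <- v[cohort$labels < 0]
  nf <- length(fun); nc <- length(ctl)
  # partition the simulated truth into curation-style sources: pathogenic,
  # benign (with two planted conflicts), significant GWAS hits, and a
  # common-variant pool
  cut1 <- max(1L, round(0.3 * nf))
  pathogenic <- fun[seq_len(cut1)]
  gwas_fun <- fun[seq(cut1 + 1L, nf)]
  cut2 <- max(1L, round(0.2 * nc))
  benign <- c(ctl[seq_len(cut2)], pathogenic[seq_len(min(2L, cut1))])
  gwas_ctl <- ctl[seq(cut2 + 1L, min(nc, cut2 + max(1L, round(0.3 * nc))))]
  kg <- ctl
  pv <- .with_seed(.child_seed(seed, "gwas_p"), {
    c(10^-stats::runif(length(gwas_fun), 9, 12),
      10^-stats::runif(length(gwas_ctl), 2, 6))
  })
  gwas <- c(gwas_fun, gwas_ctl)
  S4Vectors::mcols(gwas)$pvalue <- pv
  for (ov in c("pathogenic", "benign", "gwas", "kg")) {
    if (!is.null(config$curation[[ov]]))
      assign(ov, readVariants(.need_file(config$curation[[ov]], "curate")))
  }
  sets <- buildTrainingSets(list(
    pathogenic = pathogenic, benign = benign, gwas = gwas, kg = kg,
    tracks = cohort$tracks, conservation = cohort$conservation,
    freq = cohort$freq,
    alpha = g("curation", "alpha", 1e-8),
    fstMax = g("curation", "fstMax", 0.01),
    k = g("curation", "k", 100000L),
    m = g("curation", "m", 50L),
    window = g("curation", "window", 50L),
    perAnchor = g("curation", "perAnchor", 0L),
    C = g("curation", "C", 1),
    balance = g("curation", "balance", TRUE),
    seed = .child_seed(seed, "curate")))
  writeVariants(sets$functional, file.path(outDir, "functional.tsv"))
  writeVariants(sets$control, file.path(outDir, "control.tsv"))
  wtsv(sets$provenance, "provenance.tsv")
  .log(lvl, "stage curate: ", length(sets$functional), " functional / ",
       length(sets$control), " control")

  ## -- featurize -----------------------------------------------------------
  reg <- FeatureRegistry()
  train_v <- c(sets$functional, sets$control)
  y <- c(rep(1, length(sets$functional)), rep(-1, length(sets$control)))
  X <- assembleFeatureMatrix(
    train_v, reg, tracks = cohort$tracks,
    conservation = cohort$conservation, freq = cohort$freq,
    annotationMode = g("features", "annotationMode", "binary"),
    tssTransform = g("features", "tssTransform", "bp"))
  writeFeatureMatrix(X, file.path(outDir, "train.svmlight"), labels = y)
  .log(lvl, "stage featurize: ", nrow(featureMatrix(X)), " x ",
       ncol(featureMatrix(X)), " matrix")

  ## -- train ---------------------------------------------------------------
  grid <- g("model", "grid", NULL)
  C <- if (!is.null(grid))
    selectC(X, y, grid = grid, folds = g("model", "folds", 5L),
            seed = .child_seed(seed, "selectC"))$C
  else g("model", "C", 1)
  model <- trainL1Logistic(X, y, C = C, tol = g("model", "tol", 1e-9))
  writeModel(model, file.path(outDir, "model.tsv"))
  .log(lvl, "stage train: C = ", C, ", ",
       sum(modelWeights(model) != 0), " nonzero weights")

  ## -- score ---------------------------------------------------------------
  Xall <- assembleFeatureMatrix(
    v, reg, tracks = cohort$tracks, conservation = cohort$conservation,
    freq = cohort$freq,
    annotationMode = g("features", "annotationMode", "binary"),
    tssTransform = g("features", "tssTransform", "bp"))
  scores <- scoreVariants(model, Xall)
  wtsv(data.frame(chrom = as.character(GenomicRanges::seqnames(v)),
                  pos = GenomicRanges::start(v),
                  ref = S4Vectors::mcols(v)$ref, alt = S4Vectors::mcols(v)$alt,
                  pafa_score = format(scores, digits = 17, trim = TRUE)),
       "scores.tsv")
  .log(lvl, "stage score: ", length(scores), " variants scored")

  ## -- annotate ------------------------------------------------------------
  gs <- geneDiseaseScore(world$testVariants, world$gmap, WeightScheme(),
                         world$diseaseCounts)
  wtsv(data.frame(key = gs$key, score = gs$score), "annotate.tsv")
  .log(lvl, "stage annotate: ", nrow(gs), " variants annotated")

  ## -- vsea ----------------------------------------------------------------
  tg <- variantsToGenes(world$testVariants, world$gmap)
  bg <- variantsToGenes(world$backgroundVariants, world$gmap)
  enr <- vseaEnrich(tg, bg, world$db,
                    alternative = g("vsea", "alternative", "greater"),
                    adjust = g("vsea", "adjust", "BH"))
  wtsv(enr, "vsea.tsv")
  .log(lvl, "stage vsea: ", nrow(enr), " pathways tested, min p_adj = ",
       signif(min(enr$p_adj), 3))

  ## -- eval ----------------------------------------------------------------
  cv <- crossValidate(X, y, folds = g("model", "folds", 5L), C = C,
                      seed = .child_seed(seed, "cv"))
  rs <- ranksumPvalue(scores[cohort$labels > 0], scores[cohort$labels < 0],
                      alternative = "greater")
  wtsv(data.frame(metric = c(paste0("cv_auc_fold", seq_along(cv$foldAuc)),
                             "cv_auc_mean", "ranksum_p"),
                  value = format(c(cv$foldAuc, cv$meanAuc, rs), digits = 17,
                                 trim = TRUE)),
       "eval.tsv")
  .log(lvl, "stage eval: mean CV AUC = ", signif(cv$meanAuc, 4),
       ", rank-sum p = ", signif(rs, 3))

  invisible(list(cohort = cohort, world = world, sets = sets, matrix = X,
                 model = model, scores = scores, enrichment = enr, cv = cv))
}
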