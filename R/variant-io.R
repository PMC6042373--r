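# Variant / interval data model and readers for the standard formats.
#
# Variants are carried as a GRanges whose footprint is the reference-allele
# span (start = POS, width = nchar(ref); 1-based, closed) with metadata
# columns ref, alt and optionally id, label, source, pvalue, donor. SNVs are
# the tested path; indels are a best-effort extension via the same footprint
# rule.

normChrom <- function(x) sub("^chr", "", as.character(x))

normalizeSeqnames <- function(gr) {
  lv <- GenomeInfoDb::seqlevels(gr)
  GenomeInfoDb::seqlevels(gr) <- normChrom(lv)
  gr
}

.allele_ok <- function(a) {
  !is.na(a) & nzchar(a) & !grepl("[^ACGTN]", a)
}

#' Construct a variant set
#'
#' @param chrom chromosome names (a leading `"chr"` is stripped).
#' @param pos 1-based positions as in VCF.
#' @param ref,alt reference and alternate alleles (non-empty, over ACGTN,
#'   `ref != alt`).
#' @param ... further per-variant metadata columns (e.g. `id`, `label`,
#'   `source`, `pvalue`, `donor`), recycled if length 1.
#' @return a `GRanges`; the interval of each variant is the reference-allele
#'   footprint `[pos, pos + nchar(ref) - 1]`.
#' @export
makeVariants <- function(chrom, pos, ref, alt, ...) {
  pos <- as.integer(pos)
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad)) stop("variant ", bad[1L], ": pos must be >= 1")
  bad <- which(!.allele_ok(ref) | !.allele_ok(alt))
  if (length(bad)) stop("variant ", bad[1L], ": alleles must be non-empty ACGTN strings")
  bad <- which(ref == alt)
  if (length(bad)) stop("variant ", bad[1L], ": ref and alt must differ")
  gr <- GenomicRanges::GRanges(normChrom(chrom),
    IRanges::IRanges(pos, width = nchar(ref)), ref = ref, alt = alt)
  extra <- list(...)
  for (nm in names(extra))
    S4Vectors::mcols(gr)[[nm]] <- extra[[nm]]
  gr
}

#' Variant identity keys
#'
#' @param v a variant `GRanges` (see [makeVariants()]).
#' @return character keys `chrom:pos:ref:alt` used for set operations,
#'   deduplication and disjointness checks throughout the package.
#' @export
variantKeys <- function(v) {
  paste(as.character(GenomicRanges::seqnames(v)), GenomicRanges::start(v),
        S4Vectors::mcols(v)$ref, S4Vectors::mcols(v)$alt, sep = ":")
}

#' Read variants from TSV or VCF
#'
#' TSV input requires a header with columns `chrom, pos, ref, alt`; optional
#' columns (`id`, `label`, `pvalue`, `donor`, ...) are carried through as
#' metadata. VCF rows with multiple ALT alleles are split into one record per
#' alternate allele. Input order is preserved.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return a variant `GRanges`.
#' @export
readVariants <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") .read_variants_vcf(path) else .read_variants_tsv(path)
}

.read_variants_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% colnames(df)))
    stop("TSV variant table must have columns chrom, pos, ref, alt: ", path)
  pos <- suppressWarnings(as.integer(df$pos))
  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad))
    stop("malformed variant at line ", bad[1L] + 1L, " of ", path,
         ": pos must be an integer >= 1")
  ref <- toupper(df$ref); alt <- toupper(df$alt)
  bad <- which(!.allele_ok(ref) | !.allele_ok(alt) | ref == alt)
  if (length(bad))
    stop("malformed variant at line ", bad[1L] + 1L, " of ", path,
         ": alleles must be non-empty ACGTN strings with ref != alt")
  extra <- df[setdiff(colnames(df), req)]
  if ("pvalue" %in% colnames(extra))
    extra$pvalue <- as.numeric(extra$pvalue)
  do.call(makeVariants,
          c(list(chrom = df$chrom, pos = pos, ref = ref, alt = alt),
            as.list(extra)))
}

.read_variants_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  vcf <- VariantAnnotation::expand(vcf)  # one record per ALT allele
  rr <- SummarizedExperiment::rowRanges(vcf)
  makeVariants(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    id = names(rr))
}

#' Write variants as TSV
#'
#' Emits a tab-separated table with a single header row; `chrom, pos, ref,
#' alt` plus any metadata columns. `readVariants()` round-trips the core
#' columns exactly.
#'
#' @param v variant `GRanges`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeVariants <- function(v, path) {
  mc <- as.data.frame(S4Vectors::mcols(v))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(v)),
                   pos = GenomicRanges::start(v),
                   ref = mc$ref, alt = mc$alt,
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (nm in setdiff(colnames(mc), c("ref", "alt"))) df[[nm]] <- mc[[nm]]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED3/BED4 annotation track
#'
#' BED uses 0-based half-open intervals; they are converted to the internal
#' 1-based closed convention on read (`start + 1`). An optional 4th column is
#' stored as the per-interval gene symbol. Strand (column 6), when present,
#' is stored but ignored by overlap queries.
#'
#' @param path BED file (tab-separated, no header).
#' @param name track name.
#' @return an [AnnotationTrack-class].
#' @export
readBed <- function(path, name) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !grepl("^(track|browser|#)", lines))
  if (!length(keep)) {
    return(AnnotationTrack(name, GenomicRanges::GRanges()))
  }
  fields <- strsplit(lines[keep], "\t")
  nf <- vapply(fields, length, 1L)
  if (any(nf < 3L))
    stop("malformed BED at line ", keep[which(nf < 3L)[1L]], " of ", path)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start0) | is.na(end0) | start0 >= end0 | start0 < 0L)
  if (length(bad))
    stop("invalid BED interval (start must be < end) at line ", keep[bad[1L]],
         " of ", path)
  gr <- GenomicRanges::GRanges(
    normChrom(vapply(fields, `[`, "", 1L)),
    IRanges::IRanges(start0 + 1L, end0))
  if (all(nf >= 4L))
    S4Vectors::mcols(gr)$gene <- vapply(fields, `[`, "", 4L)
  if (all(nf >= 6L)) {
    str <- vapply(fields, `[`, "", 6L)
    str[!str %in% c("+", "-")] <- "*"
    GenomicRanges::strand(gr) <- str
  }
  AnnotationTrack(name, gr)
}

#' Overlaps between a track and variants
#'
#' Strand-agnostic overlap between variant footprints and track intervals;
#' results equal a brute-force linear scan. Variants with no overlap simply
#' contribute no rows.
#'
#' @param track an [AnnotationTrack-class].
#' @param v variant `GRanges` (one or more variants).
#' @return data.frame with one row per (variant, interval) overlap:
#'   `variant` (row index into `v`), `interval` (index into the track),
#'   `chrom`, `start`, `end` of the interval, and `overlap_length` in bp
#'   (always >= 1).
#' @export
overlapsTrack <- function(track, v) {
  tr <- track@ranges
  hits <- .quiet_seqlevels(
    GenomicRanges::findOverlaps(v, tr, ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- .quiet_seqlevels(GenomicRanges::width(GenomicRanges::pintersect(
    v[qi], tr[si], ignore.strand = TRUE)))
  data.frame(variant = qi, interval = si,
             chrom = as.character(GenomicRanges::seqnames(tr))[si],
             start = GenomicRanges::start(tr)[si],
             end = GenomicRanges::end(tr)[si],
             overlap_length = ov, stringsAsFactors = FALSE)
}

#' Read a per-locus subpopulation frequency table
#'
#' Expects one row per locus with columns `chrom, pos`, then `p_<pop>` and
#' `n_<pop>` for each population label. Sample sizes must be constant per
#' population across loci.
#'
#' @param path TSV file.
#' @return a [PopulationFrequencyTable-class].
#' @export
readFrequencyTable <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  pcols <- grep("^p_", colnames(df), value = TRUE)
  ncols <- grep("^n_", colnames(df), value = TRUE)
  pops <- sub("^p_", "", pcols)
  if (!length(pops) || !setequal(pops, sub("^n_", "", ncols)))
    stop("frequency table must have matching p_<pop> and n_<pop> columns: ", path)
  ncols <- paste0("n_", pops)
  n <- vapply(df[ncols], function(x) as.integer(x[1L]), 1L)
  p <- as.matrix(df[pcols]); colnames(p) <- pops
  PopulationFrequencyTable(p, n, pops, chrom = df$chrom, pos = df$pos)
}

#' Write a frequency table as TSV
#'
#' @param t a `PopulationFrequencyTable` carrying per-locus coordinates.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFrequencyTable <- function(t, path) {
  df <- data.frame(chrom = t@chrom, pos = t@pos, check.names = FALSE)
  for (i in seq_along(t@populations)) df[[paste0("p_", t@populations[i])]] <- t@p[, i]
  for (i in seq_along(t@populations)) df[[paste0("n_", t@populations[i])]] <- t@n[i]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a conservation score track (TSV: chrom, pos, score)
#'
#' @param path TSV file with header `chrom, pos, score`.
#' @param name score name; defaults to the file base name.
#' @return a [ConservationTrack-class].
#' @export
readConservation <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  if (!all(c("chrom", "pos", "score") %in% colnames(df)))
    stop("conservation file must have columns chrom, pos, score: ", path)
  ConservationTrack(name, df$chrom, df$pos, df$score)
}

#' Write a conservation track as TSV
#' @param track a `ConservationTrack`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeConservation <- function(track, path) {
  utils::write.table(
    data.frame(chrom = track@chrom, pos = track@pos, score = track@score),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file (pathway, description, genes..., tab-separated).
#' @param source provenance tag stored on the database.
#' @return a [PathwayDB-class].
#' @export
readGmt <- function(path, source = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t")
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad)) stop("malformed GMT at line ", bad[1L], " of ", path)
  pw <- lapply(fields, function(f) f[-(1:2)])
  names(pw) <- vapply(fields, `[`, "", 1L)
  PathwayDB(pw, source = source)
}

#' Write gene sets in GMT format
#' @param db a `PathwayDB`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(db, path) {
  lines <- vapply(names(db@pathways), function(nm)
    paste(c(nm, db@source, db@pathways[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene-disease occurrence counts (TSV: gene, count)
#'
#' @param path two-column TSV with header `gene, count`.
#' @return named numeric vector of per-gene occurrence counts `s_i`.
#' @export
readDiseaseCounts <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  if (!all(c("gene", "count") %in% colnames(df)))
    stop("disease count file must have columns gene, count: ", path)
  stats::setNames(as.numeric(df$count), as.character(df$gene))
}

#' Read a combined gene element map
#'
#' One row per element with BED-style 0-based half-open coordinates and
#' columns `chrom, start, end, gene, type` (tab-separated, with header).
#'
#' @param path TSV file.
#' @return a [GeneElementMap-class].
#' @export
readGeneElementMap <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  req <- c("chrom", "start", "end", "gene", "type")
  if (!all(req %in% colnames(df)))
    stop("gene element map must have columns chrom, start, end, gene, type: ", path)
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop("invalid element interval at line ", bad[1L] + 1L, " of ", path)
  GeneElementMap(df$chrom, df$start + 1L, df$end, df$gene, df$type)
}

#' Write a gene element map (0-based half-open, with header)
#' @param gmap a `GeneElementMap`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeneElementMap <- function(gmap, path) {
  el <- gmap@elements
  utils::write.table(
    data.frame(chrom = as.character(GenomicRanges::seqnames(el)),
               start = GenomicRanges::start(el) - 1L,
               end = GenomicRanges::end(el),
               gene = S4Vectors::mcols(el)$gene,
               type = S4Vectors::mcols(el)$type),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
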