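# Shared fixture builders.

toy_path <- function(f) {
  system.file("extdata", "toy", f, package = "pafar", mustWork = TRUE)
}

toy_curation_config <- function(m = 20L, seed = 42L, ...) {
  modifyList(list(
    pathogenic = toy_path("pathogenic.tsv"),
    benign = toy_path("benign.tsv"),
    gwas = toy_path("gwas.tsv"),
    kg = toy_path("kg.tsv"),
    tracks = list(enh = toy_path("elements.bed")),
    conservation = list(toy_path("cons.tsv")),
    freq = toy_path("freq.tsv"),
    m = m, seed = seed), list(...))
}

random_freq_table <- function(s, nloci = 1L, nmax = 200L) {
  PopulationFrequencyTable(
    matrix(runif(nloci * s), nloci, s),
    sample(2:nmax, s, replace = TRUE),
    paste0("pop", seq_len(s)))
}

write_tsv_variants <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

simple_track <- function(name, chrom, start, end) {
  AnnotationTrack(name, GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start, end)))
}
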