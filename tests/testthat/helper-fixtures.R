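# Shared fixtures, built in code at test time.

test_genome <- function() {
  # two autosomes + one sex chromosome with round numbers for hand arithmetic
  genome_build(data.frame(
    chrom = c("chr1", "chr2", "chrX"),
    length = c(200e6, 100e6, 150e6),
    cen_start = c(90e6, 45e6, 60e6),
    cen_end = c(110e6, 55e6, 70e6),
    is_autosome = c(TRUE, TRUE, FALSE)))
}

bundled_genome <- function() {
  read_genome_build(system.file("extdata", "genome_grch37.tsv",
                                package = "lmsproteo"))
}

# one-sample profile from a compact spec: list of c(start, end, major, minor)
make_profile <- function(..., chrom = "chr1", sample = "s1") {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(sample = sample, chrom = chrom, start = r[1], end = r[2],
               total_cn = r[3] + r[4], major_cn = r[3], minor_cn = r[4])
  }))
  segment_profiles(df)
}

# fully diploid profile over a genome
diploid_profile <- function(genome, sample = "s1") {
  segment_profiles(data.frame(
    sample = sample, chrom = genome$chrom, start = 0, end = genome$length,
    total_cn = 2L, major_cn = 1L, minor_cn = 1L))
}

# random valid segment profile for property tests
random_profile <- function(genome, seed, sample = "s1", max_breaks = 8) {
  set.seed(seed)
  rows <- lapply(seq_len(nrow(genome)), function(ci) {
    len <- genome$length[ci]
    nb <- sample(0:max_breaks, 1)
    cuts <- sort(unique(c(0, len, sample.int(len - 1, nb))))
    minor <- sample(0:2, length(cuts) - 1, replace = TRUE)
    major <- minor + sample(0:2, length(cuts) - 1, replace = TRUE)
    data.frame(sample = sample, chrom = genome$chrom[ci],
               start = cuts[-length(cuts)], end = cuts[-1],
               total_cn = major + minor, major_cn = major, minor_cn = minor)
  })
  segment_profiles(do.call(rbind, rows))
}

small_matrix <- function(values, scale_tag = "log2", kind = "protein") {
  omics_matrix(values, scale_tag, kind)
}

# small cohort for fast end-to-end tests; ... overrides any default
small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_samples = 24, samples_per_plex = 9, n_proteins = 300,
         n_phosphosites = 200, n_mrna = 300, signature_size = 25,
         cis_gene_count = 30, kinase_count = 6, substrates_per_kinase = 8,
         seed = seed),
    list(...))
  do.call(simulation_config, args)
}
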