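# Shared fixtures, all built in code at test time.

suppressMessages({
  library(dplyr)
  library(tibble)
})

# a 40-bp genome with known trinucleotide content plus a mitochondrial contig
tiny_genome <- function() {
  uv_genome(
    c(chrT = "ACGTACGTCCCCAATTGGCCAACGGTTACGTACGTTAGCA",
      chrM = "ACGTACGTACGTACGTACGT"),
    excluded_contigs = "chrM", ploidy = 2
  )
}

tiny_genes <- function() {
  tibble(
    gene_id = c("g1", "g2"),
    contig = "chrT",
    start = c(2L, 22L),
    end = c(14L, 34L),
    strand = c("+", "-")
  )
}

make_variant <- function(contig = "chrT", pos, ref, alt, depth = 50,
                         af = 0.5, isolate_id = "iso1", strain_id = "No PL",
                         replicate_id = "rep1",
                         type = if (nchar(ref) == 1) "snv" else "mnv2") {
  tibble(contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
         depth = depth, af = af, isolate_id = isolate_id,
         strain_id = strain_id, replicate_id = replicate_id, type = type)
}

# write a minimal single-sample VCF for read_variants()
write_test_vcf <- function(df, path, sample = "iso1") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrT,length=1000>",
    "##contig=<ID=chrM,length=1000>",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"depth\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"allele fraction\">",
    paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", sample), collapse = "\t")))
  body <- paste(df$contig, df$pos1, ".", df$ref, df$alt, ".", "PASS", ".",
                "DP:AF", paste0(df$depth, ":", df$af), sep = "\t")
  writeLines(c(header, body), path)
  path
}

# log-linear synthetic gel ladder over the HindIII-lambda band sizes
test_ladder <- function() {
  sizes <- lambda_hindiii_sizes()
  tibble(size_bp = sizes, migration = 150 - 30 * log10(sizes))
}

test_calibration <- function() calibrate_ladder(test_ladder())

# small simulated cohort reused across tests (memoised per session)
.shared_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(genome_length_bp = 4e4, n_genes = 25,
                               n_isolates = 4, n_replicates = 2)
      gg <- generate_genome(cfg, seed = 11)
      coh <- simulate_cohort(cfg, gg$genome, gg$genes, seed = 12)
      cache <<- list(config = cfg, genome = gg$genome, genes = gg$genes,
                     cohort = coh)
    }
    cache
  }
})
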