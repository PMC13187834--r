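# VCF input, site filters, recurrence filter and doublet merging.

test_that("read_variants classifies SNVs, doublet candidates and indels", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  df <- tibble(contig = "chrT", pos1 = c(10, 20, 30, 40),
               ref = c("C", "AC", "A", "ACG"),
               alt = c("T", "TT", "AT", "A"),
               depth = c(15, 20, 30, 40),
               af = c(0.5, 0.6, 0.5, 0.5))
  write_test_vcf(df, vcf)
  v <- read_variants(vcf, isolate_id = "iso1", strain_id = "s", replicate_id = "r")
  expect_equal(nrow(v), 4)
  expect_equal(v$type, c("snv", "mnv2", "other", "other"))
  expect_equal(v$pos, c(9L, 19L, 29L, 39L))  # converted to 0-based
  expect_equal(v$depth[1], 15)
  expect_equal(v$af[1], 0.5)
})

test_that("read_variants errors when depth or allele fraction is missing", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chrT\t10\t.\tC\tT\t.\tPASS\t."), vcf)
  expect_error(read_variants(vcf, "iso1"), "DP")
})

test_that("site filters are inclusive at their boundaries and audit reconciles", {
  cfg <- filter_config(excluded_contigs = "chrM")
  v <- bind_rows(
    make_variant(pos = 10, ref = "C", alt = "T", depth = 9, af = 0.5),    # depth
    make_variant(pos = 11, ref = "C", alt = "T", depth = 10, af = 0.45),  # kept
    make_variant(pos = 12, ref = "C", alt = "T", depth = 50, af = 0.449), # af
    make_variant(pos = 13, ref = "C", alt = "T", depth = 50, af = 0.45),  # kept
    make_variant(contig = "chrM", pos = 5, ref = "A", alt = "G",
                 depth = 100, af = 1.0)                                   # contig
  )
  res <- apply_site_filters(v, cfg)
  expect_equal(nrow(res$variants), 2)
  expect_equal(res$variants$pos, c(11L, 13L))
  expect_equal(sum(res$audit$n), nrow(v))
  expect_equal(res$audit$n[res$audit$rule == "depth"], 1L)
  expect_equal(res$audit$n[res$audit$rule == "allele_fraction"], 1L)
  expect_equal(res$audit$n[res$audit$rule == "excluded_contig"], 1L)
})

test_that("recurrence filter pools strains within a replicate and keys on identity", {
  mk <- function(iso, strain, rep, pos = 100) {
    make_variant(pos = pos, ref = "C", alt = "T", isolate_id = iso,
                 strain_id = strain, replicate_id = rep)
  }
  # same SNV in 3 isolates (2 strains) of rep1 -> all removed
  v3 <- bind_rows(mk("a", "s1", "rep1"), mk("b", "s1", "rep1"),
                  mk("c", "s2", "rep1"))
  r3 <- apply_recurrence_filter(v3)
  expect_equal(nrow(r3$variants), 0)
  expect_equal(r3$audit$n[r3$audit$rule == "recurrence"], 3L)
  # two isolates: boundary case, kept
  v2 <- bind_rows(mk("a", "s1", "rep1"), mk("b", "s1", "rep1"))
  expect_equal(nrow(apply_recurrence_filter(v2)$variants), 2)
  # 2 + 2 split over two replicates: kept (per-replicate grouping)
  v22 <- bind_rows(mk("a", "s1", "rep1"), mk("b", "s1", "rep1"),
                   mk("c", "s1", "rep2"), mk("d", "s1", "rep2"))
  expect_equal(nrow(apply_recurrence_filter(v22)$variants), 4)
  # a different alt at the same position is a different identity key
  vmix <- bind_rows(mk("a", "s1", "rep1"), mk("b", "s1", "rep1"),
                    make_variant(pos = 100, ref = "C", alt = "G",
                                 isolate_id = "c", replicate_id = "rep1"))
  expect_equal(nrow(apply_recurrence_filter(vmix)$variants), 3)
})

test_that("the filtering cascade is idempotent and site filters are order-free", {
  coh <- .shared_cohort()
  v <- coh$cohort$variants
  cfg <- filter_config(excluded_contigs = "chrM")
  once <- apply_recurrence_filter(apply_site_filters(v, cfg)$variants,
                                  cfg$max_recurrence)$variants
  twice <- apply_recurrence_filter(apply_site_filters(once, cfg)$variants,
                                   cfg$max_recurrence)$variants
  expect_equal(once, twice)
  # the per-site predicates themselves are order-independent
  split_cfgs <- list(
    filter_config(min_allele_fraction = 0, excluded_contigs = character()),
    filter_config(min_depth = 0, excluded_contigs = character()),
    filter_config(min_depth = 0, min_allele_fraction = 0,
                  excluded_contigs = "chrM"))
  for (perm in list(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1))) {
    out <- v
    for (k in perm) out <- apply_site_filters(out, split_cfgs[[k]])$variants
    expect_equal(arrange(out, contig, pos, isolate_id),
                 arrange(apply_site_filters(v, cfg)$variants,
                         contig, pos, isolate_id))
  }
})

test_that("adjacent SNVs merge into doublets, runs of three are set aside", {
  v <- bind_rows(
    make_variant(pos = 100, ref = "C", alt = "T"),
    make_variant(pos = 101, ref = "C", alt = "T"),
    make_variant(pos = 200, ref = "T", alt = "A"),            # lone SNV
    make_variant(pos = 300, ref = "C", alt = "T"),
    make_variant(pos = 301, ref = "C", alt = "A"),
    make_variant(pos = 302, ref = "T", alt = "G")             # run of 3
  )
  res <- call_doublets(v)
  expect_equal(nrow(res$dbs), 1)
  expect_equal(res$dbs$ref_dinuc, "CC")
  expect_equal(res$dbs$alt_dinuc, "TT")
  expect_equal(res$dbs$pos, 100L)
  expect_equal(res$snvs$pos, 200L)
  expect_equal(res$audit$n[res$audit$rule == "multi_nucleotide_event_bases"], 3L)
  # conservation: 2 x DBS + SNVs + MNE bases = input SNVs
  expect_equal(2 * nrow(res$dbs) + nrow(res$snvs) + 3L, nrow(v))
})

test_that("doublet merging does not cross isolates and passes caller MNVs through", {
  v <- bind_rows(
    make_variant(pos = 100, ref = "C", alt = "T", isolate_id = "a"),
    make_variant(pos = 101, ref = "C", alt = "T", isolate_id = "b"),
    make_variant(pos = 500, ref = "GT", alt = "AA", isolate_id = "a")
  )
  res <- call_doublets(v)
  expect_equal(nrow(res$snvs), 2)           # adjacent but different isolates
  expect_equal(nrow(res$dbs), 1)            # the caller MNV
  expect_equal(res$dbs$ref_dinuc, "GT")
})

test_that("audit conservation holds on a simulated cohort", {
  coh <- .shared_cohort()
  v <- coh$cohort$variants
  filt <- filter_variants(v, filter_config(excluded_contigs = "chrM"))
  removed <- sum(filt$audit$n[filt$audit$rule %in%
                                c("depth", "allele_fraction", "excluded_contig",
                                  "recurrence", "other_excluded")])
  counted <- filt$audit$n[filt$audit$rule == "snv"] +
    2 * filt$audit$n[filt$audit$rule == "dbs"] -
    filt$audit$n[filt$audit$rule == "caller_mnv2"] +
    filt$audit$n[filt$audit$rule == "multi_nucleotide_event_bases"]
  expect_equal(removed + counted, nrow(v))
})
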