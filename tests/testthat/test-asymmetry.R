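# Transcriptional strand assignment, normalized NTS/TS ratios, the
# chi-squared test and the reverse-asymmetry (atypical photoproduct) logic.

test_that("strand assignment follows the pyrimidine-bearing strand", {
  genes <- tibble(gene_id = "g", contig = "c1", start = 0L, end = 9L,
                  strand = "+")
  g <- uv_genome(c(c1 = "AAACGTAAA"))
  # C>T reported on + inside a + gene: pyrimidine strand == coding -> NTS
  v1 <- annotate_sbs(make_variant(contig = "c1", pos = 3, ref = "C", alt = "T"), g)
  expect_equal(assign_transcriptional_strand(v1, genes)$tx_strand, "NTS")
  # G>A reported on + (pyrimidine on -) inside a + gene -> TS
  v2 <- annotate_sbs(make_variant(contig = "c1", pos = 4, ref = "G", alt = "A"), g)
  expect_equal(assign_transcriptional_strand(v2, genes)$tx_strand, "TS")
  # outside all genes -> intergenic
  genes_short <- mutate(genes, end = 2L)
  expect_equal(assign_transcriptional_strand(v1, genes_short)$tx_strand,
               "intergenic")
  # opposite-strand overlapping genes -> ambiguous
  genes2 <- bind_rows(genes, mutate(genes, gene_id = "h", strand = "-"))
  expect_equal(assign_transcriptional_strand(v1, genes2)$tx_strand, "ambiguous")
})

test_that("chi-squared rows follow the closed-form 1-df statistic", {
  # equal abundances, 90 vs 10: chi2 = 40^2/50 + 40^2/50 = 64
  chi <- uvspectra:::chisq_1df(90, 10, 1, 1)
  expect_equal(chi$stat, 64)
  expect_equal(chi$p, pchisq(64, 1, lower.tail = FALSE))
  expect_lt(chi$p, 1.3e-15)
  # equal split: statistic 0, p 1
  chi0 <- uvspectra:::chisq_1df(50, 50, 1, 1)
  expect_equal(chi0$stat, 0)
  expect_equal(chi0$p, 1)
  # independent oracle on random rows (chisq.test with matching expecteds)
  set.seed(121)
  for (i in 1:20) {
    n <- sample(50:500, 2)
    a <- runif(2, 0.5, 2)
    mine <- uvspectra:::chisq_1df(n[1], n[2], a[1], a[2])
    ref <- suppressWarnings(
      chisq.test(n, p = a / sum(a), correct = FALSE))
    expect_equal(mine$stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("normalized ratios and Bonferroni behave on a constructed table", {
  # TCATGA is its own reverse complement when repeated, so the TCA context
  # is equally abundant on both strands of this + gene
  g <- uv_genome(c(c1 = strrep("TCATGA", 200)))
  genes <- tibble(gene_id = "g", contig = "c1", start = 0L, end = 1200L,
                  strand = "+")
  # NTS hits: C>T at the C of TCA (pyrimidine on the coding strand)
  nts <- purrr::map(seq(1L, by = 6L, length.out = 90), function(p) {
    make_variant(contig = "c1", pos = p, ref = "C", alt = "T")
  }) %>% bind_rows()
  # TS hits: G>A at the G of TGA (the same C>T-in-TCA class on the - strand)
  ts <- purrr::map(seq(4L, by = 6L, length.out = 30), function(p) {
    make_variant(contig = "c1", pos = p, ref = "G", alt = "A")
  }) %>% bind_rows()
  ann <- assign_transcriptional_strand(annotate_sbs(bind_rows(nts, ts), g), genes)
  expect_equal(sum(ann$tx_strand == "NTS"), 90)
  expect_equal(sum(ann$tx_strand == "TS"), 30)
  tab <- asymmetry_table(ann, genes, g, min_total_mutations = 50)
  expect_equal(nrow(tab), 1)
  row <- tab[tab$class_label == "T[C>T]A", ]
  expect_equal(row$n_nts, 90)
  expect_equal(row$n_ts, 30)
  expect_equal(row$a_nts, row$a_ts)     # palindromic repeat
  expect_equal(row$normalized_ratio, 3)
  chi <- uvspectra:::chisq_1df(90, 30, row$a_nts, row$a_ts)
  expect_equal(row$chi2_stat, chi$stat)
  # Bonferroni divisor is the number of tested rows
  expect_equal(row$p_bonferroni, min(1, row$chi2_p * nrow(tab)))
  expect_true(row$significant_after_bonferroni)
  expect_false(row$reverse_asymmetric)
})

test_that("swapping every gene strand swaps NTS and TS exactly", {
  coh <- .shared_cohort()
  filt <- filter_variants(coh$cohort$variants,
                          filter_config(excluded_contigs = "chrM"))
  ann <- annotate_sbs(filt$snvs, coh$genome)
  genes <- coh$genes
  genes_sw <- mutate(genes, strand = ifelse(strand == "+", "-", "+"))
  t1 <- asymmetry_table(assign_transcriptional_strand(ann, genes),
                        genes, coh$genome, min_total_mutations = 10)
  t2 <- asymmetry_table(assign_transcriptional_strand(ann, genes_sw),
                        genes_sw, coh$genome, min_total_mutations = 10)
  j <- inner_join(t1, t2, by = "class_label", suffix = c("", "_sw"))
  expect_gt(nrow(j), 0)
  expect_equal(j$n_nts, j$n_ts_sw)
  expect_equal(j$n_ts, j$n_nts_sw)
  expect_equal(j$a_nts, j$a_ts_sw)
  # ratios invert where defined on both sides (a zero TS count makes the
  # ratio undefined in one orientation and zero in the other)
  ok <- !j$undefined_ratio & !j$undefined_ratio_sw
  expect_gt(sum(ok), 0)
  expect_equal(j$normalized_ratio[ok], 1 / j$normalized_ratio_sw[ok])
})

test_that("adding tested classes never rescues significance (Bonferroni monotone)", {
  set.seed(122)
  p_raw <- runif(8, 0, 0.2)
  few <- pmin(1, p_raw[1:3] * 3) < 0.05
  many <- pmin(1, p_raw * 8)[1:3] < 0.05
  expect_true(all(many <= few))
})

test_that("reverse-asymmetric classes are re-expressed on the complementary strand", {
  rows <- tibble(class_label = c("T[T>A]A", "A[T>C]T"),
                 n_nts = c(10L, 200L), n_ts = c(90L, 100L),
                 a_nts = 1, a_ts = 1,
                 normalized_ratio = c(0.3, 2),
                 chi2_stat = c(64, 33), chi2_p = c(1e-15, 1e-8),
                 p_bonferroni = c(2e-15, 2e-8),
                 significant_after_bonferroni = TRUE,
                 reverse_asymmetric = c(TRUE, FALSE),
                 undefined_ratio = FALSE, n_tested = 2L)
  rep <- reverse_asymmetry_report(rows)
  expect_equal(nrow(rep), 1)
  expect_equal(rep$complementary_class, "T[A>T]A")
  # no reverse-asymmetric rows: empty report
  rows$reverse_asymmetric <- FALSE
  expect_equal(nrow(reverse_asymmetry_report(rows)), 0)
})

test_that("a transcription-suppressed channel yields the configured NTS/TS ratio", {
  # CPD channel only, TS suppression 10, dense genes
  cfg <- simulation_config(
    genome_length_bp = 1.2e5, n_genes = 80, gene_length_range = c(800, 1400),
    channels = list(CPD = channel_spec(
      "CPD", targets = c("TT", "TC", "CT", "CC"), rate = 8e-4,
      outcomes = bind_rows(
        tibble(target = "TC", kind = "sbs", position = 2L, alt = "T", prob = 1),
        tibble(target = "CC", kind = "sbs", position = 2L, alt = "T", prob = 1),
        tibble(target = "CT", kind = "sbs", position = 1L, alt = "T", prob = 1),
        tibble(target = "TT", kind = "sbs", position = 2L, alt = "A", prob = 1)),
      ts_suppression = 10)),
    strains = list(strain_spec("No PL")),
    n_isolates = 12, n_replicates = 1,
    recurrent_contaminants = 0, mito_variant_rate = 0)
  gg <- generate_genome(cfg, seed = 41)
  coh <- simulate_cohort(cfg, gg$genome, gg$genes, seed = 42)
  filt <- filter_variants(coh$variants, filter_config(excluded_contigs = "chrM"))
  ann <- assign_transcriptional_strand(annotate_sbs(filt$snvs, gg$genome),
                                       gg$genes)
  in_genes <- sum(ann$tx_strand %in% c("NTS", "TS"))
  expect_gt(in_genes, 2000)
  tab <- asymmetry_table(ann, gg$genes, gg$genome, min_total_mutations = 50)
  pooled <- (sum(tab$n_nts) / sum(tab$a_nts)) / (sum(tab$n_ts) / sum(tab$a_ts))
  expect_lt(abs(pooled - 10) / 10, 0.15)
})
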