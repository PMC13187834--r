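# Fold reductions, quadrant classification, replicate concordance and the
# mutagenic-potential arithmetic.

spectrum_from_counts <- function(count_list, class_label = "A[C>A]A",
                                 strain = "s", replicate = "r") {
  labels <- sbs_classes()$class_label
  counts <- tidyr::crossing(
    tibble(isolate_id = names(count_list), strain_id = strain,
           replicate_id = replicate),
    class_label = labels) %>%
    mutate(count = 0L)
  v <- unlist(count_list)
  idx <- counts$class_label == class_label
  counts$count[idx] <- v[match(counts$isolate_id[idx], names(count_list))]
  uvspectra:::new_uv_spectrum(counts, "SBS96", labels,
                              uvspectra:::audit_tibble("countable", sum(v)))
}

test_that("fold reduction handles constant and identical groups", {
  ctl <- spectrum_from_counts(list(a = 6L, b = 6L, c = 6L))
  trt <- spectrum_from_counts(list(d = 3L, e = 3L, f = 3L))
  ft <- fold_reduction_table(ctl, trt, min_total_mutations = 10)
  expect_equal(nrow(ft), 1)
  expect_equal(ft$fold_reduction, 2.0)
  expect_true(ft$degenerate)
  expect_equal(ft$welch_p, 0)   # constant unequal groups
  ft2 <- fold_reduction_table(ctl, ctl, min_total_mutations = 10)
  expect_equal(ft2$fold_reduction, 1.0)
  expect_equal(ft2$welch_p, 1)
  # treated mean of zero reports an infinite fold
  zero <- spectrum_from_counts(list(d = 0L, e = 0L, f = 0L))
  ft3 <- fold_reduction_table(ctl, zero, min_total_mutations = 10)
  expect_true(is.infinite(ft3$fold_reduction))
  expect_equal(ft3$mean_control, 6)
})

test_that("fold estimate and Welch p are recovered on Poisson groups", {
  set.seed(111)
  x <- rpois(20, 10); y <- rpois(20, 5)
  ctl <- spectrum_from_counts(setNames(as.list(x), paste0("c", 1:20)))
  trt <- spectrum_from_counts(setNames(as.list(y), paste0("t", 1:20)))
  ft <- fold_reduction_table(ctl, trt, min_total_mutations = 10)
  # fold within 3 SE of 2.0 (delta method on the ratio)
  se_ratio <- 2 * sqrt(10 / 20 / 100 + 5 / 20 / 25)
  expect_lt(abs(ft$fold_reduction - 2), 3 * se_ratio)
  ref <- t.test(x, y)
  expect_equal(ft$welch_p, ref$p.value, tolerance = 1e-10)
  expect_equal(ft$welch_t, unname(ref$statistic), tolerance = 1e-10)
})

test_that("fold table respects the control-count reporting threshold", {
  ctl <- spectrum_from_counts(list(a = 30L, b = 35L))
  trt <- spectrum_from_counts(list(c = 10L, d = 12L))
  expect_equal(nrow(fold_reduction_table(ctl, trt, min_total_mutations = 70)), 0)
  expect_equal(nrow(fold_reduction_table(ctl, trt, min_total_mutations = 65)), 1)
})

test_that("photoproduct quadrant classification partitions the fold plane", {
  expect_equal(classify_photoproduct(19, 1.2)$label, "CPD-dominant")
  expect_equal(classify_photoproduct(1.2, 19)$label, "6-4PP-dominant")
  expect_equal(classify_photoproduct(1.3, 1.4)$label, "atypical")
  expect_equal(classify_photoproduct(3, 3)$label, "mixed")
  # every point gets exactly one label, including boundaries and infinities
  grid <- expand.grid(f1 = c(0, 0.5, 1, 2, 2.5, 19, Inf),
                      f2 = c(0, 0.5, 1, 2, 2.5, 19, Inf))
  lab <- classify_photoproduct(grid$f1, grid$f2)$label
  expect_true(all(lab %in% c("CPD-dominant", "6-4PP-dominant", "mixed", "atypical")))
  expect_false(any(is.na(lab)))
})

test_that("replicate concordance uses the exact Mann-Whitney distribution", {
  mk_iso <- function(tot, rep) {
    setNames(as.list(as.integer(tot)), paste0(rep, "_", seq_along(tot)))
  }
  sp1 <- spectrum_from_counts(mk_iso(c(1, 2, 3), "r1"), replicate = "rep1")
  sp2 <- spectrum_from_counts(mk_iso(c(10, 11, 12), "r2"), replicate = "rep2")
  sp <- uvspectra:::new_uv_spectrum(bind_rows(sp1$counts, sp2$counts), "SBS96",
                                    sp1$class_labels, sp1$audit)
  res <- replicate_concordance(sp, "s")
  expect_equal(res$p_value, 0.1)
  # identical replicate totals: p = 1
  sp3 <- spectrum_from_counts(mk_iso(c(5, 6, 7), "r3"), replicate = "rep2")
  spi <- uvspectra:::new_uv_spectrum(
    bind_rows(spectrum_from_counts(mk_iso(c(5, 6, 7), "r4"),
                                   replicate = "rep1")$counts, sp3$counts),
    "SBS96", sp1$class_labels, sp1$audit)
  expect_equal(replicate_concordance(spi, "s")$p_value, 1)
  expect_error(replicate_concordance(sp1, "s"), "two replicates")
})

test_that("attribution reproduces the subtractive per-replicate-median arithmetic", {
  totals <- tibble(strain_id = rep(c("No PL", "CPD PL"), each = 2),
                   replicate_id = rep(c("rep1", "rep2"), 2),
                   median_total = c(652, 694, 264, 285))
  att <- attribute_mutation_counts(totals, "No PL", "CPD PL")
  expect_equal(att$control_mean_median, 673)
  expect_equal(att$treated_mean_median, 274.5)
  expect_equal(att$attributed_per_isolate, 398.5)
  # the photolyase strain against a zero baseline reads the non-CPD burden
  att2 <- attribute_mutation_counts(totals, "CPD PL")
  expect_equal(att2$attributed_per_isolate, 274.5)
  # identical strains attribute nothing
  expect_equal(
    attribute_mutation_counts(totals, "No PL", "No PL")$attributed_per_isolate, 0)
})

test_that("mutagenic potential combines lesion totals and attributed counts", {
  mp <- mutagenic_potential(398.5, 1.26, haploid_size_kb = 12070, ploidy = 2)
  expect_equal(mp$total_lesions, 1.26 * 12070 * 2 * 2)
  expect_equal(round(mp$total_lesions, -3), 61000)  # the ~60 000 CPD figure
  expect_equal(sprintf("%.2f", mp$percent_mutagenic), "0.66")
  mp2 <- mutagenic_potential(274.5, 0.26, haploid_size_kb = 12070, ploidy = 2)
  expect_equal(round(mp2$total_lesions), 12553)     # the ~12 500 figure
  expect_equal(round(mp2$percent_mutagenic, 1), 2.2)
  expect_equal(mutagenic_potential(0, 1, haploid_size_kb = 10,
                                   ploidy = 2)$percent_mutagenic, 0)
})

test_that("attribution is additive across independent lesion channels", {
  cfg <- simulation_config(genome_length_bp = 8e4, n_genes = 40,
                           n_isolates = 8, n_replicates = 1)
  gg <- generate_genome(cfg, seed = 31)
  coh <- simulate_cohort(cfg, gg$genome, gg$genes, seed = 32)
  filt <- filter_variants(coh$variants, filter_config(excluded_contigs = "chrM"))
  sp <- build_sbs_matrix(filt$snvs, gg$genome, isolates = coh$metadata)
  tot <- spectrum_totals(sp)
  m <- function(s) mean(tot$total[tot$strain_id == s])
  se2 <- function(s) {
    v <- tot$total[tot$strain_id == s]
    var(v) / length(v)
  }
  gap <- (m("No PL") - m("CPD PL")) + (m("No PL") - m("6-4PP PL")) -
    (m("No PL") - m("Both PL"))
  se_gap <- sqrt(se2("No PL") + se2("CPD PL") + se2("6-4PP PL") + se2("Both PL"))
  expect_lt(abs(gap), 3 * se_gap)
})
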