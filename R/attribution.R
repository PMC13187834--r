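# Photolyase-subtractive attribution: per-class fold reductions between a
# control strain (no photolyase) and a photolyase-expressing strain,
# quadrant classification of classes by their CPD / 6-4PP fold
# reductions, replicate concordance, and the mutagenic-potential
# arithmetic combining attributed mutations with lesion totals.

per_class_count_vectors <- function(spectrum) {
  spectrum$counts %>%
    group_by(.data$class_label) %>%
    summarise(counts = list(.data$count), .groups = "drop")
}

#' Per-class fold reduction between control and treated spectra
#'
#' For every mutation class, divides the mean mutations per isolate in
#' the control (no-photolyase) spectrum by the mean in the treated
#' (photolyase-expressing) spectrum, and tests the difference with
#' Welch's unpaired t-test (two-sided, no multiple-testing correction).
#' Classes with fewer than `min_total_mutations` cumulative control
#' mutations are omitted — figure-level analyses of this kind use
#' thresholds of 50, 70 or 100 depending on how rare the classes are.
#'
#' @param control,treated `uv_spectrum` objects built on the same class
#'   set (typically [filter_spectrum()] slices of one cohort spectrum).
#' @param min_total_mutations minimum cumulative control-count for a
#'   class to be reported.
#' @param p_threshold two-sided significance threshold for the
#'   `significant` flag (default 0.001, the three-star convention).
#' @return tibble with one row per reported class: `class_label`,
#'   `mean_control`, `mean_treated`, `fold_reduction` (Inf when the
#'   treated mean is 0 and the control mean positive, NA when both are
#'   0), `welch_t`, `welch_df`, `welch_p`, `significant`, `degenerate`,
#'   `n_control`, `n_treated`, `total_control_mutations`.
#' @export
fold_reduction_table <- function(control, treated, min_total_mutations = 70,
                                 p_threshold = 0.001) {
  if (!identical(control$class_labels, treated$class_labels)) {
    abort("control and treated spectra must share one class label set")
  }
  ctl <- per_class_count_vectors(control)
  trt <- per_class_count_vectors(treated)
  joined <- inner_join(ctl, trt, by = "class_label",
                       suffix = c("_control", "_treated"))
  rows <- pmap(joined, function(class_label, counts_control, counts_treated) {
    x <- counts_control; y <- counts_treated
    total_control <- sum(x)
    mx <- mean(x); my <- mean(y)
    fold <- if (my > 0) mx / my else if (mx > 0) Inf else NA_real_
    w <- welch_t_test(x, y)
    tibble(class_label = class_label,
           mean_control = mx, mean_treated = my,
           fold_reduction = fold,
           welch_t = w$statistic, welch_df = w$df, welch_p = w$p_value,
           degenerate = w$degenerate,
           n_control = length(x), n_treated = length(y),
           total_control_mutations = total_control)
  }) %>% list_rbind()
  rows %>%
    filter(.data$total_control_mutations >= min_total_mutations) %>%
    mutate(significant = !is.na(.data$welch_p) & .data$welch_p < p_threshold) %>%
    arrange(match(.data$class_label, control$class_labels))
}

#' Classify a mutation class by its photolyase fold reductions
#'
#' A class strongly reduced by CPD photolyase but not by 6-4PP photolyase
#' derives predominantly from CPDs; the converse from 6-4PPs; strong
#' reduction in both is a mixed origin; weak reduction in both points to
#' an atypical photoproduct resistant to both photolyases. The 2-fold
#' default thresholds are this package's operational choice for that
#' qualitative quadrant reading and are exposed as parameters.
#'
#' @param fold_cpd,fold_64pp fold reductions from the CPD-photolyase and
#'   6-4PP-photolyase comparisons (vectorised).
#' @param cpd_threshold,pp64_threshold fold thresholds (> 1).
#' @return tibble: `fold_cpd`, `fold_64pp`, `label` in
#'   `CPD-dominant`, `6-4PP-dominant`, `mixed`, `atypical`.
#' @export
classify_photoproduct <- function(fold_cpd, fold_64pp,
                                  cpd_threshold = 2, pp64_threshold = 2) {
  stopifnot(cpd_threshold > 1, pp64_threshold > 1)
  if (any(c(fold_cpd, fold_64pp) < 0, na.rm = TRUE)) {
    abort("fold reductions must be non-negative")
  }
  hi_cpd <- fold_cpd >= cpd_threshold
  hi_64 <- fold_64pp >= pp64_threshold
  label <- dplyr::case_when(
    hi_cpd & !hi_64 ~ "CPD-dominant",
    !hi_cpd & hi_64 ~ "6-4PP-dominant",
    hi_cpd & hi_64 ~ "mixed",
    TRUE ~ "atypical"
  )
  tibble(fold_cpd = fold_cpd, fold_64pp = fold_64pp, label = label,
         cpd_threshold = cpd_threshold, pp64_threshold = pp64_threshold)
}

#' Photoproduct calls for all classes shared by two fold tables
#'
#' @param fold_cpd_table,fold_64pp_table outputs of
#'   [fold_reduction_table()] for the CPD-photolyase and 6-4PP-photolyase
#'   comparisons against the same control.
#' @inheritParams classify_photoproduct
#' @return tibble with `class_label`, both folds and the quadrant `label`.
#' @export
photoproduct_calls <- function(fold_cpd_table, fold_64pp_table,
                               cpd_threshold = 2, pp64_threshold = 2) {
  joined <- inner_join(
    fold_cpd_table %>% select("class_label", fold_cpd = "fold_reduction"),
    fold_64pp_table %>% select("class_label", fold_64pp = "fold_reduction"),
    by = "class_label")
  bind_cols(joined["class_label"],
            classify_photoproduct(joined$fold_cpd, joined$fold_64pp,
                                  cpd_threshold, pp64_threshold))
}

#' Quadrant plot of fold reductions
#'
#' @param calls output of [photoproduct_calls()].
#' @return ggplot scatter of CPD fold (x) vs 6-4PP fold (y) with
#'   threshold guides, coloured by call.
#' @export
plot_fold_plane <- function(calls) {
  finite <- calls %>%
    mutate(fold_cpd = pmin(.data$fold_cpd, 100),
           fold_64pp = pmin(.data$fold_64pp, 100))
  ggplot2::ggplot(finite, ggplot2::aes(x = .data$fold_cpd, y = .data$fold_64pp,
                                       colour = .data$label)) +
    ggplot2::geom_hline(yintercept = finite$pp64_threshold[1], linetype = 2) +
    ggplot2::geom_vline(xintercept = finite$cpd_threshold[1], linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "fold decrease in CPD PL", y = "fold decrease in 6-4PP PL",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Compare per-isolate totals between the two replicates of a strain
#'
#' Two-sided Mann-Whitney U on per-isolate mutation totals; used to
#' justify aggregating the two passaging replicates.
#'
#' @param spectrum a `uv_spectrum`.
#' @param strain strain to test; it must have exactly two replicates,
#'   each with at least one isolate.
#' @return one-row tibble: `strain_id`, `n_rep1`, `n_rep2`, `statistic`,
#'   `p_value`, `method`.
#' @export
replicate_concordance <- function(spectrum, strain) {
  totals <- spectrum_totals(filter_spectrum(spectrum, strains = strain))
  reps <- sort(unique(totals$replicate_id))
  if (length(reps) != 2) {
    abort(paste0("strain ", strain, " must have exactly two replicates"))
  }
  x <- totals$total[totals$replicate_id == reps[1]]
  y <- totals$total[totals$replicate_id == reps[2]]
  if (length(x) == 0 || length(y) == 0) abort("a replicate has no isolates")
  mw <- mann_whitney_u(x, y)
  tibble(strain_id = strain, n_rep1 = length(x), n_rep2 = length(y),
         statistic = mw$statistic, p_value = mw$p_value, method = mw$method)
}

#' Mutations per isolate attributed to a lesion class
#'
#' Subtracts the treated strain's per-replicate median totals from the
#' control's: attributed = mean over replicates of control medians minus
#' mean over replicates of treated medians. With `treated = NULL` the
#' treated baseline is zero, which reads the control strain's own median
#' count as caused by the lesions it still accumulates (used for the
#' non-CPD photoproducts via the CPD-photolyase strain).
#'
#' @param totals per-group totals tibble with columns `strain_id`,
#'   `replicate_id`, `median_total` — e.g.
#'   `summarize_spectrum(x, by = "strain_replicate")$totals`.
#' @param control,treated strain identifiers.
#' @return one-row tibble: `control`, `treated`, `control_mean_median`,
#'   `treated_mean_median`, `attributed_per_isolate`.
#' @export
attribute_mutation_counts <- function(totals, control, treated = NULL) {
  med_of <- function(strain) {
    m <- totals$median_total[totals$strain_id == strain]
    if (length(m) == 0) abort(paste0("strain not in totals: ", strain))
    mean(m)
  }
  ctl <- med_of(control)
  trt <- if (is.null(treated)) 0 else med_of(treated)
  tibble(control = control,
         treated = treated %||% "(zero baseline)",
         control_mean_median = ctl,
         treated_mean_median = trt,
         attributed_per_isolate = ctl - trt)
}

#' Mutagenic potential of a photoproduct class
#'
#' Divides the mutations per isolate attributed to a lesion class by the
#' total number of such lesions formed per cell over the exposure
#' regimen: total lesions = lesions/kb x haploid genome size (kb) x
#' ploidy x 2 strands.
#'
#' @param attributed_mutations mutations per isolate attributed to the
#'   lesion class (>= 0).
#' @param lesions_per_kb net lesion frequency per kb per strand (from
#'   [lesion_frequency()]).
#' @param genome a [uv_genome()], or NULL if `haploid_size_kb` and
#'   `ploidy` are given directly.
#' @param haploid_size_kb,ploidy genome size per haploid complement in kb
#'   and ploidy, overriding `genome`.
#' @return one-row tibble: `attributed_mutations`, `lesions_per_kb`,
#'   `haploid_size_kb`, `ploidy`, `total_lesions`, `percent_mutagenic`.
#' @export
mutagenic_potential <- function(attributed_mutations, lesions_per_kb,
                                genome = NULL, haploid_size_kb = NULL,
                                ploidy = NULL) {
  if (!is.null(genome)) {
    haploid_size_kb <- haploid_size_kb %||% genome$haploid_size_kb
    ploidy <- ploidy %||% genome$ploidy
  }
  if (is.null(haploid_size_kb) || is.null(ploidy)) {
    abort("supply a genome or haploid_size_kb and ploidy")
  }
  stopifnot(attributed_mutations >= 0, lesions_per_kb >= 0,
            haploid_size_kb > 0, ploidy >= 1)
  total <- lesions_per_kb * haploid_size_kb * ploidy * 2
  tibble(attributed_mutations = attributed_mutations,
         lesions_per_kb = lesions_per_kb,
         haploid_size_kb = haploid_size_kb,
         ploidy = ploidy,
         total_lesions = total,
         percent_mutagenic = if (total > 0) 100 * attributed_mutations / total else 0)
}
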