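# Transcriptional strand asymmetry: assign each mutation's class-bearing
# strand to the non-transcribed (NTS, = coding) or transcribed (TS)
# strand of the gene containing it, normalize NTS/TS counts by
# strand-specific context abundance, and test each class with a 1-df
# chi-squared test under Bonferroni correction. Classes significantly
# enriched on the TS (normalized ratio < 1) are re-expressed on the
# complementary strand — the reading that exposes atypical photoproducts
# such as the thymine-adenine photoproduct (A>T in TAN).

#' Assign mutations to the NTS or TS of genes
#'
#' The strand carrying the canonical (pyrimidine-central SBS, or
#' canonical-reference DBS) representation of each mutation is compared
#' with the coding strand of the gene containing it: equal means NTS,
#' opposite means TS. Positions outside all genes are `intergenic`;
#' positions inside genes annotated on both strands are `ambiguous`
#' (NTS/TS undefined). Both are excluded from asymmetry statistics.
#'
#' @param annotated annotated mutation tibble from [annotate_sbs()] or
#'   [annotate_dbs()].
#' @param genes gene tibble (see [read_genes()]).
#' @return the input with a `tx_strand` column
#'   (`NTS`/`TS`/`intergenic`/`ambiguous`).
#' @export
assign_transcriptional_strand <- function(annotated, genes) {
  validate_genes(genes)
  flag_col <- if ("pyrimidine_on_reported_strand" %in% names(annotated)) {
    "pyrimidine_on_reported_strand"
  } else if ("kept_as_is" %in% names(annotated)) {
    "kept_as_is"
  } else {
    abort("annotate the mutations (annotate_sbs / annotate_dbs) first")
  }
  class_strand <- ifelse(annotated[[flag_col]], "+", "-")
  ivals <- strand_intervals(genes)
  in_plus <- logical(nrow(annotated))
  in_minus <- logical(nrow(annotated))
  for (ct in names(ivals)) {
    idx <- which(annotated$contig == ct)
    if (length(idx) == 0) next
    q <- IRanges::IRanges(start = annotated$pos[idx] + 1L, width = 1L)
    in_plus[idx] <- IRanges::overlapsAny(q, ivals[[ct]]$plus)
    in_minus[idx] <- IRanges::overlapsAny(q, ivals[[ct]]$minus)
  }
  gene_strand <- dplyr::case_when(
    in_plus & in_minus ~ "ambiguous",
    in_plus ~ "+",
    in_minus ~ "-",
    TRUE ~ "intergenic"
  )
  annotated$tx_strand <- dplyr::case_when(
    gene_strand == "ambiguous" ~ "ambiguous",
    gene_strand == "intergenic" ~ "intergenic",
    gene_strand == class_strand ~ "NTS",
    TRUE ~ "TS"
  )
  annotated
}

chisq_1df <- function(n_nts, n_ts, a_nts, a_ts) {
  total <- n_nts + n_ts
  e_nts <- total * a_nts / (a_nts + a_ts)
  e_ts <- total - e_nts
  stat <- (n_nts - e_nts)^2 / e_nts + (n_ts - e_ts)^2 / e_ts
  list(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Trinucleotide-normalized strand-asymmetry table
#'
#' For every mutation class with at least `min_total_mutations` NTS+TS
#' mutations: the observed NTS and TS counts, the strand-specific
#' abundance of the class's context across gene bodies, the normalized
#' ratio (n_nts/a_nts)/(n_ts/a_ts), and a 1-df chi-squared test of the
#' observed split against expected proportions a_nts : a_ts (or 50:50
#' with `expected = "equal"`, provided for sensitivity analysis).
#' Bonferroni divides by the number of classes tested in this call.
#'
#' @param annotated mutation tibble carrying `class_label`, `context`
#'   (SBS) and `tx_strand` (run [assign_transcriptional_strand()] first);
#'   DBS tables use the canonical reference dinucleotide as context.
#' @param genes gene tibble.
#' @param genome a [uv_genome()].
#' @param min_total_mutations minimum NTS+TS count for a class to be
#'   tested (default 50).
#' @param expected `"abundance"` (default) or `"equal"`.
#' @param p_threshold family-wise significance level before Bonferroni
#'   division (default 0.05; figure annotations additionally mark
#'   corrected p < 0.001).
#' @return tibble with one row per tested class: `class_label`, `n_nts`,
#'   `n_ts`, `a_nts`, `a_ts`, `normalized_ratio`, `chi2_stat`, `chi2_p`,
#'   `p_bonferroni`, `significant_after_bonferroni`,
#'   `reverse_asymmetric`, `undefined_ratio`, `n_tested`.
#' @export
asymmetry_table <- function(annotated, genes, genome, min_total_mutations = 50,
                            expected = c("abundance", "equal"),
                            p_threshold = 0.05) {
  expected <- match.arg(expected)
  if (!"tx_strand" %in% names(annotated)) {
    annotated <- assign_transcriptional_strand(annotated, genes)
  }
  is_dbs <- "kept_as_is" %in% names(annotated)
  width <- if (is_dbs) 2 else 3
  counts <- annotated %>%
    filter(.data$tx_strand %in% c("NTS", "TS"), .data$countable) %>%
    count(.data$class_label, .data$tx_strand) %>%
    pivot_wider(names_from = "tx_strand", values_from = "n", values_fill = 0)
  for (col in c("NTS", "TS")) if (!col %in% names(counts)) counts[[col]] <- 0L
  counts <- counts %>%
    rename(n_nts = "NTS", n_ts = "TS") %>%
    mutate(total = .data$n_nts + .data$n_ts) %>%
    filter(.data$total >= min_total_mutations)
  if (nrow(counts) == 0) {
    return(tibble(class_label = character(), n_nts = integer(),
                  n_ts = integer(), a_nts = numeric(), a_ts = numeric(),
                  normalized_ratio = numeric(), chi2_stat = numeric(),
                  chi2_p = numeric(), p_bonferroni = numeric(),
                  significant_after_bonferroni = logical(),
                  reverse_asymmetric = logical(), undefined_ratio = logical(),
                  n_tested = integer()))
  }
  cen_nts <- context_census(genome, genes, "gene_NTS", width = width)
  cen_ts <- context_census(genome, genes, "gene_TS", width = width)
  ctx_of <- function(lbl) {
    if (is_dbs) sub(">.*$", "", lbl) else {
      paste0(substr(lbl, 1, 1), substr(lbl, 3, 3), substr(lbl, 7, 7))
    }
  }
  counts <- counts %>%
    mutate(context = ctx_of(.data$class_label)) %>%
    left_join(rename(cen_nts, a_nts = "count"), by = "context") %>%
    left_join(rename(cen_ts, a_ts = "count"), by = "context")
  n_tested <- nrow(counts)
  e_nts <- if (expected == "abundance") counts$a_nts else rep(1, n_tested)
  e_ts <- if (expected == "abundance") counts$a_ts else rep(1, n_tested)
  chi <- chisq_1df(counts$n_nts, counts$n_ts, e_nts, e_ts)
  out <- counts %>%
    mutate(
      undefined_ratio = .data$n_ts == 0 | .data$a_nts == 0 | .data$a_ts == 0,
      normalized_ratio = ifelse(.data$undefined_ratio, NA_real_,
                                (.data$n_nts / .data$a_nts) /
                                  (.data$n_ts / .data$a_ts)),
      chi2_stat = chi$stat,
      chi2_p = chi$p,
      p_bonferroni = pmin(1, chi$p * n_tested),
      significant_after_bonferroni = .data$p_bonferroni < p_threshold,
      reverse_asymmetric = !is.na(.data$normalized_ratio) &
        .data$normalized_ratio < 1 & .data$significant_after_bonferroni,
      n_tested = n_tested
    ) %>%
    select("class_label", "n_nts", "n_ts", "a_nts", "a_ts",
           "normalized_ratio", "chi2_stat", "chi2_p", "p_bonferroni",
           "significant_after_bonferroni", "reverse_asymmetric",
           "undefined_ratio", "n_tested")
  out
}

complement_sbs_label <- function(class_label) {
  up <- substr(class_label, 1, 1)
  ref <- substr(class_label, 3, 3)
  alt <- substr(class_label, 5, 5)
  down <- substr(class_label, 7, 7)
  paste0(comp(down), "[", comp(ref), ">", comp(alt), "]", comp(up))
}

#' Report reverse-asymmetric classes on the complementary strand
#'
#' Classes significantly enriched on the TS (normalized ratio < 1)
#' indicate that the causative photoproduct sits on the opposite strand:
#' a T>A class in an NTA context re-expressed on the complementary strand
#' is an A>T mutation in a TAN context, the signature of the atypical
#' thymine-adenine photoproduct. DBS classes re-express as the
#' reverse-complement doublet change.
#'
#' @param rows output of [asymmetry_table()].
#' @return the reverse-asymmetric subset with `complementary_class`
#'   appended.
#' @export
reverse_asymmetry_report <- function(rows) {
  out <- filter(rows, .data$reverse_asymmetric)
  if (nrow(out) == 0) return(mutate(out, complementary_class = character(0)))
  is_dbs <- !grepl("\\[", out$class_label[1])
  out$complementary_class <- if (is_dbs) {
    ref <- sub(">.*$", "", out$class_label)
    alt <- sub("^.*>", "", out$class_label)
    paste0(revcomp(ref), ">", revcomp(alt))
  } else {
    complement_sbs_label(out$class_label)
  }
  out
}

#' Scatter plot of normalized NTS/TS ratio against total mutation count
#'
#' @param rows output of [asymmetry_table()] (SBS).
#' @return ggplot with dipyrimidine-context classes outlined.
#' @export
plot_asymmetry <- function(rows) {
  rows <- rows %>%
    mutate(total = .data$n_nts + .data$n_ts,
           substitution = str_sub(.data$class_label, 3, 5),
           context = paste0(substr(.data$class_label, 1, 1),
                            substr(.data$class_label, 3, 3),
                            substr(.data$class_label, 7, 7)),
           dipyrimidine = str_detect(.data$context, "[CT][CT]"))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$total,
                                     y = .data$normalized_ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$substitution,
                                     colour = .data$dipyrimidine),
                        shape = 21, size = 2, stroke = 0.7) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "black", `FALSE` = "grey70")) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "total mutations in class", y = "normalized NTS/TS ratio",
                  fill = NULL, colour = "dipyrimidine") +
    ggplot2::theme_minimal()
}
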