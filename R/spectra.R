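# Per-isolate SBS-96 and DBS spectrum matrices with mean/SEM summaries.

genome_base_at <- function(genome, contig, pos, width = 1L) {
  # pos is 0-based; returns NA outside the contig
  seqs <- genome$contigs
  out <- rep(NA_character_, length(pos))
  for (ct in unique(contig)) {
    idx <- which(contig == ct)
    s <- contig_seq(genome, ct)
    ok <- pos[idx] >= 0 & (pos[idx] + width) <= nchar(s)
    out[idx[ok]] <- substring(s, pos[idx][ok] + 1L, pos[idx][ok] + width)
  }
  out
}

#' Annotate SNVs with their pyrimidine-centric SBS class
#'
#' Looks up the trinucleotide context from the genome, verifies the
#' reference allele against the genome base (a mismatch is a hard error —
#' it signals a genome/VCF build mismatch), and collapses each change
#' onto its SBS-96 class. Records whose context contains N or falls off a
#' contig end are flagged `countable = FALSE`.
#'
#' @param snvs SNV tibble (see [read_variants()]).
#' @param genome a [uv_genome()].
#' @return the input with columns `substitution`, `context`,
#'   `class_label`, `pyrimidine_on_reported_strand`, `countable` appended.
#' @export
annotate_sbs <- function(snvs, genome) {
  if (nrow(snvs) == 0) {
    return(mutate(snvs, substitution = character(0), context = character(0),
                  class_label = character(0),
                  pyrimidine_on_reported_strand = logical(0),
                  countable = logical(0)))
  }
  gbase <- genome_base_at(genome, snvs$contig, snvs$pos)
  mism <- which(!is.na(gbase) & gbase != snvs$ref)
  if (length(mism)) {
    i <- mism[1]
    abort(paste0("reference mismatch at ", snvs$contig[i], ":", snvs$pos[i] + 1L,
                 " (VCF ref ", snvs$ref[i], ", genome ", gbase[i], ")"))
  }
  up <- genome_base_at(genome, snvs$contig, snvs$pos - 1L)
  down <- genome_base_at(genome, snvs$contig, snvs$pos + 1L)
  up[is.na(up)] <- "N"
  down[is.na(down)] <- "N"
  bind_cols(snvs, canonicalize_sbs(snvs$ref, snvs$alt, up, down))
}

#' Annotate doublet records with their canonical DBS class
#'
#' @param dbs doublet tibble (see [call_doublets()]).
#' @param genome a [uv_genome()]; reference dinucleotides are checked
#'   against it (mismatch is a hard error).
#' @return the input with `class_label` and `kept_as_is` appended (plus
#'   `countable`, always TRUE for valid doublets, kept for symmetry).
#' @export
annotate_dbs <- function(dbs, genome) {
  if (nrow(dbs) == 0) {
    return(mutate(dbs, class_label = character(0), kept_as_is = logical(0),
                  countable = logical(0)))
  }
  gd <- genome_base_at(genome, dbs$contig, dbs$pos, width = 2L)
  mism <- which(!is.na(gd) & gd != dbs$ref_dinuc)
  if (length(mism)) {
    i <- mism[1]
    abort(paste0("reference mismatch at ", dbs$contig[i], ":", dbs$pos[i] + 1L,
                 " (doublet ref ", dbs$ref_dinuc[i], ", genome ", gd[i], ")"))
  }
  canon <- canonicalize_dbs(dbs$ref_dinuc, dbs$alt_dinuc)
  bind_cols(dbs, tibble(class_label = canon$class_label,
                        kept_as_is = canon$kept_as_is,
                        countable = TRUE))
}

new_uv_spectrum <- function(counts, type, class_labels, audit) {
  structure(list(counts = counts, type = type, class_labels = class_labels,
                 audit = audit),
            class = "uv_spectrum")
}

spectrum_from_annotated <- function(annotated, type, class_labels, isolates) {
  if (is.null(isolates)) {
    isolates <- distinct(annotated[, c("isolate_id", "strain_id", "replicate_id")])
  }
  countable <- annotated %>% filter(.data$countable)
  counts <- countable %>%
    count(.data$isolate_id, .data$class_label, name = "count") %>%
    right_join(tidyr::crossing(isolates["isolate_id"],
                               class_label = class_labels),
               by = c("isolate_id", "class_label")) %>%
    mutate(count = ifelse(is.na(.data$count), 0L, .data$count)) %>%
    left_join(isolates, by = "isolate_id") %>%
    arrange(.data$isolate_id, match(.data$class_label, class_labels)) %>%
    select("isolate_id", "strain_id", "replicate_id", "class_label", "count")
  audit <- audit_tibble(c("countable", "uncountable_context"),
                        c(nrow(countable), sum(!annotated$countable)))
  new_uv_spectrum(counts, type, class_labels, audit)
}

#' Build the per-isolate SBS-96 spectrum matrix
#'
#' @inheritParams annotate_sbs
#' @param isolates optional tibble (`isolate_id`, `strain_id`,
#'   `replicate_id`) so isolates with zero surviving mutations still get a
#'   row of zeros; defaults to the isolates present in `snvs`.
#' @return a `uv_spectrum` object holding a long counts tibble
#'   (isolate x 96 classes), the class label set, and an audit of
#'   uncountable-context records.
#' @export
build_sbs_matrix <- function(snvs, genome, isolates = NULL) {
  ann <- annotate_sbs(snvs, genome)
  spectrum_from_annotated(ann, "SBS96", sbs_classes()$class_label, isolates)
}

#' Build the per-isolate DBS spectrum matrix
#'
#' @inheritParams annotate_dbs
#' @inheritParams build_sbs_matrix
#' @return a `uv_spectrum` object over the 78 canonical DBS classes.
#' @export
build_dbs_matrix <- function(dbs, genome, isolates = NULL) {
  ann <- annotate_dbs(dbs, genome)
  spectrum_from_annotated(ann, "DBS", dbs_classes()$class_label, isolates)
}

#' @export
print.uv_spectrum <- function(x, ...) {
  n_iso <- n_distinct(x$counts$isolate_id)
  cat("<uv_spectrum> ", x$type, ": ", n_iso, " isolate(s) x ",
      length(x$class_labels), " classes, ", sum(x$counts$count),
      " mutations\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.uv_spectrum <- function(x, ...) x$counts

#' @exportS3Method generics::glance
glance.uv_spectrum <- function(x, ...) {
  tibble(type = x$type,
         n_isolates = n_distinct(x$counts$isolate_id),
         n_classes = length(x$class_labels),
         total_mutations = sum(x$counts$count),
         n_uncountable = x$audit$n[x$audit$rule == "uncountable_context"])
}

#' Subset a spectrum by strain and/or replicate
#'
#' @param x a `uv_spectrum`.
#' @param strains,replicates values of `strain_id` / `replicate_id` to
#'   keep (NULL keeps all).
#' @return a `uv_spectrum` over the retained isolates.
#' @export
filter_spectrum <- function(x, strains = NULL, replicates = NULL) {
  counts <- x$counts
  if (!is.null(strains)) counts <- filter(counts, .data$strain_id %in% strains)
  if (!is.null(replicates)) {
    counts <- filter(counts, .data$replicate_id %in% replicates)
  }
  new_uv_spectrum(counts, x$type, x$class_labels, x$audit)
}

#' Per-isolate mutation totals
#'
#' @param x a `uv_spectrum`.
#' @return tibble with one row per isolate and its total mutation count.
#' @export
spectrum_totals <- function(x) {
  x$counts %>%
    group_by(.data$isolate_id, .data$strain_id, .data$replicate_id) %>%
    summarise(total = sum(.data$count), .groups = "drop")
}

sem <- function(v) {
  n <- sum(!is.na(v))
  if (n < 2) return(NA_real_)
  stats::sd(v, na.rm = TRUE) / sqrt(n)
}

#' Summarise a spectrum by strain (or strain x replicate)
#'
#' Medians of even-sized groups are the mean of the two central values.
#' SEM uses the n-1 sample standard deviation and is undefined (NA) for
#' groups of fewer than two isolates.
#'
#' @param x a `uv_spectrum`.
#' @param by `"strain"` or `"strain_replicate"`.
#' @return list of class `uv_spectrum_summary` with `totals` (per group:
#'   `n_isolates`, `median_total`, `mean_total`, `sem_total`) and
#'   `classes` (per group and class: `mean`, `sem`, `total`).
#' @export
summarize_spectrum <- function(x, by = c("strain", "strain_replicate")) {
  by <- match.arg(by)
  keys <- if (by == "strain") "strain_id" else c("strain_id", "replicate_id")
  totals <- spectrum_totals(x) %>%
    group_by(across(all_of(keys))) %>%
    summarise(n_isolates = n(),
              median_total = stats::median(.data$total),
              mean_total = mean(.data$total),
              sem_total = sem(.data$total),
              .groups = "drop")
  classes <- x$counts %>%
    group_by(across(all_of(c(keys, "class_label")))) %>%
    summarise(mean = mean(.data$count),
              sem = sem(.data$count),
              total = sum(.data$count),
              .groups = "drop")
  structure(list(totals = totals, classes = classes, by = by),
            class = "uv_spectrum_summary")
}

#' @export
print.uv_spectrum_summary <- function(x, ...) {
  cat("<uv_spectrum_summary> by ", x$by, "\n", sep = "")
  print(x$totals)
  invisible(x)
}

#' Bar chart of per-class mean mutations per isolate
#'
#' @param object a `uv_spectrum`.
#' @param by grouping passed to [summarize_spectrum()].
#' @param ... unused.
#' @return a ggplot object (classes on x, mean per isolate with SEM bars,
#'   faceted by strain).
#' @exportS3Method ggplot2::autoplot
autoplot.uv_spectrum <- function(object, by = "strain", ...) {
  stats <- summarize_spectrum(object, by = by)$classes
  stats$class_label <- factor(stats$class_label, levels = object$class_labels)
  if (object$type == "SBS96") {
    stats$substitution <- str_sub(stats$class_label, 3, 5)
  } else {
    stats$substitution <- sub(">.*$", "", stats$class_label)
  }
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$class_label, y = .data$mean,
                                      fill = .data$substitution)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.3, linewidth = 0.2, na.rm = TRUE) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$strain_id)) +
    ggplot2::labs(x = NULL, y = "mean mutations per isolate", fill = NULL) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 4))
}

#' Write a spectrum as a classes x isolates TSV
#'
#' @param x a `uv_spectrum`.
#' @param path output file.
#' @export
write_spectrum_tsv <- function(x, path) {
  wide <- x$counts %>%
    select("isolate_id", "class_label", "count") %>%
    pivot_wider(names_from = "isolate_id", values_from = "count")
  wide <- wide[match(x$class_labels, wide$class_label), ]
  readr::write_tsv(wide, path)
  invisible(path)
}
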