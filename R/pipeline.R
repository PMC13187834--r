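# End-to-end orchestration: filter -> spectra -> attribution ->
# asymmetry -> lesion quantification -> consolidated report, with every
# stage's table written as TSV and stage audits logged to stderr.

#' Pipeline run configuration
#'
#' Inputs may be given as paths (FASTA / GFF3-BED / metadata TSV / lane
#' TSVs) or as in-memory objects from the simulator.
#'
#' @param genome a [uv_genome()] or FASTA path.
#' @param genes gene tibble or GFF3/BED path.
#' @param variants variant tibble, or NULL to read from `metadata`.
#' @param metadata metadata TSV path or tibble (see [read_cohort()]).
#' @param filter a [filter_config()].
#' @param comparisons list of `list(control=, treated=)` strain pairs for
#'   fold-reduction analysis; the first pair also drives attribution.
#' @param lanes optional named list:
#'   `list(CPD = list(enzyme=, control=), non_CPD = ...)` of lane
#'   tibbles or TSV paths.
#' @param ladder ladder band tibble (`size_bp`, `migration`) or TSV path;
#'   required when `lanes` is given.
#' @param min_total_fold,min_total_asymmetry class-count thresholds.
#' @param fold_threshold quadrant threshold for photoproduct calls.
#' @param poisson_correction correction for [lesion_frequency()].
#' @param asymmetry_strain strain whose mutations enter the asymmetry
#'   analysis (default: all).
#' @param excluded_contigs forwarded to genome loading / filtering.
#' @param out_dir output directory, or NULL to skip writing.
#' @return a `run_config` list.
#' @export
run_config <- function(genome, genes, variants = NULL, metadata = NULL,
                       filter = filter_config(),
                       comparisons = list(),
                       lanes = NULL, ladder = NULL,
                       min_total_fold = 70, min_total_asymmetry = 50,
                       fold_threshold = 2, poisson_correction = 1.678,
                       asymmetry_strain = NULL,
                       excluded_contigs = NULL,
                       out_dir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

log_stage <- function(...) message("[uvspectra] ", ...)

resolve_inputs <- function(config) {
  genome <- config$genome
  if (is.character(genome)) {
    genome <- load_genome(genome,
                          excluded_contigs = config$excluded_contigs %||% character())
  }
  genes <- config$genes
  if (is.character(genes)) genes <- read_genes(genes)
  variants <- config$variants
  if (is.null(variants)) {
    if (is.null(config$metadata)) abort("supply variants or metadata")
    variants <- read_cohort(config$metadata)
  }
  excl <- config$excluded_contigs %||% genome$excluded_contigs
  filter <- config$filter
  filter$excluded_contigs <- union(filter$excluded_contigs, excl)
  list(genome = genome, genes = genes, variants = variants, filter = filter)
}

#' Run the full analysis pipeline
#'
#' Executes filtering, spectrum construction, strain comparisons,
#' strand-asymmetry analysis and (when lane profiles are supplied)
#' lesion quantification with the mutagenic-potential arithmetic, writes
#' each stage's TSV into `out_dir` and a consolidated human-readable
#' report, and returns all results invisibly.
#'
#' A comparison strain missing from the cohort is a configuration error
#' raised before any computation.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `snvs`, `dbs`, `audit`, `sbs`, `dbs_spectrum`,
#'   `summary`, `fold_tables`, `calls`, `concordance`, `asymmetry`,
#'   `reverse_asymmetry`, `lesions`, `attribution`, `params`.
#' @export
run_pipeline <- function(config) {
  inp <- resolve_inputs(config)
  strains_present <- unique(inp$variants$strain_id)
  for (cmp in config$comparisons) {
    missing <- setdiff(c(cmp$control, cmp$treated), strains_present)
    if (length(missing)) {
      abort(paste0("comparison strain not in cohort: ",
                   paste(missing, collapse = ", ")))
    }
  }

  log_stage("filtering ", nrow(inp$variants), " variant records")
  filt <- filter_variants(inp$variants, inp$filter)
  log_stage("kept ", nrow(filt$snvs), " SNVs and ", nrow(filt$dbs), " doublets")

  isolates <- distinct(inp$variants[, c("isolate_id", "strain_id", "replicate_id")])
  sbs <- build_sbs_matrix(filt$snvs, inp$genome, isolates = isolates)
  dbs_spectrum <- build_dbs_matrix(filt$dbs, inp$genome, isolates = isolates)
  summary_rep <- summarize_spectrum(sbs, by = "strain_replicate")
  summary_strain <- summarize_spectrum(sbs, by = "strain")

  fold_tables <- list()
  attribution <- list()
  for (cmp in config$comparisons) {
    key <- paste0(cmp$control, "_vs_", cmp$treated)
    log_stage("fold-reduction table: ", key)
    fold_tables[[key]] <- fold_reduction_table(
      filter_spectrum(sbs, strains = cmp$control),
      filter_spectrum(sbs, strains = cmp$treated),
      min_total_mutations = config$min_total_fold)
    attribution[[key]] <- attribute_mutation_counts(
      summary_rep$totals, control = cmp$control, treated = cmp$treated)
  }
  calls <- NULL
  if (length(fold_tables) >= 2) {
    calls <- photoproduct_calls(fold_tables[[1]], fold_tables[[2]],
                                cpd_threshold = config$fold_threshold,
                                pp64_threshold = config$fold_threshold)
  }

  concordance <- list()
  for (st in strains_present) {
    reps <- unique(inp$variants$replicate_id[inp$variants$strain_id == st])
    if (length(reps) == 2) {
      concordance[[st]] <- replicate_concordance(sbs, st)
    }
  }
  concordance <- if (length(concordance)) list_rbind(concordance) else NULL

  log_stage("strand asymmetry")
  asym_snvs <- filt$snvs
  if (!is.null(config$asymmetry_strain)) {
    asym_snvs <- filter(asym_snvs, .data$strain_id %in% config$asymmetry_strain)
  }
  ann <- assign_transcriptional_strand(annotate_sbs(asym_snvs, inp$genome),
                                       inp$genes)
  asymmetry <- asymmetry_table(ann, inp$genes, inp$genome,
                               min_total_mutations = config$min_total_asymmetry)
  rev_asym <- reverse_asymmetry_report(asymmetry)

  lesions <- NULL
  if (!is.null(config$lanes)) {
    ladder <- config$ladder
    if (is.character(ladder)) ladder <- readr::read_tsv(ladder, show_col_types = FALSE)
    calib <- calibrate_ladder(ladder)
    lesions <- imap(config$lanes, function(pair, kind) {
      enzyme <- if (is.character(pair$enzyme)) {
        read_lane_profile(pair$enzyme, "t4_endoV")
      } else pair$enzyme
      control <- if (is.character(pair$control)) {
        read_lane_profile(pair$control, "no_enzyme")
      } else pair$control
      lesion_frequency(enzyme, control, calib,
                       correction = config$poisson_correction,
                       lesion_kind = if (kind == "CPD") "CPD" else "non_CPD")
    }) %>% list_rbind()
    log_stage("lesion quantification: ",
              paste(sprintf("%s %.3g/kb", lesions$lesion_kind,
                            lesions$net_lesions_per_kb), collapse = ", "))
  } else {
    log_stage("no lane profiles provided; lesion section skipped")
  }

  params <- tibble(
    parameter = c("min_depth", "min_allele_fraction", "max_recurrence",
                  "excluded_contigs", "min_total_fold", "min_total_asymmetry",
                  "fold_threshold", "poisson_correction"),
    value = c(inp$filter$min_depth, inp$filter$min_allele_fraction,
              inp$filter$max_recurrence,
              paste(inp$filter$excluded_contigs, collapse = ","),
              config$min_total_fold, config$min_total_asymmetry,
              config$fold_threshold, config$poisson_correction))

  results <- list(snvs = filt$snvs, dbs = filt$dbs, audit = filt$audit,
                  sbs = sbs, dbs_spectrum = dbs_spectrum,
                  summary = summary_rep, summary_strain = summary_strain,
                  fold_tables = fold_tables, calls = calls,
                  concordance = concordance,
                  asymmetry = asymmetry, reverse_asymmetry = rev_asym,
                  lesions = lesions, attribution = attribution,
                  genome = inp$genome, params = params)

  if (!is.null(config$out_dir)) {
    dir <- config$out_dir
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(filt$snvs, file.path(dir, "filtered_snvs.tsv"))
    readr::write_tsv(filt$dbs, file.path(dir, "filtered_dbs.tsv"))
    readr::write_tsv(filt$audit, file.path(dir, "filter_audit.tsv"))
    write_spectrum_tsv(sbs, file.path(dir, "sbs96_matrix.tsv"))
    write_spectrum_tsv(dbs_spectrum, file.path(dir, "dbs_matrix.tsv"))
    readr::write_tsv(summary_rep$totals, file.path(dir, "totals_by_replicate.tsv"))
    readr::write_tsv(summary_strain$classes, file.path(dir, "class_stats_by_strain.tsv"))
    for (key in names(fold_tables)) {
      readr::write_tsv(fold_tables[[key]],
                       file.path(dir, paste0("fold_", gsub("[^A-Za-z0-9_]", "_", key), ".tsv")))
    }
    if (!is.null(calls)) readr::write_tsv(calls, file.path(dir, "photoproduct_calls.tsv"))
    readr::write_tsv(asymmetry, file.path(dir, "asymmetry.tsv"))
    if (!is.null(lesions)) readr::write_tsv(lesions, file.path(dir, "lesions.tsv"))
    readr::write_tsv(params, file.path(dir, "parameters.tsv"))
    writeLines(utils::capture.output(pipeline_report(results)),
               file.path(dir, "report.txt"))
  }
  invisible(results)
}

fmt_num <- function(x, digits = 2) formatC(x, format = "f", digits = digits)

#' Consolidated human-readable report
#'
#' Prints per-strain median totals, the strongest fold-reduced classes
#' per comparison, photoproduct calls, reverse-asymmetric classes, and
#' the full mutagenic-potential arithmetic with every intermediate
#' factor shown. All parameters affecting the numbers are echoed in the
#' header.
#'
#' @param results output of [run_pipeline()], or a hand-built list with
#'   any of the fields `summary`, `fold_tables`, `calls`,
#'   `reverse_asymmetry`, `lesions`, `attribution`, `genome`, `params`.
#' @return the results, invisibly.
#' @export
pipeline_report <- function(results) {
  cat("== uvspectra report ==\n")
  if (!is.null(results$params)) {
    cat("parameters: ",
        paste0(results$params$parameter, "=", results$params$value,
               collapse = "; "), "\n", sep = "")
  }
  if (!is.null(results$summary)) {
    cat("\n-- per-strain / per-replicate mutation totals --\n")
    t <- results$summary$totals
    for (i in seq_len(nrow(t))) {
      cat(sprintf("  %s %s: n=%d median=%s mean=%s\n",
                  t$strain_id[i],
                  if ("replicate_id" %in% names(t)) t$replicate_id[i] else "",
                  t$n_isolates[i], fmt_num(t$median_total[i], 1),
                  fmt_num(t$mean_total[i], 1)))
    }
  }
  for (key in names(results$fold_tables)) {
    ft <- results$fold_tables[[key]]
    top <- ft %>% filter(is.finite(.data$fold_reduction)) %>%
      arrange(desc(.data$fold_reduction)) %>% head(5)
    cat("\n-- strongest fold reductions, ", key, " --\n", sep = "")
    for (i in seq_len(nrow(top))) {
      cat(sprintf("  %s: %.1f-fold (p=%.2g)\n", top$class_label[i],
                  top$fold_reduction[i], top$welch_p[i]))
    }
  }
  if (!is.null(results$calls)) {
    cat("\n-- photoproduct calls --\n")
    tab <- table(results$calls$label)
    for (lab in names(tab)) cat(sprintf("  %s: %d classes\n", lab, tab[[lab]]))
  }
  if (!is.null(results$reverse_asymmetry) && nrow(results$reverse_asymmetry)) {
    cat("\n-- reverse-asymmetric classes (putative atypical photoproducts) --\n")
    ra <- results$reverse_asymmetry
    for (i in seq_len(nrow(ra))) {
      cat(sprintf("  %s (ratio %.2f) -> %s on the complementary strand\n",
                  ra$class_label[i], ra$normalized_ratio[i],
                  ra$complementary_class[i]))
    }
  }
  if (!is.null(results$lesions) && !is.null(results$attribution) &&
      !is.null(results$genome)) {
    cat("\n-- mutagenic potential --\n")
    g <- results$genome
    for (i in seq_along(results$attribution)) {
      att <- results$attribution[[i]]
      kind <- if (i <= nrow(results$lesions)) results$lesions$lesion_kind[i] else NA
      if (is.na(kind)) next
      freq <- results$lesions$net_lesions_per_kb[results$lesions$lesion_kind == kind]
      mp <- mutagenic_potential(att$attributed_per_isolate, freq, genome = g)
      cat(sprintf(
        paste0("  %s: attributed %s mutations/isolate; %s lesions/kb x %s kb",
               " x ploidy %d x 2 strands = %s lesions; %s%% mutagenic\n"),
        kind, fmt_num(att$attributed_per_isolate, 1),
        fmt_num(freq, 2), format(g$haploid_size_kb, big.mark = " "),
        g$ploidy, format(round(mp$total_lesions), big.mark = " "),
        fmt_num(mp$percent_mutagenic, 2)))
    }
  }
  invisible(results)
}
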