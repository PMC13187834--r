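# Variant input and the study's filtering rules: depth / allele-fraction
# thresholds, mitochondrial exclusion, per-replicate recurrence screening
# and merging of adjacent SNVs into doublet substitutions.

#' Variant filter configuration
#'
#' Defaults mirror the calling thresholds used for the passaged isolates:
#' a minimum of 10 reads, a minimum 45% allelic fraction (both inclusive),
#' removal of mitochondrial calls, and removal of identical mutations seen
#' in more than two isolates of the same passaging replicate (which flags
#' variants pre-existing in the parental strain rather than UV-induced).
#'
#' @param min_depth minimum read depth (inclusive).
#' @param min_allele_fraction minimum allele fraction (inclusive, 0-1).
#' @param max_recurrence maximum number of distinct isolates within one
#'   replicate experiment that may carry an identical variant.
#' @param excluded_contigs contigs whose variants are dropped.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_depth = 10, min_allele_fraction = 0.45,
                          max_recurrence = 2, excluded_contigs = character()) {
  stopifnot(min_depth >= 0, min_allele_fraction >= 0,
            min_allele_fraction <= 1, max_recurrence >= 1)
  structure(list(min_depth = min_depth,
                 min_allele_fraction = min_allele_fraction,
                 max_recurrence = max_recurrence,
                 excluded_contigs = as.character(excluded_contigs)),
            class = "filter_config")
}

variant_cols <- function() {
  c("contig", "pos", "ref", "alt", "depth", "af",
    "isolate_id", "strain_id", "replicate_id", "type")
}

classify_alleles <- function(ref, alt) {
  ok <- grepl("^[ACGT]+$", ref) & grepl("^[ACGT]+$", alt)
  n_ref <- nchar(ref)
  n_alt <- nchar(alt)
  dplyr::case_when(
    !ok ~ "other",
    n_ref == 1 & n_alt == 1 ~ "snv",
    n_ref == 2 & n_alt == 2 &
      substr(ref, 1, 1) != substr(alt, 1, 1) &
      substr(ref, 2, 2) != substr(alt, 2, 2) ~ "mnv2",
    TRUE ~ "other"
  )
}

#' Read per-isolate variant calls from a VCF
#'
#' Positions are converted to 0-based on read. Single-base records become
#' SNV rows (`type = "snv"`); length-2 multi-nucleotide records differing
#' at both positions are doublet candidates (`type = "mnv2"`); indels and
#' longer records are kept with `type = "other"` so filter audits can
#' account for them, and are excluded from all spectra downstream.
#' Multi-allelic records are expanded to one row per alternate allele.
#'
#' @param vcf_path path to a VCF 4.x file (single sample).
#' @param isolate_id,strain_id,replicate_id provenance attached to every
#'   record.
#' @param depth_field,af_field FORMAT (preferred) or INFO field names
#'   holding read depth and allele fraction.
#' @return tibble with columns `contig`, `pos` (0-based), `ref`, `alt`,
#'   `depth`, `af`, `isolate_id`, `strain_id`, `replicate_id`, `type`.
#' @export
read_variants <- function(vcf_path, isolate_id, strain_id = NA_character_,
                          replicate_id = NA_character_,
                          depth_field = "DP", af_field = "AF") {
  if (!file.exists(vcf_path)) abort(paste0("VCF not found: ", vcf_path))
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix_m <- vcfR::getFIX(v)
  if (is.null(dim(fix_m))) fix_m <- t(fix_m)  # single-record VCF drops to a vector
  fix <- as.data.frame(fix_m, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(contig = character(), pos = integer(), ref = character(),
                  alt = character(), depth = numeric(), af = numeric(),
                  isolate_id = character(), strain_id = character(),
                  replicate_id = character(), type = character()))
  }
  get_field <- function(field) {
    val <- rep(NA_character_, nrow(fix))
    if (nrow(v@gt) > 0) {
      fmt <- tryCatch(vcfR::extract.gt(v, element = field, as.numeric = FALSE),
                      error = function(e) NULL)
      if (!is.null(fmt)) val <- as.character(fmt[, 1])
    }
    if (all(is.na(val))) {
      val <- vcfR::extract.info(v, element = field)
    }
    val
  }
  depth <- suppressWarnings(as.numeric(get_field(depth_field)))
  af_raw <- get_field(af_field)
  out <- tibble(
    contig = fix$CHROM,
    pos = as.integer(fix$POS) - 1L,
    ref = toupper(fix$REF),
    alt_all = toupper(fix$ALT),
    depth = depth,
    af_raw = af_raw
  ) %>%
    mutate(alt = str_split(.data$alt_all, ","),
           af_chr = str_split(.data$af_raw, ",")) %>%
    mutate(af_chr = map2(.data$af_chr, lengths(.data$alt),
                         function(a, k) rep_len(a, k))) %>%
    select(-"alt_all", -"af_raw") %>%
    unnest(c("alt", "af_chr")) %>%
    mutate(af = suppressWarnings(as.numeric(.data$af_chr)))
  # allele fraction may be given as a percentage
  if (any(out$af > 1, na.rm = TRUE)) out$af <- out$af / 100
  bad <- which(is.na(out$depth) | is.na(out$af))
  if (length(bad)) {
    abort(paste0("record ", out$contig[bad[1]], ":", out$pos[bad[1]] + 1L,
                 " in ", vcf_path, " is missing the ", depth_field, " or ",
                 af_field, " field"))
  }
  out %>%
    mutate(isolate_id = isolate_id,
           strain_id = strain_id,
           replicate_id = replicate_id,
           type = classify_alleles(.data$ref, .data$alt)) %>%
    select(all_of(variant_cols()))
}

#' Read a whole cohort from a sample-metadata table
#'
#' @param metadata path to a TSV with columns `isolate_id`, `strain_id`,
#'   `replicate_id`, `vcf_path`, or an equivalent tibble. Relative
#'   `vcf_path` entries are resolved against the metadata file's directory.
#' @inheritParams read_variants
#' @return tibble of variant records (see [read_variants()]).
#' @export
read_cohort <- function(metadata, depth_field = "DP", af_field = "AF") {
  if (is.character(metadata)) {
    dir <- dirname(metadata)
    metadata <- readr::read_tsv(metadata, show_col_types = FALSE)
    metadata$vcf_path <- ifelse(file.exists(metadata$vcf_path),
                                metadata$vcf_path,
                                file.path(dir, metadata$vcf_path))
  }
  need <- c("isolate_id", "strain_id", "replicate_id", "vcf_path")
  if (!all(need %in% names(metadata))) {
    abort(paste0("metadata must have columns ", paste(need, collapse = ", ")))
  }
  pmap(metadata[need], function(isolate_id, strain_id, replicate_id, vcf_path) {
    read_variants(vcf_path, isolate_id = isolate_id, strain_id = strain_id,
                  replicate_id = replicate_id,
                  depth_field = depth_field, af_field = af_field)
  }) %>% list_rbind()
}

audit_tibble <- function(rule, n) tibble(rule = rule, n = as.integer(n))

#' Apply per-site quality filters
#'
#' A record is kept iff `depth >= min_depth`, `af >= min_allele_fraction`
#' (both inclusive) and its contig is not excluded. The audit attributes
#' each removed record to the first failing rule (depth, then allele
#' fraction, then excluded contig); the predicates themselves are
#' independent, so filtering order cannot change which records survive.
#'
#' @param variants variant tibble (see [read_variants()]).
#' @param config a [filter_config()].
#' @return list with `variants` (kept rows) and `audit` (tibble of rule,
#'   n; includes a `retained` row; buckets sum to the input count).
#' @export
apply_site_filters <- function(variants, config = filter_config()) {
  fail_depth <- variants$depth < config$min_depth
  fail_af <- !fail_depth & variants$af < config$min_allele_fraction
  fail_contig <- !fail_depth & !fail_af &
    variants$contig %in% config$excluded_contigs
  keep <- !fail_depth & !fail_af & !fail_contig
  audit <- audit_tibble(
    c("depth", "allele_fraction", "excluded_contig", "retained"),
    c(sum(fail_depth), sum(fail_af), sum(fail_contig), sum(keep)))
  list(variants = variants[keep, , drop = FALSE], audit = audit)
}

#' Remove variants recurring across isolates of a replicate
#'
#' Within each passaging replicate (pooling all strains passaged in it),
#' any identical variant — keyed on (contig, position, ref, alt) — seen in
#' more than `max_recurrence` distinct isolates is removed wholesale.
#' Such variants most likely pre-existed in the parental strain.
#' Recurrence across different replicates is not filtered.
#'
#' @inheritParams apply_site_filters
#' @param max_recurrence see [filter_config()].
#' @return list with `variants` and `audit`.
#' @export
apply_recurrence_filter <- function(variants, max_recurrence = 2) {
  flagged <- variants %>%
    group_by(.data$replicate_id, .data$contig, .data$pos, .data$ref, .data$alt) %>%
    mutate(.n_isolates = n_distinct(.data$isolate_id)) %>%
    ungroup()
  keep <- flagged$.n_isolates <= max_recurrence
  audit <- audit_tibble(c("recurrence", "retained"),
                        c(sum(!keep), sum(keep)))
  list(variants = variants[keep, , drop = FALSE], audit = audit)
}

#' Merge adjacent SNVs into doublet substitutions
#'
#' Within each isolate, two filtered SNVs at adjacent positions merge into
#' one doublet (DBS) record; runs of three or more adjacent SNVs are set
#' aside as multi-nucleotide events and excluded from both SBS and DBS
#' spectra. Length-2 MNV records from the caller (`type = "mnv2"`) pass
#' through as doublets directly.
#'
#' @inheritParams apply_site_filters
#' @return list with `dbs` (tibble: contig, pos of first base, ref_dinuc,
#'   alt_dinuc, provenance), `snvs` (remaining single-base records) and
#'   `audit` (counts of doublets, remaining SNVs, multi-nucleotide-event
#'   bases, caller doublets, and `other`-type records excluded).
#' @export
call_doublets <- function(variants) {
  snv <- variants %>% filter(.data$type == "snv") %>%
    arrange(.data$isolate_id, .data$contig, .data$pos)
  mnv2 <- variants %>% filter(.data$type == "mnv2")
  other <- variants %>% filter(!.data$type %in% c("snv", "mnv2"))

  if (nrow(snv) > 0) {
    run_break <- c(TRUE, !(snv$isolate_id[-1] == snv$isolate_id[-nrow(snv)] &
                             snv$contig[-1] == snv$contig[-nrow(snv)] &
                             snv$pos[-1] == snv$pos[-nrow(snv)] + 1L))
    run_id <- cumsum(run_break)
    run_len <- ave(run_id, run_id, FUN = length)
  } else {
    run_id <- integer(0)
    run_len <- integer(0)
  }

  singles <- snv[run_len == 1, , drop = FALSE]
  pair_rows <- snv[run_len == 2, , drop = FALSE]
  mne_rows <- snv[run_len >= 3, , drop = FALSE]

  merged <- snv[0, , drop = FALSE]
  if (nrow(pair_rows) > 0) {
    first <- pair_rows[seq(1, nrow(pair_rows), by = 2), ]
    second <- pair_rows[seq(2, nrow(pair_rows), by = 2), ]
    merged <- first %>%
      mutate(ref = paste0(first$ref, second$ref),
             alt = paste0(first$alt, second$alt),
             depth = pmin(first$depth, second$depth),
             af = pmin(first$af, second$af))
  }
  dbs <- bind_rows(merged, mnv2) %>%
    rename(ref_dinuc = "ref", alt_dinuc = "alt") %>%
    select(-"type")
  # merging two SNVs always yields a doublet differing at both positions,
  # since each constituent already differs from its reference base
  audit <- audit_tibble(
    c("dbs", "snv", "multi_nucleotide_event_bases", "caller_mnv2", "other_excluded"),
    c(nrow(dbs), nrow(singles), nrow(mne_rows), nrow(mnv2), nrow(other)))
  list(dbs = dbs, snvs = singles, audit = audit)
}

#' Run the full filtering cascade
#'
#' Site filters, recurrence filter, then doublet merging, with a combined
#' audit reconciling every input record.
#'
#' @inheritParams apply_site_filters
#' @return list with `snvs`, `dbs`, and `audit`.
#' @export
filter_variants <- function(variants, config = filter_config()) {
  site <- apply_site_filters(variants, config)
  rec <- apply_recurrence_filter(site$variants, config$max_recurrence)
  dbl <- call_doublets(rec$variants)
  audit <- bind_rows(
    site$audit %>% filter(.data$rule != "retained") %>% mutate(stage = "site"),
    rec$audit %>% filter(.data$rule != "retained") %>% mutate(stage = "recurrence"),
    dbl$audit %>% mutate(stage = "doublets"))
  list(snvs = dbl$snvs, dbs = dbl$dbs, audit = audit)
}
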