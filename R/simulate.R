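# Synthetic mutation-accumulation cohorts with known ground truth.
# Lesion channels (CPD, 6-4PP, thymine-adenine photoproduct, AC
# photoproduct) deposit Poisson lesions on target dinucleotides on both
# strands; photolyase repair thins whole channels per strain;
# transcription-coupled repair thins lesions on the transcribed strand
# inside genes; surviving lesions convert directly into SBS or doublet
# mutations via per-context outcome distributions.

#' Photoproduct channel specification
#'
#' @param photoproduct channel name (`"CPD"`, `"PP64"`, `"TA_PP"`,
#'   `"AC_PP"` or custom).
#' @param targets dinucleotides the lesion forms at (read 5'->3' on the
#'   lesion strand).
#' @param rate expected mutations per target-dinucleotide occurrence per
#'   passage, before any repair.
#' @param outcomes tibble with columns `target`, `kind` (`"sbs"` or
#'   `"dbs"`), `position` (1 or 2 within the dinucleotide; NA for dbs),
#'   `alt` (single base for sbs, 2-mer for dbs), `prob`; probabilities
#'   must sum to 1 within each target.
#' @param ts_suppression factor by which lesions on the transcribed
#'   strand inside genes are reduced (TC-NER bias; >= 1).
#' @return a `channel_spec` list.
#' @export
channel_spec <- function(photoproduct, targets, rate, outcomes,
                         ts_suppression = 4) {
  stopifnot(rate >= 0, ts_suppression >= 1)
  sums <- tapply(outcomes$prob, outcomes$target, sum)
  if (any(abs(sums - 1) > 1e-8)) {
    abort("outcome probabilities must sum to 1 within each target dinucleotide")
  }
  if (!all(outcomes$target %in% targets)) {
    abort("outcome targets must be among the channel targets")
  }
  structure(list(photoproduct = photoproduct, targets = targets, rate = rate,
                 outcomes = outcomes, ts_suppression = ts_suppression),
            class = "channel_spec")
}

outcome_row <- function(target, kind, position, alt, prob) {
  tibble(target = target, kind = kind, position = position, alt = alt,
         prob = prob)
}

#' Default photoproduct channel presets
#'
#' Qualitative presets (not fitted parameters): the CPD channel is
#' C>T-heavy at TC/CC and contributes C>T, T>C, T>A and T>G at CT/TT
#' dipyrimidines; the 6-4PP channel drives T>C at the 3' T of TT and C>A
#' at TC; the thymine-adenine photoproduct yields A>T at the A of TA;
#' the AC photoproduct yields AC>TT doublets. Rates are per target
#' occurrence per passage and sized for the default desk-scale genome.
#'
#' @param ts_suppression transcription-coupled repair bias applied to all
#'   channels (default 4).
#' @return named list of [channel_spec()] objects.
#' @export
channel_presets <- function(ts_suppression = 4) {
  list(
    CPD = channel_spec(
      "CPD", targets = c("TT", "TC", "CT", "CC"), rate = 3e-4,
      outcomes = bind_rows(
        outcome_row("TC", "sbs", 2L, "T", 1),
        outcome_row("CC", "sbs", 2L, "T", 1),
        outcome_row("CT", "sbs", 1L, "T", 0.50),
        outcome_row("CT", "sbs", 2L, "C", 0.35),
        outcome_row("CT", "sbs", 2L, "A", 0.10),
        outcome_row("CT", "sbs", 2L, "G", 0.05),
        outcome_row("TT", "sbs", 2L, "A", 0.45),
        outcome_row("TT", "sbs", 2L, "C", 0.30),
        outcome_row("TT", "sbs", 2L, "G", 0.25)),
      ts_suppression = ts_suppression),
    PP64 = channel_spec(
      "PP64", targets = c("TT", "TC", "CC"), rate = 2.4e-4,
      outcomes = bind_rows(
        outcome_row("TT", "sbs", 2L, "C", 1),
        outcome_row("TC", "sbs", 2L, "A", 0.5),
        outcome_row("TC", "sbs", 2L, "T", 0.5),
        outcome_row("CC", "sbs", 2L, "T", 1)),
      ts_suppression = ts_suppression),
    TA_PP = channel_spec(
      "TA_PP", targets = "TA", rate = 6e-5,
      outcomes = outcome_row("TA", "sbs", 2L, "T", 1),
      ts_suppression = ts_suppression),
    AC_PP = channel_spec(
      "AC_PP", targets = "AC", rate = 6e-6,
      outcomes = outcome_row("AC", "dbs", NA_integer_, "TT", 1),
      ts_suppression = ts_suppression)
  )
}

#' Strain specification: photolyase repair efficiencies
#'
#' @param strain_id strain name.
#' @param repair named numeric vector in \[0, 1\]: fraction of each
#'   channel's lesions removed before mutagenesis (channels not named
#'   get 0).
#' @return a `strain_spec` list.
#' @export
strain_spec <- function(strain_id, repair = c()) {
  if (length(repair) && (any(repair < 0) || any(repair > 1))) {
    abort("repair efficiencies must lie in [0, 1]")
  }
  structure(list(strain_id = strain_id, repair = repair),
            class = "strain_spec")
}

#' The four-strain photolyase design
#'
#' No PL (no repair), CPD PL (CPD photolyase only), 6-4PP PL, and Both
#' PL, with complete (efficiency 1) photoreactivation of the targeted
#' channel, mirroring the experimental design.
#'
#' @return list of [strain_spec()] objects.
#' @export
strain_presets <- function() {
  list(
    strain_spec("No PL"),
    strain_spec("CPD PL", c(CPD = 1)),
    strain_spec("6-4PP PL", c(PP64 = 1)),
    strain_spec("Both PL", c(CPD = 1, PP64 = 1))
  )
}

#' Simulation configuration
#'
#' Defaults reflect the study conditions at desk scale: 15 UV passages,
#' two independent replicates, diploid calls with binomial heterozygous
#' allele fractions, a small mitochondrial contig to exercise the
#' exclusion filter, and a few recurrent contaminant variants per
#' replicate to exercise the recurrence filter.
#'
#' @param genome_length_bp nuclear genome length.
#' @param gc_fraction genomic GC content (yeast-like 0.38).
#' @param n_genes number of non-overlapping genes (placed ~50/50 on the
#'   two strands).
#' @param gene_length_range min/max gene length (uniform).
#' @param channels list of [channel_spec()]s.
#' @param strains list of [strain_spec()]s.
#' @param n_isolates isolates per strain per replicate.
#' @param n_replicates passaging replicates.
#' @param n_passages UV exposures per isolate (15).
#' @param mean_depth mean sequencing depth (Poisson).
#' @param mito_length_bp length of the excluded mitochondrial contig.
#' @param mito_variant_rate expected mitochondrial variants per isolate.
#' @param recurrent_contaminants pre-existing variants injected per
#'   replicate, each shared by more than two isolates.
#' @param ploidy ploidy of the simulated calls.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(genome_length_bp = 1e5,
                              gc_fraction = 0.38,
                              n_genes = 60,
                              gene_length_range = c(500, 1500),
                              channels = channel_presets(),
                              strains = strain_presets(),
                              n_isolates = 8,
                              n_replicates = 2,
                              n_passages = 15,
                              mean_depth = 60,
                              mito_length_bp = 2000,
                              mito_variant_rate = 1,
                              recurrent_contaminants = 2,
                              ploidy = 2) {
  stopifnot(genome_length_bp > 0, gc_fraction > 0, gc_fraction < 1,
            n_genes >= 0, n_isolates >= 1, n_replicates >= 1, n_passages >= 1)
  structure(as.list(environment()), class = "sim_config")
}

random_seq <- function(n, gc) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a random genome and gene annotation
#'
#' One nuclear contig at the configured GC fraction plus an excluded
#' mitochondrial contig; genes are non-overlapping, uniformly sized
#' within the configured range, strand drawn 50/50. Deterministic under
#' the seed.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return list with `genome` (a [uv_genome()], `chrM` excluded) and
#'   `genes` (tibble).
#' @export
generate_genome <- function(config, seed) {
  set.seed(seed)
  contigs <- c(chrS = random_seq(config$genome_length_bp, config$gc_fraction))
  if (config$mito_length_bp > 0) {
    contigs <- c(contigs, chrM = random_seq(config$mito_length_bp, 0.2))
  }
  genes <- tibble(gene_id = character(), contig = character(),
                  start = integer(), end = integer(), strand = character())
  if (config$n_genes > 0) {
    lens <- sample(config$gene_length_range[1]:config$gene_length_range[2],
                   config$n_genes, replace = TRUE)
    slack <- config$genome_length_bp - sum(lens)
    if (slack < config$n_genes) {
      abort("genes do not fit in the genome; reduce n_genes or lengths")
    }
    # random gaps between consecutive genes (multinomial split of slack)
    gaps <- as.vector(stats::rmultinom(1, slack, rep(1, config$n_genes + 1)))
    starts <- cumsum(gaps[-length(gaps)] + c(0, lens[-length(lens)]))
    genes <- tibble(
      gene_id = sprintf("gene_%03d", seq_len(config$n_genes)),
      contig = "chrS",
      start = as.integer(starts),
      end = as.integer(starts + lens),
      strand = sample(c("+", "-"), config$n_genes, replace = TRUE)
    )
  }
  genome <- uv_genome(contigs, excluded_contigs = intersect("chrM", names(contigs)),
                      ploidy = config$ploidy)
  list(genome = genome, genes = genes)
}

# All occurrences of each target dinucleotide on both strands of the
# non-excluded contigs: tibble(target, contig, pos, strand) where pos is
# the 0-based forward-strand coordinate of the occurrence's first base.
dinuc_occurrences <- function(genome, targets) {
  kept <- setdiff(names(genome$contigs), genome$excluded_contigs)
  out <- list()
  for (target in unique(targets)) {
    for (ct in kept) {
      s <- contig_seq(genome, ct)
      fwd <- Biostrings::start(Biostrings::matchPattern(target, Biostrings::DNAString(s)))
      rc <- revcomp(target)
      rev_hits <- Biostrings::start(Biostrings::matchPattern(rc, Biostrings::DNAString(s)))
      rows <- list()
      if (length(fwd)) {
        rows <- c(rows, list(tibble(target = target, contig = ct,
                                    pos = fwd - 1L, strand = "+")))
      }
      if (length(rev_hits)) {
        rows <- c(rows, list(tibble(target = target, contig = ct,
                                    pos = rev_hits - 1L, strand = "-")))
      }
      out <- c(out, rows)
    }
  }
  if (length(out) == 0) {
    return(tibble(target = character(), contig = character(),
                  pos = integer(), strand = character()))
  }
  list_rbind(out)
}

# template-strand membership: for each occurrence, is its strand the
# transcribed strand of a (single-strand-covered) gene at that position?
mark_template_strand <- function(occ, genes) {
  if (nrow(occ) == 0 || nrow(genes) == 0) {
    occ$on_ts <- rep(FALSE, nrow(occ))
    return(occ)
  }
  ivals <- strand_intervals(genes)
  in_plus <- logical(nrow(occ))
  in_minus <- logical(nrow(occ))
  for (ct in names(ivals)) {
    idx <- which(occ$contig == ct)
    if (!length(idx)) next
    q <- IRanges::IRanges(start = occ$pos[idx] + 1L, width = 1L)
    in_plus[idx] <- IRanges::overlapsAny(q, ivals[[ct]]$plus)
    in_minus[idx] <- IRanges::overlapsAny(q, ivals[[ct]]$minus)
  }
  coding <- ifelse(in_plus & in_minus, NA_character_,
                   ifelse(in_plus, "+", ifelse(in_minus, "-", NA_character_)))
  occ$on_ts <- !is.na(coding) & occ$strand != coding
  occ
}

lesions_to_mutations <- function(lesions, channel) {
  # lesions: tibble(target, contig, pos, strand); sample an outcome per
  # lesion and convert to forward-strand VCF-style records
  out <- lesions %>%
    group_by(.data$target) %>%
    group_map(function(df, key) {
      oc <- channel$outcomes[channel$outcomes$target == key$target, ]
      if (nrow(oc) == 0) return(NULL)
      df$target <- key$target
      pick <- sample.int(nrow(oc), nrow(df), replace = TRUE, prob = oc$prob)
      df$kind <- oc$kind[pick]
      df$out_pos <- oc$position[pick]
      df$out_alt <- oc$alt[pick]
      df
    }) %>%
    list_rbind()
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(contig = character(), pos = integer(), ref = character(),
                  alt = character(), type = character(), lesion_strand = character()))
  }
  sbs <- out[out$kind == "sbs", ]
  dbs <- out[out$kind == "dbs", ]
  res <- list()
  if (nrow(sbs) > 0) {
    strand_ref <- substr(sbs$target, sbs$out_pos, sbs$out_pos)
    plus <- sbs$strand == "+"
    gpos <- ifelse(plus, sbs$pos + sbs$out_pos - 1L, sbs$pos + 2L - sbs$out_pos)
    ref <- ifelse(plus, strand_ref, comp(strand_ref))
    alt <- ifelse(plus, sbs$out_alt, comp(sbs$out_alt))
    res <- c(res, list(tibble(contig = sbs$contig, pos = as.integer(gpos),
                              ref = ref, alt = alt, type = "snv",
                              lesion_strand = sbs$strand)))
  }
  if (nrow(dbs) > 0) {
    plus <- dbs$strand == "+"
    ref <- ifelse(plus, dbs$target, revcomp(dbs$target))
    alt <- ifelse(plus, dbs$out_alt, revcomp(dbs$out_alt))
    res <- c(res, list(tibble(contig = dbs$contig, pos = as.integer(dbs$pos),
                              ref = ref, alt = alt, type = "mnv2",
                              lesion_strand = dbs$strand)))
  }
  list_rbind(res)
}

add_read_noise <- function(df, mean_depth) {
  n <- nrow(df)
  depth <- pmax(1L, stats::rpois(n, mean_depth))
  alt_reads <- stats::rbinom(n, depth, 0.5)
  df$depth <- depth
  df$af <- alt_reads / depth
  df
}

#' Simulate a mutation-accumulation cohort
#'
#' For every isolate of every strain and replicate: each channel deposits
#' Poisson lesions across its target-dinucleotide occurrences over the
#' passages, thinned by the strain's photolyase efficiency for that
#' channel and by the transcription-coupled repair factor for lesions on
#' the transcribed strand inside genes; surviving lesions become SBS or
#' doublet mutations via the channel's outcome distribution. Read depth
#' is Poisson and the heterozygous allele fraction binomial. Recurrent
#' contaminants (pre-existing variants shared by >2 isolates of a
#' replicate) and mitochondrial variants are injected to exercise the
#' filters. The ground-truth table records each emitted variant's causal
#' channel and lesion strand.
#'
#' @param config a [simulation_config()].
#' @param genome,genes from [generate_genome()].
#' @param seed integer seed (mandatory; identical seed and config give
#'   identical output).
#' @return list with `variants` (tibble in [read_variants()] layout),
#'   `metadata` (isolate_id, strain_id, replicate_id) and `ground_truth`
#'   (one row per emitted variant with `channel` and `lesion_strand`).
#' @export
simulate_cohort <- function(config, genome, genes, seed) {
  set.seed(seed)
  all_targets <- unique(unlist(map(config$channels, "targets")))
  occ <- dinuc_occurrences(genome, all_targets)
  occ <- mark_template_strand(occ, genes)
  for (ch in config$channels) {
    missing <- setdiff(ch$targets, occ$target)
    if (length(missing)) {
      warn(paste0("channel ", ch$photoproduct, ": target ",
                  paste(missing, collapse = ","),
                  " absent from genome; zero yield"))
    }
  }
  metadata <- tidyr::crossing(
    replicate_id = paste0("rep", seq_len(config$n_replicates)),
    strain_id = map_chr(config$strains, "strain_id"),
    isolate = seq_len(config$n_isolates)
  ) %>%
    mutate(isolate_id = sprintf("%s_%s_iso%02d",
                                gsub("[^A-Za-z0-9]", "", .data$strain_id),
                                .data$replicate_id, .data$isolate)) %>%
    select("isolate_id", "strain_id", "replicate_id")

  strain_map <- setNames(config$strains, map_chr(config$strains, "strain_id"))
  variants <- list()
  truth <- list()

  for (i in seq_len(nrow(metadata))) {
    iso <- metadata$isolate_id[i]
    strain <- strain_map[[metadata$strain_id[i]]]
    rows <- list()
    for (ch in config$channels) {
      eff <- if (ch$photoproduct %in% names(strain$repair)) {
        strain$repair[[ch$photoproduct]]
      } else 0
      occ_t <- occ[occ$target %in% ch$targets, ]
      n_opp <- nrow(occ_t)
      if (n_opp == 0) next
      lambda <- ch$rate * n_opp * config$n_passages * (1 - eff)
      n_lesions <- stats::rpois(1, lambda)
      if (n_lesions == 0) next
      hit <- occ_t[sample.int(n_opp, n_lesions, replace = TRUE), ]
      # transcription-coupled repair of template-strand lesions
      keep <- !hit$on_ts | stats::runif(n_lesions) < 1 / ch$ts_suppression
      hit <- hit[keep, ]
      if (nrow(hit) == 0) next
      muts <- lesions_to_mutations(hit, ch)
      if (nrow(muts) > 0) {
        muts$channel <- ch$photoproduct
        rows <- c(rows, list(muts))
      }
    }
    # mitochondrial variants (excluded downstream)
    if (config$mito_variant_rate > 0 && "chrM" %in% names(genome$contigs)) {
      n_m <- stats::rpois(1, config$mito_variant_rate)
      if (n_m > 0) {
        mseq <- contig_seq(genome, "chrM")
        mpos <- sample.int(nchar(mseq) - 2L, n_m) # keep off contig edges
        ref <- substring(mseq, mpos + 1L, mpos + 1L)
        alt <- map_chr(ref, function(r) sample(setdiff(DNA_BASES, r), 1))
        rows <- c(rows, list(tibble(contig = "chrM", pos = as.integer(mpos),
                                    ref = ref, alt = alt, type = "snv",
                                    lesion_strand = NA_character_,
                                    channel = "mito")))
      }
    }
    if (length(rows) == 0) next
    df <- list_rbind(rows) %>%
      distinct(.data$contig, .data$pos, .keep_all = TRUE) %>%
      mutate(isolate_id = iso,
             strain_id = metadata$strain_id[i],
             replicate_id = metadata$replicate_id[i])
    variants <- c(variants, list(df))
  }

  variants <- if (length(variants)) list_rbind(variants) else
    tibble(contig = character(), pos = integer(), ref = character(),
           alt = character(), type = character(), lesion_strand = character(),
           channel = character(), isolate_id = character(),
           strain_id = character(), replicate_id = character())

  # recurrent contaminants: identical SNV in >2 isolates of one replicate
  if (config$recurrent_contaminants > 0) {
    s <- contig_seq(genome, "chrS")
    cont <- list()
    for (rep_id in unique(metadata$replicate_id)) {
      iso_pool <- metadata[metadata$replicate_id == rep_id, ]
      for (k in seq_len(config$recurrent_contaminants)) {
        p <- sample.int(nchar(s) - 2L, 1)
        ref <- substring(s, p + 1L, p + 1L)
        alt <- sample(setdiff(DNA_BASES, ref), 1)
        n_carriers <- min(nrow(iso_pool), 3 + stats::rpois(1, 1))
        carriers <- iso_pool[sample.int(nrow(iso_pool), n_carriers), ]
        cont <- c(cont, list(tibble(
          contig = "chrS", pos = as.integer(p), ref = ref, alt = alt,
          type = "snv", lesion_strand = NA_character_, channel = "preexisting",
          isolate_id = carriers$isolate_id, strain_id = carriers$strain_id,
          replicate_id = rep_id)))
      }
    }
    variants <- bind_rows(variants, list_rbind(cont))
  }

  variants <- add_read_noise(variants, config$mean_depth)
  ground_truth <- variants %>%
    select("contig", "pos", "ref", "alt", "isolate_id", "strain_id",
           "replicate_id", "channel", "lesion_strand")
  list(
    variants = variants %>% select(all_of(variant_cols())),
    metadata = metadata,
    ground_truth = ground_truth
  )
}

#' Simulate an alkaline-gel lane profile pair
#'
#' Poisson breaks (lesions plus background in the enzyme lane; background
#' only in the control lane) are placed uniformly on each strand; the
#' resulting fragment lengths are binned onto the calibrated migration
#' axis with intensity proportional to fragment length (mass weighting,
#' as for a stained gel).
#'
#' @param true_lesions_per_kb lesion cleavage frequency (per kb).
#' @param background_per_kb background cutting frequency (per kb).
#' @param strand_length_kb length of each DNA strand in kb.
#' @param n_strands number of strands.
#' @param calibration a [calibrate_ladder()] object (defines the
#'   migration axis).
#' @param seed integer seed.
#' @param n_bins migration bins.
#' @return list with `enzyme` and `control` lane tibbles
#'   (`migration`, `intensity`).
#' @export
simulate_lane_profile <- function(true_lesions_per_kb, background_per_kb,
                                  strand_length_kb = 50, n_strands = 1e4,
                                  calibration, seed, n_bins = 600) {
  stopifnot(true_lesions_per_kb >= 0, background_per_kb >= 0)
  set.seed(seed)
  one_lane <- function(rate_per_kb) {
    L <- strand_length_kb * 1000
    counts <- stats::rpois(n_strands, rate_per_kb * strand_length_kb)
    total <- sum(counts)
    strand <- rep.int(seq_len(n_strands), counts)
    pos <- stats::runif(total, 0, L)
    ord <- order(strand, pos)
    strand <- strand[ord]; pos <- pos[ord]
    first <- !duplicated(strand)
    lead_frag <- pos[first]
    inner <- diff(pos)
    inner <- inner[strand[-1] == strand[-length(strand)]]
    last_pos <- pos[!duplicated(strand, fromLast = TRUE)]
    tail_frag <- L - last_pos
    unbroken <- rep(L, sum(counts == 0))
    frags <- c(lead_frag, inner, tail_frag, unbroken)
    frags <- frags[frags > 0]
    # bin mass (length-weighted) on the migration axis
    mig <- calibration$migration_at(frags)
    rng <- range(calibration$migration_at(c(L, 1)))
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
    mig <- pmin(pmax(mig, rng[1]), rng[2])
    bin <- findInterval(mig, breaks, rightmost.closed = TRUE)
    intensity <- as.vector(tapply(frags, factor(bin, levels = seq_len(n_bins)),
                                  sum, default = 0))
    tibble(migration = (breaks[-1] + breaks[-length(breaks)]) / 2,
           intensity = intensity)
  }
  list(enzyme = one_lane(true_lesions_per_kb + background_per_kb),
       control = one_lane(background_per_kb))
}

#' Write a simulated cohort to disk
#'
#' One plain-text VCF per isolate plus a metadata TSV (isolate_id,
#' strain_id, replicate_id, vcf_path) and the ground-truth table.
#'
#' @param cohort output of [simulate_cohort()].
#' @param genome the genome the cohort was simulated on.
#' @param dir output directory (created if needed).
#' @return path of the metadata TSV, invisibly.
#' @export
write_cohort_vcfs <- function(cohort, genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", names(genome$contigs),
           ",length=", nchar(genome$contigs), ">"),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">")
  meta <- cohort$metadata
  paths <- character(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    iso <- meta$isolate_id[i]
    v <- cohort$variants %>% filter(.data$isolate_id == iso) %>%
      arrange(.data$contig, .data$pos)
    path <- file.path(dir, paste0(iso, ".vcf"))
    body <- if (nrow(v)) {
      paste(v$contig, v$pos + 1L, ".", v$ref, v$alt, ".", "PASS", ".",
            "DP:AF", paste0(v$depth, ":", sprintf("%.4f", v$af)),
            sep = "\t")
    } else character(0)
    writeLines(c(header,
                 paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                                     "FILTER", "INFO", "FORMAT", iso),
                                   collapse = "\t")),
                 body),
               path)
    paths[i] <- path
  }
  meta$vcf_path <- paths
  meta_path <- file.path(dir, "metadata.tsv")
  readr::write_tsv(meta, meta_path)
  readr::write_tsv(cohort$ground_truth, file.path(dir, "ground_truth.tsv"))
  invisible(meta_path)
}

#' Write a genome to FASTA and genes to BED
#'
#' @param genome a [uv_genome()].
#' @param genes gene tibble.
#' @param fasta_path,bed_path output paths.
#' @export
write_genome_files <- function(genome, genes, fasta_path, bed_path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$contigs), fasta_path)
  bed <- genes %>%
    transmute(.data$contig, .data$start, .data$end, .data$gene_id,
              score = 0L, .data$strand)
  readr::write_tsv(bed, bed_path, col_names = FALSE)
  invisible(fasta_path)
}
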