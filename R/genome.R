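# Genome and gene-annotation handling: FASTA/GFF3/BED input, strand
# conventions (NTS = coding strand, TS = its complement) and context
# censuses used for trinucleotide normalization.

#' Construct a genome assembly object
#'
#' @param contigs named character vector or `Biostrings::DNAStringSet` of
#'   contig sequences (uppercased on construction).
#' @param excluded_contigs contig names excluded from all analyses
#'   (typically the mitochondrial chromosome); names absent from the
#'   assembly are tolerated.
#' @param ploidy positive integer, 2 for the diploid strains analysed here.
#' @return object of class `uv_genome` with fields `contigs` (named
#'   character), `excluded_contigs`, `ploidy` and `haploid_size_kb`
#'   (total non-excluded length / 1000).
#' @export
uv_genome <- function(contigs, excluded_contigs = character(), ploidy = 2L) {
  if (inherits(contigs, "DNAStringSet")) {
    contigs <- setNames(as.character(contigs), names(contigs))
  }
  if (length(contigs) == 0 || is.null(names(contigs)) || any(names(contigs) == "")) {
    abort("genome must contain at least one named contig")
  }
  contigs <- toupper(contigs)
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad)) {
    abort(paste0("contig ", names(contigs)[bad][1],
                 " contains characters other than A, C, G, T, N"))
  }
  if (!is.numeric(ploidy) || ploidy < 1) abort("ploidy must be a positive integer")
  kept <- setdiff(names(contigs), excluded_contigs)
  size_kb <- sum(nchar(contigs[kept])) / 1000
  if (size_kb <= 0) abort("genome has no non-excluded sequence")
  structure(
    list(contigs = contigs,
         excluded_contigs = as.character(excluded_contigs),
         ploidy = as.integer(ploidy),
         haploid_size_kb = size_kb),
    class = "uv_genome"
  )
}

#' @export
print.uv_genome <- function(x, ...) {
  cat("<uv_genome> ", length(x$contigs), " contig(s), haploid size ",
      format(x$haploid_size_kb, big.mark = ","), " kb, ploidy ", x$ploidy, "\n",
      sep = "")
  if (length(x$excluded_contigs)) {
    cat("  excluded: ", paste(x$excluded_contigs, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Load a genome from FASTA
#'
#' @param fasta_path path to a FASTA file.
#' @inheritParams uv_genome
#' @return a [uv_genome()] object.
#' @export
load_genome <- function(fasta_path, excluded_contigs = character(), ploidy = 2L) {
  if (!file.exists(fasta_path)) abort(paste0("FASTA file not found: ", fasta_path))
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  # FASTA headers may carry descriptions after the identifier
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  uv_genome(seqs, excluded_contigs = excluded_contigs, ploidy = ploidy)
}

contig_seq <- function(genome, contig) {
  s <- genome$contigs[[contig]]
  if (is.null(s)) abort(paste0("contig not in genome: ", contig))
  s
}

#' Read gene annotation from GFF3 or BED
#'
#' Coordinates are converted to 0-based half-open on read. Only the
#' contig, interval and strand are used; a gene identifier is taken from
#' the `ID`/`Name`/`gene_id` attribute (GFF3) or the name column (BED),
#' falling back to `gene_<i>`.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED file with a strand column.
#' @param feature_type for GFF3, restrict to this `type` (default `"gene"`;
#'   `NULL` keeps all records).
#' @return tibble with columns `gene_id`, `contig`, `start` (0-based),
#'   `end` (exclusive), `strand` (`"+"`/`"-"`).
#' @export
read_genes <- function(path, feature_type = "gene") {
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  gr <- rtracklayer::import(path)
  meta <- as.data.frame(gr)
  if (!is.null(feature_type) && "type" %in% names(meta)) {
    keep <- as.character(meta$type) == feature_type
    if (any(keep)) {
      gr <- gr[keep]
      meta <- meta[keep, , drop = FALSE]
    }
  }
  ids <- NULL
  for (col in c("ID", "Name", "gene_id", "name")) {
    if (col %in% names(meta) && !all(is.na(meta[[col]]))) {
      ids <- as.character(meta[[col]])
      break
    }
  }
  if (is.null(ids)) ids <- paste0("gene_", seq_along(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(!strand %in% c("+", "-"))) {
    abort("gene annotation must give every gene a +/- strand")
  }
  tibble(
    gene_id = ids,
    contig = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = strand
  )
}

validate_genes <- function(genes, genome = NULL) {
  need <- c("gene_id", "contig", "start", "end", "strand")
  if (!all(need %in% names(genes))) {
    abort(paste0("genes must have columns ", paste(need, collapse = ", ")))
  }
  if (any(genes$start < 0) || any(genes$start >= genes$end)) {
    abort("gene intervals must satisfy 0 <= start < end")
  }
  if (any(!genes$strand %in% c("+", "-"))) abort("gene strand must be + or -")
  if (!is.null(genome)) {
    len <- nchar(genome$contigs)[genes$contig]
    if (any(is.na(len))) {
      abort(paste0("gene contig not in genome: ",
                   genes$contig[is.na(len)][1]))
    }
    if (any(genes$end > len)) abort("gene interval extends beyond contig end")
  }
  invisible(genes)
}

# Per-contig intervals covered by genes of each strand, and the
# opposite-strand overlap where NTS/TS is undefined (ambiguous).
strand_intervals <- function(genes) {
  genes %>%
    group_by(.data$contig) %>%
    group_map(function(df, key) {
      plus <- IRanges::reduce(IRanges::IRanges(
        start = df$start[df$strand == "+"] + 1L, end = df$end[df$strand == "+"]))
      minus <- IRanges::reduce(IRanges::IRanges(
        start = df$start[df$strand == "-"] + 1L, end = df$end[df$strand == "-"]))
      list(contig = key$contig, plus = plus, minus = minus,
           ambiguous = IRanges::intersect(plus, minus))
    }) %>%
    setNames(unique(sort(genes$contig)))
}

# Sequences (5'->3' on the coding strand) of gene bodies after removing
# opposite-strand overlapped stretches.
nts_segment_seqs <- function(genome, genes) {
  validate_genes(genes, genome)
  ivals <- strand_intervals(genes)
  segs <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gene_ir <- IRanges::IRanges(start = g$start + 1L, end = g$end)
    keep <- IRanges::setdiff(gene_ir, ivals[[g$contig]]$ambiguous)
    if (length(keep) == 0) next
    seq <- contig_seq(genome, g$contig)
    pieces <- substring(seq, IRanges::start(keep), IRanges::end(keep))
    if (g$strand == "-") pieces <- revcomp(pieces)
    segs <- c(segs, pieces)
  }
  segs
}

count_oligos <- function(seqs, width) {
  if (length(seqs) == 0) {
    keys <- if (width == 3) mkAllStrings_acgt(3) else all_dinucs()
    return(setNames(rep(0L, length(keys)), keys))
  }
  f <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = width)
  colSums(f)
}

mkAllStrings_acgt <- function(width) {
  sort(apply(expand.grid(rep(list(DNA_BASES), width)), 1, paste, collapse = ""))
}

#' Census of mutation-class contexts on a strand set
#'
#' Counts trinucleotide (or, with `width = 2`, dinucleotide) occurrences
#' used to normalize mutation counts by sequence opportunity.
#'
#' * `genome_both_strands` — occurrences of each pyrimidine-central
#'   trinucleotide (canonical reference dinucleotide for `width = 2`)
#'   enumerated over both strands of all non-excluded contigs; each
#'   double-stranded window contributes its one pyrimidine-central reading.
#' * `gene_NTS` — literal occurrences on the coding (non-transcribed)
#'   strand of each gene body; `gene_TS` on its complement. Stretches
#'   where genes on opposite strands overlap are excluded (NTS/TS
#'   undefined there). Windows containing N are never counted.
#'
#' @param genome a [uv_genome()].
#' @param regions gene tibble as from [read_genes()]; required for the
#'   gene strand modes, ignored for `genome_both_strands`.
#' @param strand_mode one of `"genome_both_strands"`, `"gene_NTS"`,
#'   `"gene_TS"`.
#' @param width 3 for trinucleotide (SBS) contexts, 2 for dinucleotide
#'   (DBS) contexts.
#' @return tibble with columns `context` and `count` (32 rows for
#'   trinucleotides, 10 for dinucleotides), with the strand mode stored in
#'   the `"strand_mode"` attribute.
#' @export
context_census <- function(genome, regions = NULL,
                           strand_mode = c("genome_both_strands", "gene_NTS", "gene_TS"),
                           width = 3) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(width %in% c(2, 3))
  keys <- if (width == 3) pyrimidine_contexts() else dbs_canonical_refs()
  if (strand_mode == "genome_both_strands") {
    kept <- setdiff(names(genome$contigs), genome$excluded_contigs)
    f <- count_oligos(unname(genome$contigs[kept]), width)
    counts <- f[keys] + f[revcomp(keys)]
    # self-reverse-complementary dinucleotides: fwd occurrence == rev
    # occurrence at the same position; f[key] + f[revcomp(key)] already
    # counts both strand readings
  } else {
    if (is.null(regions)) abort("gene strand censuses need a gene table")
    segs <- nts_segment_seqs(genome, regions)
    if (strand_mode == "gene_TS") segs <- revcomp(segs)
    f <- count_oligos(segs, width)
    counts <- f[keys]
  }
  out <- tibble(context = keys, count = as.numeric(counts))
  attr(out, "strand_mode") <- strand_mode
  out
}
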