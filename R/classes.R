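# Canonical mutation-class encodings: pyrimidine-centric SBS-96 and the
# 78-class doublet (DBS) catalogue with reverse-complement collapse.

DNA_BASES <- c("A", "C", "G", "T")

#' Complement / reverse-complement of nucleotide strings
#'
#' Vectorised over character vectors of equal-length or mixed-length DNA
#' strings (A, C, G, T, N allowed).
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @examples
#' revcomp(c("ACG", "TT"))
#' @export
revcomp <- function(x) {
  out <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(out, "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), character(1))
}

#' @rdname revcomp
#' @export
comp <- function(x) chartr("ACGTN", "TGCAN", x)

#' The six pyrimidine-centric substitution types
#' @return character vector `c("C>A", ..., "T>G")`.
#' @export
sbs_substitutions <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

#' The 96 SBS classes in conventional order
#'
#' Classes are ordered by substitution type (C>A, C>G, C>T, T>A, T>C, T>G),
#' then by 5' flank (A, C, G, T), then 3' flank. Labels use the
#' `"A[C>T]G"` format.
#'
#' @return tibble with columns `substitution`, `context` (pyrimidine-central
#'   trinucleotide) and `class_label`.
#' @export
sbs_classes <- function() {
  grid <- expand.grid(down = DNA_BASES, up = DNA_BASES,
                      substitution = sbs_substitutions(),
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$substitution, sbs_substitutions()),
                     match(grid$up, DNA_BASES), match(grid$down, DNA_BASES)), ]
  ref <- substr(grid$substitution, 1, 1)
  tibble(
    substitution = grid$substitution,
    context = paste0(grid$up, ref, grid$down),
    class_label = paste0(grid$up, "[", grid$substitution, "]", grid$down)
  )
}

#' The 32 pyrimidine-central trinucleotides
#' @return character vector of length 32.
#' @export
pyrimidine_contexts <- function() unique(sbs_classes()$context)

# Ten reference dinucleotides under which all 78 doublet changes are filed.
dbs_canonical_refs <- function() {
  c("AC", "AT", "CC", "CG", "CT", "GC", "TA", "TC", "TG", "TT")
}

all_dinucs <- function() {
  as.vector(outer(DNA_BASES, DNA_BASES, paste0))
}

#' The 78 canonical DBS classes
#'
#' Every doublet change (a 2-mer replaced by a 2-mer differing at both
#' positions) collapses with its reverse complement onto one of 78 classes
#' whose reference dinucleotide belongs to the canonical set
#' AC, AT, CC, CG, CT, GC, TA, TC, TG, TT. For self-reverse-complementary
#' references (AT, CG, GC, TA) the lexicographically smaller alternate
#' breaks the tie.
#'
#' @return tibble with columns `ref`, `alt`, `class_label` (e.g. `"CC>TT"`),
#'   78 rows.
#' @export
dbs_classes <- function() {
  refs <- all_dinucs()
  pairs <- expand.grid(ref = refs, alt = refs, stringsAsFactors = FALSE)
  both_differ <- substr(pairs$ref, 1, 1) != substr(pairs$alt, 1, 1) &
    substr(pairs$ref, 2, 2) != substr(pairs$alt, 2, 2)
  pairs <- pairs[both_differ, ]
  canon <- canonicalize_dbs(pairs$ref, pairs$alt)
  out <- distinct(tibble(ref = canon$ref, alt = canon$alt,
                         class_label = canon$class_label))
  arrange(out, .data$ref, .data$alt)
}

#' Collapse an SBS onto its pyrimidine-centric class
#'
#' A substitution whose reference base is a purine is re-expressed as the
#' reverse-complement change, so that the mutated base is always a
#' pyrimidine at the centre of its trinucleotide context. Vectorised.
#'
#' @param ref_base,alt_base reference and alternate bases (single characters).
#' @param upstream_base,downstream_base flanking bases on the reported
#'   strand; `N` renders the record uncountable.
#' @return tibble with columns `substitution`, `context`, `class_label`,
#'   `pyrimidine_on_reported_strand` (FALSE when the class was obtained by
#'   reverse complementing) and `countable`.
#' @examples
#' canonicalize_sbs("G", "A", "C", "T")  # C>T in ACG, reported on the other strand
#' @export
canonicalize_sbs <- function(ref_base, alt_base, upstream_base, downstream_base) {
  n <- length(ref_base)
  stopifnot(length(alt_base) == n, length(upstream_base) == n,
            length(downstream_base) == n)
  if (any(!ref_base %in% DNA_BASES) || any(!alt_base %in% DNA_BASES)) {
    abort("ref and alt bases must be one of A, C, G, T")
  }
  if (any(ref_base == alt_base)) {
    abort("ref and alt bases must differ")
  }
  is_purine <- ref_base %in% c("A", "G")
  ref <- ifelse(is_purine, comp(ref_base), ref_base)
  alt <- ifelse(is_purine, comp(alt_base), alt_base)
  up <- ifelse(is_purine, comp(downstream_base), upstream_base)
  down <- ifelse(is_purine, comp(upstream_base), downstream_base)
  countable <- up %in% DNA_BASES & down %in% DNA_BASES
  substitution <- paste0(ref, ">", alt)
  context <- ifelse(countable, paste0(up, ref, down), NA_character_)
  tibble(
    substitution = substitution,
    context = context,
    class_label = ifelse(countable,
                         paste0(up, "[", substitution, "]", down),
                         NA_character_),
    pyrimidine_on_reported_strand = !is_purine,
    countable = countable
  )
}

#' Collapse a doublet change onto its canonical DBS class
#'
#' Returns the representation (as given or reverse complemented) whose
#' reference dinucleotide lies in the canonical set; for
#' self-reverse-complementary references the lexicographically smaller
#' alternate is kept. Deterministic for all 144 doublet changes, yielding
#' 78 classes. Vectorised.
#'
#' @param ref_dinuc,alt_dinuc 2-mers over A, C, G, T differing at both
#'   positions.
#' @return tibble with columns `ref`, `alt`, `class_label` and `kept_as_is`
#'   (FALSE when the canonical form is the reverse complement of the input).
#' @examples
#' canonicalize_dbs("GT", "AA")  # AC>TT
#' @export
canonicalize_dbs <- function(ref_dinuc, alt_dinuc) {
  n <- length(ref_dinuc)
  stopifnot(length(alt_dinuc) == n)
  ok_alpha <- grepl("^[ACGT]{2}$", ref_dinuc) & grepl("^[ACGT]{2}$", alt_dinuc)
  if (any(!ok_alpha)) abort("dinucleotides must be 2-mers over A, C, G, T")
  differ_both <- substr(ref_dinuc, 1, 1) != substr(alt_dinuc, 1, 1) &
    substr(ref_dinuc, 2, 2) != substr(alt_dinuc, 2, 2)
  if (any(!differ_both)) {
    abort("ref and alt dinucleotides must differ at both positions")
  }
  canon <- dbs_canonical_refs()
  rc_ref <- revcomp(ref_dinuc)
  rc_alt <- revcomp(alt_dinuc)
  self_rc <- ref_dinuc == rc_ref
  keep <- ifelse(self_rc,
                 alt_dinuc <= rc_alt,
                 ref_dinuc %in% canon)
  ref <- ifelse(keep, ref_dinuc, rc_ref)
  alt <- ifelse(keep, alt_dinuc, rc_alt)
  tibble(
    ref = ref,
    alt = alt,
    class_label = paste0(ref, ">", alt),
    kept_as_is = keep
  )
}
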