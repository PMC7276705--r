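#' Annotate point mutations at the codon level
#'
#' Classifies single-nucleotide substitutions in the coding sequence by their
#' protein-level consequence, recomputing each codon with the single
#' substitution applied in an otherwise wild-type context.
#'
#' @param keys Data frame with columns `pos` (1-based CDS coordinate), `ref`
#'   and `alt` (single bases). `ref` must match the reference CDS.
#' @param ref A [reference_amplicon()].
#' @return The input with added columns `codon_index`, `residue` (equal to the
#'   codon index, 1-based precursor numbering), `ref_aa`, `alt_aa` and
#'   `effect_class` (one of `"synonymous"`, `"missense"`, `"nonsense"`,
#'   `"stop_loss"`).
#' @export
annotate_mutations <- function(keys, ref) {
  stopifnot(all(c("pos", "ref", "alt") %in% names(keys)))
  keys <- as.data.frame(keys)
  L <- cds_length(ref)
  if (nrow(keys) == 0) {
    keys$codon_index <- integer(0); keys$residue <- integer(0)
    keys$ref_aa <- character(0); keys$alt_aa <- character(0)
    keys$effect_class <- character(0)
    return(keys)
  }
  if (any(keys$pos < 1L | keys$pos > L)) {
    stop("mutation position outside the coding sequence")
  }
  cds <- cds_sequence(ref)
  ref_at <- substring(cds, keys$pos, keys$pos)
  if (any(ref_at != keys$ref)) {
    stop("ref base does not match the reference CDS")
  }
  if (any(keys$ref == keys$alt)) stop("ref and alt base must differ")

  codon_index <- (keys$pos - 1L) %/% 3L + 1L
  offset <- (keys$pos - 1L) %% 3L + 1L
  codon_start <- (codon_index - 1L) * 3L + 1L
  ref_codon <- substring(cds, codon_start, codon_start + 2L)
  alt_codon <- ref_codon
  substr(alt_codon, offset, offset) <- keys$alt

  gc <- ref$genetic_code
  ref_aa <- unname(gc[ref_codon])
  alt_aa <- unname(gc[alt_codon])
  effect_class <- ifelse(
    ref_aa == alt_aa, "synonymous",
    ifelse(alt_aa == "*" & ref_aa != "*", "nonsense",
      ifelse(ref_aa == "*" & alt_aa != "*", "stop_loss", "missense")
    )
  )
  keys$codon_index <- codon_index
  keys$residue <- codon_index
  keys$ref_aa <- ref_aa
  keys$alt_aa <- alt_aa
  keys$effect_class <- effect_class
  keys
}

#' @rdname annotate_mutations
#' @param pos,ref_base,alt_base Scalar mutation key for the single-mutation form.
#' @export
annotate_mutation <- function(pos, ref_base, alt_base, ref) {
  annotate_mutations(
    data.frame(pos = as.integer(pos), ref = ref_base, alt = alt_base),
    ref
  )
}

#' Enumerate every possible single-nucleotide substitution in the CDS
#'
#' @param ref A [reference_amplicon()].
#' @return Annotated data frame with one row per (position, alt base) pair;
#'   3 * CDS-length rows.
#' @export
all_cds_mutations <- function(ref) {
  L <- cds_length(ref)
  cds <- cds_sequence(ref)
  ref_base <- strsplit(cds, "")[[1]]
  keys <- data.frame(
    pos = rep(seq_len(L), each = 3L),
    ref = rep(ref_base, each = 3L),
    alt = unlist(lapply(ref_base, function(b) setdiff(BASES, b)), use.names = FALSE)
  )
  annotate_mutations(keys, ref)
}
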