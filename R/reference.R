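#' Reference amplicon
#'
#' Container for the wild-type amplicon against which fragments are aligned:
#' the full sequence (coding sequence plus flanks), the 1-based inclusive
#' bounds of the coding sequence within the amplicon, and the genetic code
#' used for codon-level annotation.
#'
#' @param sequence Single DNA string (alphabet A/C/G/T).
#' @param cds_start,cds_end 1-based inclusive bounds of the CDS within
#'   `sequence`; the CDS length must be a multiple of 3.
#' @param genetic_code Named character vector mapping codons to single-letter
#'   amino acids with `"*"` for stop; defaults to the standard code.
#' @return An object of class `reference_amplicon`.
#' @export
reference_amplicon <- function(sequence, cds_start, cds_end,
                               genetic_code = as.character(Biostrings::GENETIC_CODE)) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) > 0)
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) {
    stop("reference sequence must contain only A, C, G, T")
  }
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  if (cds_start < 1L || cds_end > nchar(sequence) || cds_start > cds_end) {
    stop("CDS bounds fall outside the amplicon")
  }
  if ((cds_end - cds_start + 1L) %% 3L != 0L) {
    stop("CDS length must be a multiple of 3")
  }
  if (is.null(names(genetic_code))) {
    names(genetic_code) <- names(Biostrings::GENETIC_CODE)
  }
  structure(
    list(
      sequence = sequence,
      cds_start = cds_start,
      cds_end = cds_end,
      genetic_code = genetic_code
    ),
    class = "reference_amplicon"
  )
}

#' @export
print.reference_amplicon <- function(x, ...) {
  cat(sprintf(
    "<reference_amplicon> %d bp amplicon, CDS %d-%d (%d bp, %d codons)\n",
    nchar(x$sequence), x$cds_start, x$cds_end,
    cds_length(x), cds_length(x) / 3L
  ))
  invisible(x)
}

#' @rdname reference_amplicon
#' @param ref A `reference_amplicon`.
#' @export
cds_length <- function(ref) ref$cds_end - ref$cds_start + 1L

#' @rdname reference_amplicon
#' @export
cds_sequence <- function(ref) substr(ref$sequence, ref$cds_start, ref$cds_end)

#' Synthetic LamB-like reference amplicon
#'
#' Builds a deterministic random coding sequence with the length of the LamB
#' precursor CDS (1341 bp: ATG start, 445 internal sense codons, one stop),
#' embedded in an amplicon with flanking sequence on both sides, mimicking
#' the PCR amplicon that carries the gene plus vector-derived flanks. The
#' sequence is synthetic: it shares LamB's length and structure, not its
#' actual sequence.
#'
#' @param cds_length CDS length in bp, a multiple of 3 (default 1341).
#' @param flank Flank length on each side in bp (default 100).
#' @param seed Integer seed making the sequence reproducible.
#' @return A [reference_amplicon()].
#' @export
synthetic_reference <- function(cds_length = 1341L, flank = 100L, seed = 20L) {
  stopifnot(cds_length %% 3L == 0L, cds_length >= 6L, flank >= 0L)
  gc <- as.character(Biostrings::GENETIC_CODE)
  names(gc) <- names(Biostrings::GENETIC_CODE)
  sense <- names(gc)[gc != "*"]
  sense <- setdiff(sense, "ATG")  # keep internal ATG out for a cleaner toy CDS
  stops <- names(gc)[gc == "*"]
  with_seed(seed, {
    n_internal <- cds_length / 3L - 2L
    cds <- paste0(
      "ATG",
      paste(sample(sense, n_internal, replace = TRUE), collapse = ""),
      "TAA"
    )
    left <- paste(sample(BASES, flank, replace = TRUE), collapse = "")
    right <- paste(sample(BASES, flank, replace = TRUE), collapse = "")
    reference_amplicon(
      paste0(left, cds, right),
      cds_start = flank + 1L,
      cds_end = flank + cds_length
    )
  })
}

#' Read a reference amplicon from FASTA
#'
#' @param fasta Path to a single-record FASTA file.
#' @param cds_start,cds_end 1-based inclusive CDS bounds within the record.
#' @return A [reference_amplicon()].
#' @export
read_reference <- function(fasta, cds_start, cds_end) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L) stop("expected exactly one FASTA record")
  reference_amplicon(as.character(seqs[[1]]), cds_start, cds_end)
}

#' Write a reference amplicon to FASTA
#'
#' @param ref A [reference_amplicon()].
#' @param path Output FASTA path.
#' @param name Record name.
#' @export
write_reference <- function(ref, path, name = "amplicon") {
  x <- Biostrings::DNAStringSet(ref$sequence)
  names(x) <- sprintf("%s cds=%d-%d", name, ref$cds_start, ref$cds_end)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

## amplicon coordinate of a 1-based CDS position
cds_to_amplicon <- function(ref, pos) ref$cds_start - 1L + pos

## 1-based CDS coordinate of an amplicon position (may fall outside CDS)
amplicon_to_cds <- function(ref, pos) pos - ref$cds_start + 1L
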