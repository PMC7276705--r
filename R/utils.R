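#' @importFrom stats median rbinom rpois rlnorm rmultinom runif setNames
#' @importFrom utils head tail write.table read.delim
#' @import data.table
NULL

BASES <- c("A", "C", "G", "T")

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded package functions do
#' not perturb the caller's random stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Derive a task-specific seed from a global seed
#'
#' Deterministic counter scheme: each (stage, index) pair maps to a distinct
#' seed below 2^31, so replicates are independent but reproducible from a
#' single experiment seed.
#'
#' @param seed Global integer seed.
#' @param stage Character stage label (e.g. `"reads"`).
#' @param index Integer counter within the stage.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage, index = 1L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  val <- (abs(seed) %% 1e6) * 2039 + h * 1009 + index * 7919
  as.integer(val %% 2147483645 + 1)
}

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## cheap stable hash of an R object, for output provenance headers
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 8191)) %% 4294967296)
}
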