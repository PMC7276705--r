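#' Collapse raw read pairs and apply the consensus filter
#'
#' Identical raw read pairs (exact sequence identity of both mates) are
#' grouped into unique read pairs; groups represented by fewer than `min_raw`
#' raw reads are discarded. This is the error-correction step: a true
#' tagmentation fragment is sequenced as many identical copies, whereas a
#' copy carrying a sequencing error forms a rare unique pair that fails the
#' threshold.
#'
#' @param reads data.table with columns `r1`, `r2` and optionally `q1`, `q2`.
#' @param min_raw Minimum raw reads per unique pair (default 5).
#' @return data.table of unique pairs with `r1`, `r2`, `q1`, `q2`,
#'   `raw_count`, ordered by decreasing count. Empty output is permitted.
#' @export
collapse_and_filter <- function(reads, min_raw = 5L) {
  stopifnot(nrow(reads) > 0)
  dt <- data.table::as.data.table(reads)
  if ("q1" %in% names(dt)) {
    out <- dt[, list(raw_count = .N, q1 = q1[1L], q2 = q2[1L]), by = c("r1", "r2")]
  } else {
    out <- dt[, list(raw_count = .N), by = c("r1", "r2")]
  }
  n_all <- nrow(out)
  out <- out[out$raw_count >= min_raw]
  ## constant base quality when the input carries none
  if (!"q1" %in% names(out)) {
    out$q1 <- strrep("I", nchar(out$r1))
    out$q2 <- strrep("I", nchar(out$r2))
  }
  data.table::setattr(out, "n_below_min_raw", n_all - nrow(out))
  data.table::setorderv(out, "raw_count", order = -1L)
  data.table::setcolorder(out, c("r1", "r2", "q1", "q2", "raw_count"))
  out[]
}

## merge one read pair at a specific overlap length; mate 2 already on the
## forward strand; returns NULL if the overlap mismatch fraction is too high
merge_at_overlap <- function(c1, c2, cq1, cq2, o, max_mismatch_frac) {
  n1 <- length(c1); n2 <- length(c2)
  a_idx <- (n1 - o + 1L):n1
  mism <- which(c1[a_idx] != c2[1:o])
  frac <- length(mism) / o
  if (frac > max_mismatch_frac) return(NULL)
  ov <- c1[a_idx]
  if (length(mism) > 0) {
    ## resolve disagreements toward the higher-quality base; mate 1 on ties
    qa <- utf8ToInt(paste(cq1[a_idx][mism], collapse = ""))
    qb <- utf8ToInt(paste(cq2[mism], collapse = ""))
    use_b <- qb > qa
    ov[mism[use_b]] <- c2[mism][use_b]
  }
  merged <- paste(c(
    c1[seq_len(n1 - o)], ov, c2[(o + 1L):n2][seq_len(max(n2 - o, 0L))]
  ), collapse = "")
  list(seq = merged, frac = frac)
}

#' Merge read pairs overlapping at their 3' ends
#'
#' Mate 2 is reverse-complemented to the forward strand and the maximal
#' consistent 3' overlap with mate 1 is sought. Pairs overlapping perfectly
#' are merged directly; overlaps with disagreements are resolved toward the
#' higher-quality base (mate 1 wins ties) provided the mismatch fraction in
#' the overlap does not exceed `max_mismatch_frac`, otherwise the pair is
#' discarded. Pairs with no overlap of at least `min_overlap` bases are
#' emitted as two unmerged segments that are subsequently aligned
#' independently.
#'
#' @param pairs Unique-pair table from [collapse_and_filter()].
#' @param min_overlap Minimum acceptable overlap (default 10).
#' @param max_mismatch_frac Maximum mismatch fraction within the overlap
#'   (default 0.2).
#' @return List with `segments`: data.table (`pair_id`, `seq`, `raw_count`,
#'   `merged`), one row per merged pair or two rows per unmerged pair, and
#'   `n_discarded`: pairs dropped for irreconcilable overlaps.
#' @export
merge_pairs <- function(pairs, min_overlap = 10L, max_mismatch_frac = 0.2) {
  n <- nrow(pairs)
  if (n == 0) {
    return(list(
      segments = data.table::data.table(
        pair_id = integer(0), seq = character(0),
        raw_count = integer(0), merged = logical(0)
      ),
      n_discarded = 0L
    ))
  }
  r1 <- pairs$r1
  r2f <- revcomp(pairs$r2)
  len1 <- nchar(r1)
  len2 <- nchar(r2f)
  merged_seq <- rep(NA_character_, n)
  n_discarded <- 0L

  ## fast path: largest exact overlap, found by vectorised passes over
  ## candidate overlap lengths (largest first)
  pending <- rep(TRUE, n)
  max_o <- max(pmin(len1, len2))
  for (o in if (max_o >= min_overlap) seq(max_o, min_overlap) else integer(0)) {
    cand <- which(pending & pmin(len1, len2) >= o)
    if (length(cand) == 0) next
    hit <- substring(r1[cand], len1[cand] - o + 1L, len1[cand]) ==
      substring(r2f[cand], 1L, o)
    ok <- cand[hit]
    if (length(ok) > 0) {
      merged_seq[ok] <- paste0(r1[ok], substring(r2f[ok], o + 1L, len2[ok]))
      pending[ok] <- FALSE
    }
  }

  ## mismatch-tolerant path for the remainder: candidate overlap lengths are
  ## anchored on the occurrence of mate 1's terminal 8-mer within mate 2, so
  ## genuinely non-overlapping pairs are dismissed without a full scan
  anchor_k <- 8L
  unresolved <- which(pending & pmin(len1, len2) >= max(min_overlap, anchor_k))
  if (length(unresolved) > 0) {
    q1 <- pairs$q1
    q2f <- vapply(strsplit(pairs$q2[unresolved], ""), function(q) {
      paste(rev(q), collapse = "")
    }, character(1))
    anchor <- substring(r1[unresolved], len1[unresolved] - anchor_k + 1L,
                        len1[unresolved])
    for (j in seq_along(unresolved)) {
      i <- unresolved[j]
      hits <- gregexpr(anchor[j], r2f[i], fixed = TRUE)[[1]]
      if (hits[1] == -1L) next
      ## anchor at r2f position s means overlap length o = s + k - 1
      os <- hits + anchor_k - 1L
      os <- os[os >= min_overlap & os <= min(len1[i], len2[i])]
      if (length(os) == 0) next
      c1 <- strsplit(r1[i], "")[[1]]
      c2 <- strsplit(r2f[i], "")[[1]]
      cq1 <- strsplit(q1[i], "")[[1]]
      cq2 <- strsplit(q2f[j], "")[[1]]
      best <- NULL
      for (o in sort(os, decreasing = TRUE)) {
        m <- merge_at_overlap(c1, c2, cq1, cq2, o, max_mismatch_frac)
        if (!is.null(m) && (is.null(best) || m$frac < best$frac)) best <- m
      }
      if (!is.null(best)) {
        merged_seq[i] <- best$seq
      } else {
        ## an anchored overlap exists but disagrees too much: discard the pair
        merged_seq[i] <- ""
        n_discarded <- n_discarded + 1L
      }
    }
  }

  disc <- !is.na(merged_seq) & merged_seq == ""
  merged_seq[disc] <- NA_character_
  is_merged <- !is.na(merged_seq)
  ## unmerged pairs: short mates can simply lack overlap; emit both segments
  unm <- which(!is_merged & !disc)
  segments <- data.table::rbindlist(list(
    data.table::data.table(
      pair_id = which(is_merged),
      seq = merged_seq[is_merged],
      raw_count = pairs$raw_count[is_merged],
      merged = TRUE
    ),
    data.table::data.table(
      pair_id = rep(unm, 2L),
      seq = c(r1[unm], r2f[unm]),
      raw_count = rep(pairs$raw_count[unm], 2L),
      merged = FALSE
    )
  ))
  data.table::setorderv(segments, "pair_id")
  list(segments = segments[], n_discarded = n_discarded)
}

## k-mer index of the reference: position of each k-mer (first occurrence)
ref_kmer_index <- function(ref_seq, k) {
  A <- nchar(ref_seq)
  starts <- seq_len(A - k + 1L)
  kmers <- substring(ref_seq, starts, starts + k - 1L)
  list(kmers = kmers, k = k)
}

## per-sequence mismatch positions against an equal-length reference substring
mismatch_positions <- function(seq, refsub) {
  a <- utf8ToInt(seq)
  b <- utf8ToInt(refsub)
  which(a != b)
}

#' Align fragment sequences to the reference by seed-and-extend
#'
#' Substitution-only (ungapped) alignment: a k-mer seed (default k = 16,
#' taken from either end or the middle of the fragment, with a fallback to
#' k = 12) locates
#' the candidate offset by exact match against the reference; the fragment is
#' then compared base-by-base over its full length. Both orientations are
#' tried and hits on the reverse strand are reported after
#' reverse-complementing to the forward strand. Fragments whose best
#' candidate exceeds `max_mismatch_frac` mismatches, or with no seed match,
#' are rejected and counted.
#'
#' @param seqs Character vector of fragment sequences.
#' @param ref A [reference_amplicon()].
#' @param k,k_fallback Seed k-mer sizes (defaults 16 and 12).
#' @param max_mismatch_frac Maximum fraction of mismatching bases (default 0.1).
#' @return List with `alignments`: data.table (`seq_id`, `start`, `end`,
#'   `strand`, `n_mismatch`, `aligned`), spans 1-based inclusive on the
#'   amplicon, and `substitutions`: data.table (`seq_id`, `pos`, `ref`,
#'   `alt`) in amplicon coordinates.
#' @export
align_fragments <- function(seqs, ref, k = 16L, k_fallback = 12L,
                            max_mismatch_frac = 0.1) {
  n <- length(seqs)
  ref_seq <- ref$sequence
  A <- nchar(ref_seq)
  out_start <- rep(NA_integer_, n)
  out_strand <- rep(NA_character_, n)
  out_nmis <- rep(NA_integer_, n)
  len <- nchar(seqs)
  rc <- revcomp(seqs)

  idx16 <- ref_kmer_index(ref_seq, k)
  idx12 <- if (k_fallback < k) ref_kmer_index(ref_seq, k_fallback) else NULL

  ## substitution rows accumulate as flat vectors; one table is built at the end
  acc_id <- vector("list", 16L)
  acc_off <- vector("list", 16L)
  acc_n <- 0L

  try_attempt <- function(unres, oriented, kindex, anchor) {
    kk <- kindex$k
    cand_ok <- unres[len[unres] >= kk]
    if (length(cand_ok) == 0) return(invisible(NULL))
    s <- oriented[cand_ok]
    ## seed k-mer taken from the start, end or middle of the fragment
    off <- switch(anchor,
      start = rep(1L, length(cand_ok)),
      end = len[cand_ok] - kk + 1L,
      mid = pmax(1L, (len[cand_ok] - kk) %/% 2L + 1L)
    )
    seed <- substring(s, off, off + kk - 1L)
    hit <- match(seed, kindex$kmers)
    start <- hit - (off - 1L)
    valid <- !is.na(start) & start >= 1L & (start + len[cand_ok] - 1L) <= A
    cand <- cand_ok[valid]
    if (length(cand) == 0) return(invisible(NULL))
    st <- start[valid]
    refsub <- substring(ref_seq, st, st + len[cand] - 1L)
    sc <- oriented[cand]
    exact <- sc == refsub
    acc <- cand[exact]
    if (length(acc) > 0) {
      out_start[acc] <<- st[exact]
      out_nmis[acc] <<- 0L
    }
    ## inexact candidates: count and locate mismatches per sequence
    inex <- which(!exact)
    if (length(inex) > 0) {
      offs_l <- vector("list", length(inex))
      nm <- integer(length(inex))
      ok <- logical(length(inex))
      for (jj in seq_along(inex)) {
        j <- inex[jj]
        mp <- mismatch_positions(sc[j], refsub[j])
        if (length(mp) / len[cand[j]] <= max_mismatch_frac) {
          ok[jj] <- TRUE
          nm[jj] <- length(mp)
          offs_l[[jj]] <- mp
        }
      }
      hit_ids <- cand[inex[ok]]
      out_start[hit_ids] <<- st[inex[ok]]
      out_nmis[hit_ids] <<- nm[ok]
      if (length(hit_ids) > 0) {
        acc_n <<- acc_n + 1L
        acc_id[[acc_n]] <<- rep(hit_ids, nm[ok])
        acc_off[[acc_n]] <<- unlist(offs_l[ok], use.names = FALSE)
      }
    }
    invisible(NULL)
  }

  attempts <- list()
  for (kindex in c(list(idx16), if (!is.null(idx12)) list(idx12))) {
    for (anchor in c("start", "end", "mid")) {
      for (fwd in c(TRUE, FALSE)) {
        attempts[[length(attempts) + 1L]] <-
          list(fwd = fwd, kindex = kindex, anchor = anchor)
      }
    }
  }
  for (at in attempts) {
    unres <- which(is.na(out_start))
    if (length(unres) == 0) break
    before <- is.na(out_start)
    try_attempt(unres, if (at$fwd) seqs else rc, at$kindex, at$anchor)
    newly <- which(before & !is.na(out_start))
    out_strand[newly] <- if (at$fwd) "+" else "-"
  }

  aligned <- !is.na(out_start)
  sub_id <- unlist(acc_id[seq_len(acc_n)], use.names = FALSE)
  if (length(sub_id) > 0) {
    sub_off <- unlist(acc_off[seq_len(acc_n)], use.names = FALSE)
    pos <- out_start[sub_id] + sub_off - 1L
    oriented <- ifelse(out_strand[sub_id] == "+", seqs[sub_id], rc[sub_id])
    subs <- data.table::data.table(
      seq_id = sub_id,
      pos = pos,
      ref = substring(ref_seq, pos, pos),
      alt = substring(oriented, sub_off, sub_off)
    )
    data.table::setorderv(subs, c("seq_id", "pos"))
  } else {
    subs <- data.table::data.table(
      seq_id = integer(0), pos = integer(0),
      ref = character(0), alt = character(0)
    )
  }
  list(
    alignments = data.table::data.table(
      seq_id = seq_len(n),
      start = out_start,
      end = out_start + len - 1L,
      strand = out_strand,
      n_mismatch = out_nmis,
      aligned = aligned
    ),
    substitutions = subs
  )
}

#' Deduplicate aligned fragments into unique fragments
#'
#' Fragments are grouped by their identifier (start, end, substitution set);
#' each group is a single transposition event and is emitted once, with raw
#' multiplicities summed.
#'
#' @param alignments,substitutions Output of [align_fragments()].
#' @param raw_count Raw-read multiplicity per aligned sequence (defaults to 1).
#' @return data.table of unique fragments: `start`, `end`, `subs` (canonical
#'   `"pos:ref>alt"` signature, `""` if none), `n_sub`, `raw_count`.
#' @export
dedup_fragments <- function(alignments, substitutions, raw_count = NULL) {
  al <- data.table::as.data.table(alignments)[alignments$aligned]
  if (is.null(raw_count)) raw_count <- rep(1L, nrow(alignments))
  al$raw_count <- raw_count[al$seq_id]
  if (nrow(substitutions) > 0) {
    sig <- substitutions[, list(
      subs = paste(sprintf("%d:%s>%s", pos, ref, alt), collapse = ";")
    ), by = "seq_id"]
    al <- merge(al, sig, by = "seq_id", all.x = TRUE)
  } else {
    al$subs <- NA_character_
  }
  al$subs[is.na(al$subs)] <- ""
  out <- al[, list(raw_count = sum(raw_count)), by = c("start", "end", "subs")]
  out$n_sub <- ifelse(out$subs == "", 0L,
    lengths(strsplit(out$subs, ";", fixed = TRUE))
  )
  data.table::setorderv(out, c("start", "end", "subs"))
  out[]
}

## expand a unique-fragment "subs" signature into a table
parse_subs <- function(fragments) {
  has <- which(fragments$subs != "")
  if (length(has) == 0) {
    return(data.table::data.table(
      frag_id = integer(0), pos = integer(0),
      ref = character(0), alt = character(0)
    ))
  }
  parts <- strsplit(fragments$subs[has], ";", fixed = TRUE)
  flat <- unlist(parts, use.names = FALSE)
  m <- regmatches(flat, regexec("^(\\d+):([ACGT])>([ACGT])$", flat))
  data.table::data.table(
    frag_id = rep(has, lengths(parts)),
    pos = as.integer(vapply(m, `[`, character(1), 2L)),
    ref = vapply(m, `[`, character(1), 3L),
    alt = vapply(m, `[`, character(1), 4L)
  )
}

#' Per-position base counts over unique fragments
#'
#' Every unique fragment contributes exactly one count (regardless of its raw
#' multiplicity) to the base it carries at every position it covers, so that
#' per-position base counts sum to fragment coverage.
#'
#' @param fragments Unique-fragment table from [dedup_fragments()].
#' @param ref A [reference_amplicon()].
#' @return A `count_table`: data.frame with `position` (1-based amplicon),
#'   `ref_base` and columns `A`, `C`, `G`, `T`.
#' @export
count_bases <- function(fragments, ref) {
  A <- nchar(ref$sequence)
  if (nrow(fragments) > 0 &&
      (min(fragments$start) < 1L || max(fragments$end) > A)) {
    stop("fragment span outside the amplicon")
  }
  cov <- cumsum(
    tabulate(fragments$start, nbins = A) -
      tabulate(pmin(fragments$end + 1L, A + 1L), nbins = A + 1L)[seq_len(A)]
  )
  counts <- matrix(0L, nrow = A, ncol = 4L, dimnames = list(NULL, BASES))
  subs <- parse_subs(fragments)
  if (nrow(subs) > 0) {
    bad <- subs$pos < fragments$start[subs$frag_id] |
      subs$pos > fragments$end[subs$frag_id]
    if (any(bad)) stop("substitution outside its fragment span")
    tal <- subs[, list(n = .N), by = c("pos", "alt")]
    counts[cbind(tal$pos, match(tal$alt, BASES))] <- tal$n
  }
  ref_chars <- strsplit(ref$sequence, "")[[1]]
  n_sub_at <- if (nrow(subs) > 0) {
    tabulate(subs$pos, nbins = A)
  } else {
    integer(A)
  }
  counts[cbind(seq_len(A), match(ref_chars, BASES))] <- cov - n_sub_at
  out <- data.frame(
    position = seq_len(A),
    ref_base = ref_chars,
    counts,
    stringsAsFactors = FALSE
  )
  class(out) <- c("count_table", "data.frame")
  attr(out, "ref_sequence") <- ref$sequence
  out
}

#' Process one sequencing sample into unique fragments and base counts
#'
#' Runs the full consensus chain: collapse raw pairs and apply the minimum
#' raw-read filter, merge overlapping mates, align to the reference, group
#' into unique fragments and tally per-position base counts.
#'
#' @param reads Raw read-pair data.table (`r1`, `r2`, optionally `q1`, `q2`).
#' @param ref A [reference_amplicon()].
#' @param min_raw Minimum raw reads per unique pair (default 5).
#' @param min_overlap,merge_max_mismatch_frac Merge parameters.
#' @param max_mismatch_frac Alignment rejection threshold (default 0.1).
#' @return List with `fragments`, `counts` and `drops` (named integer vector
#'   of pairs/segments removed at each stage).
#' @export
process_sample <- function(reads, ref, min_raw = 5L,
                           min_overlap = 10L, merge_max_mismatch_frac = 0.2,
                           max_mismatch_frac = 0.1) {
  pairs <- collapse_and_filter(reads, min_raw = min_raw)
  mg <- merge_pairs(pairs, min_overlap = min_overlap,
                    max_mismatch_frac = merge_max_mismatch_frac)
  seg <- mg$segments
  al <- align_fragments(seg$seq, ref, max_mismatch_frac = max_mismatch_frac)
  fragments <- dedup_fragments(al$alignments, al$substitutions,
                               raw_count = seg$raw_count)
  counts <- count_bases(fragments, ref)
  list(
    fragments = fragments,
    counts = counts,
    drops = c(
      raw_reads = nrow(reads),
      unique_pairs = nrow(pairs),
      pairs_below_min_raw = attr(pairs, "n_below_min_raw"),
      merged = sum(seg$merged),
      unmerged_segments = sum(!seg$merged),
      discarded_overlap = mg$n_discarded,
      unaligned = sum(!al$alignments$aligned)
    )
  )
}

#' Estimate the per-base mutation rate from aligned fragments
#'
#' Mismatches in successfully aligned fragments divided by the number of
#' aligned bases, restricted (by default) to positions within the coding
#' sequence, where the error-prone PCR operates. With sequencing error
#' disabled this recovers the library's per-base substitution rate.
#'
#' @param fragments Unique-fragment table from [dedup_fragments()].
#' @param ref A [reference_amplicon()].
#' @param cds_only Restrict the tally to CDS positions (default TRUE).
#' @param weight_by_raw Weight fragments by raw multiplicity (default FALSE:
#'   each unique fragment counts once, matching the counting scheme).
#' @return List with `rate`, `n_mismatch`, `n_bases`, `se` (binomial
#'   standard error).
#' @export
estimate_mutation_rate <- function(fragments, ref, cds_only = TRUE,
                                   weight_by_raw = FALSE) {
  w <- if (weight_by_raw) fragments$raw_count else rep(1L, nrow(fragments))
  lo <- if (cds_only) ref$cds_start else 1L
  hi <- if (cds_only) ref$cds_end else nchar(ref$sequence)
  ov_lo <- pmax(fragments$start, lo)
  ov_hi <- pmin(fragments$end, hi)
  n_bases <- sum(pmax(ov_hi - ov_lo + 1L, 0L) * w)
  subs <- parse_subs(fragments)
  in_win <- subs$pos >= lo & subs$pos <= hi
  n_mis <- sum(w[subs$frag_id[in_win]])
  rate <- n_mis / n_bases
  list(
    rate = rate,
    n_mismatch = n_mis,
    n_bases = n_bases,
    se = sqrt(rate * (1 - rate) / n_bases)
  )
}

#' Write / read unique-fragment and count tables as TSV
#'
#' Coordinates in the emitted files are 1-based inclusive.
#'
#' @param x Table to write.
#' @param path File path.
#' @param header Optional comment lines (prefixed `#`) for provenance.
#' @export
write_tsv <- function(x, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE)
}
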