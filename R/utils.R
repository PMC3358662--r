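# Internal helpers shared across modules. Coordinates are 0-based half-open
# everywhere inside the package; the SAM boundary converts.

#' @importFrom rlang .data %||%
#' @importFrom tibble tibble as_tibble
NULL

# reverse-complement for plain character vectors (A/C/G/T/N only)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# integer codes for fast per-position comparison
seq_ints <- function(s) utf8ToInt(s)

# 0-based offsets (within `query`) at which query and window disagree, when
# query positions [q_lo, q_hi) are laid against window positions starting at
# w_at (0-based). Caller guarantees the slice is inside the window.
mm_offsets_at <- function(query_int, window_int, q_lo, q_hi, w_at) {
  if (q_hi <= q_lo) return(integer(0))
  qa <- query_int[(q_lo + 1L):q_hi]
  wa <- window_int[(w_at + 1L):(w_at + (q_hi - q_lo))]
  which(qa != wa) + q_lo - 1L
}

# mismatch count of a full candidate (1 or 2 blocks) against a window string
count_block_mismatches <- function(query_int, window_int, starts, ends) {
  q0 <- 0L
  n <- 0L
  for (b in seq_along(starts)) {
    len <- ends[b] - starts[b]
    n <- n + length(mm_offsets_at(query_int, window_int, q0, q0 + len, starts[b]))
    q0 <- q0 + len
  }
  n
}

# outermost genomic end of an alignment row set (end2 where present)
outer_end <- function(end1, end2) ifelse(is.na(end2), end1, end2)

# canonical empty alignment tibble
empty_alignments <- function() {
  tibble(
    read_id = character(), rname = character(), strand = character(),
    start1 = integer(), end1 = integer(),
    start2 = integer(), end2 = integer(),
    mismatches = integer(), provenance = character()
  )
}

# validate structural invariants of an alignment tibble; returns invisibly
validate_alignments <- function(aln, read_lengths = NULL) {
  if (nrow(aln) == 0) return(invisible(aln))
  stopifnot(
    all(aln$end1 > aln$start1),
    all(is.na(aln$start2) | (aln$start2 >= aln$end1)),
    all(is.na(aln$start2) | (aln$end2 > aln$start2)),
    all(aln$mismatches >= 0L, na.rm = TRUE)
  )
  if (!is.null(read_lengths)) {
    bl <- (aln$end1 - aln$start1) +
      ifelse(is.na(aln$start2), 0L, aln$end2 - aln$start2)
    l <- unname(read_lengths[aln$read_id])
    bad <- which(!is.na(l) & bl != l)
    if (length(bad)) {
      stop("block lengths do not sum to read length for read(s): ",
           paste(utils::head(aln$read_id[bad], 3), collapse = ", "))
    }
  }
  invisible(aln)
}

# deterministic ordering used for all tie-breaking on alignment tables
order_alignments <- function(aln) {
  order(aln$mismatches, aln$rname, aln$start1,
        ifelse(is.na(aln$start2), -1L, aln$start2), aln$read_id,
        method = "radix")
}

local_seed <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(as.integer(seed), .local_envir = env)
  invisible(NULL)
}
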