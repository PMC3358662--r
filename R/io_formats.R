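# Standard-format I/O: FASTA references, FASTQ reads, SAM alignments.
#
# Alignments travel through the package as tibbles with one row per placement:
#   read_id, rname, strand ("+"/"-"),
#   start1/end1   first (or only) aligned block, 0-based half-open,
#   start2/end2   second block of a split alignment (NA for full alignments),
#   mismatches    edit count under the mismatch-only model (NA if unknown),
#   provenance    "initial", "realigned" or "splice_extended".
# For a split alignment the splice site is (end1 - 1, start2): the last
# aligned base before the intron and the first aligned base after it.

#' Read a reference genome from FASTA
#'
#' Loads all records, uppercases the sequences and enforces the A/C/G/T/N
#' alphabet. Multi-line sequences are concatenated.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] (one element per reference
#'   sequence); lengths are available via [Biostrings::width()].
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(raw) == 0) stop("no FASTA records in ", path)
  names(raw) <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(names(raw))) {
    stop("duplicate reference names in ", path, ": ",
         paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "))
  }
  seqs <- toupper(as.character(raw))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record '", names(raw)[!nzchar(seqs)][1], "'")
  }
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("invalid character '", substr(seqs[i], bad[i], bad[i]),
         "' at position ", bad[i], " of record '", names(raw)[i],
         "' (alphabet is A,C,G,T,N)")
  }
  Biostrings::DNAStringSet(stats::setNames(seqs, names(raw)))
}

#' Read sequencing reads from FASTQ
#'
#' @param path Path to a FASTQ file.
#' @param min_length Reads shorter than this are dropped with a warning
#'   (`NULL` keeps everything). The refinement pipeline requires a read to be
#'   at least twice the minimum seed-fragment length.
#' @return A tibble with columns `read_id`, `bases`, `qualities`.
#' @export
read_reads_fastq <- function(path, min_length = NULL) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  q <- S4Vectors::mcols(x)$qualities
  out <- tibble(
    read_id = sub("\\s.*$", "", names(x)),
    bases = unname(toupper(as.character(x))),
    qualities = if (is.null(q)) NA_character_ else unname(as.character(q))
  )
  if (!is.null(min_length)) {
    short <- nchar(out$bases) < min_length
    if (any(short)) {
      warning(sum(short), " read(s) shorter than ", min_length,
              " bp were rejected")
      out <- out[!short, , drop = FALSE]
    }
  }
  out
}

#' Write reads to FASTQ
#'
#' @param reads Tibble with `read_id`, `bases` and optionally `qualities`.
#' @param path Output path.
#' @export
write_reads_fastq <- function(reads, path) {
  qual <- reads$qualities
  if (is.null(qual) || all(is.na(qual))) {
    qual <- vapply(nchar(reads$bases),
                   function(n) strrep("I", n), character(1))
  }
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$bases, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

cigar_ops <- function(cigar) {
  m <- gregexpr("(\\d+)([A-Z=])", cigar)[[1]]
  if (m[1] == -1) return(NULL)
  toks <- regmatches(cigar, gregexpr("(\\d+)([A-Z=])", cigar))[[1]]
  list(len = as.integer(sub("[A-Z=]$", "", toks)),
       op = sub("^\\d+", "", toks))
}

# CIGAR string (POS 1-based) -> list(blocks 0-based half-open) or a reason
# string when the record uses ops outside the mismatch-only model.
blocks_from_cigar <- function(pos1, cigar) {
  ops <- cigar_ops(cigar)
  if (is.null(ops)) return("unparsable CIGAR")
  if (any(!ops$op %in% c("M", "=", "X", "N"))) {
    return(paste0("unsupported CIGAR op '",
                  ops$op[!ops$op %in% c("M", "=", "X", "N")][1], "'"))
  }
  if (sum(ops$op == "N") > 1) return("more than one splice gap")
  at <- pos1 - 1L
  starts <- integer(0); ends <- integer(0)
  open <- NA_integer_
  for (i in seq_along(ops$op)) {
    if (ops$op[i] == "N") {
      if (is.na(open)) return("leading splice gap")
      starts <- c(starts, open); ends <- c(ends, at)
      open <- NA_integer_
      at <- at + ops$len[i]
    } else {
      if (is.na(open)) open <- at
      at <- at + ops$len[i]
    }
  }
  if (!is.na(open)) { starts <- c(starts, open); ends <- c(ends, at) }
  list(starts = starts, ends = ends)
}

cigar_from_blocks <- function(start1, end1, start2, end2) {
  if (is.na(start2)) {
    paste0(end1 - start1, "M")
  } else {
    paste0(end1 - start1, "M", start2 - end1, "N", end2 - start2, "M")
  }
}

#' Read an initial mapping from SAM
#'
#' Converts single-end SAM records to 0-based half-open blocks. `M`, `=` and
#' `X` consume read and reference, a single `N` opens the splice gap. Records
#' with clips, indels or other ops are routed to the re-alignment pool (the
#' alignment model is mismatch-only), with a warning.
#'
#' @param path Path to a SAM file.
#' @param unique_only When `TRUE` (the default, matching the rule that only
#'   unique initial mappings seed contexts), reads with more than one mapped
#'   record are returned in the `ambiguous` pool and contribute no alignment
#'   rows.
#' @return A list with elements `alignments` (tibble, see package docs),
#'   `unmapped` (ids of flagged-unmapped reads), `ambiguous` (ids of
#'   multi-mapped reads when `unique_only`), and `rejected` (ids whose records
#'   were skipped because of unsupported CIGAR ops).
#' @export
read_alignments_sam <- function(path, unique_only = TRUE) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    return(list(alignments = empty_alignments(), unmapped = character(0),
                ambiguous = character(0), rejected = character(0)))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  qname <- vapply(f, `[`, "", 1)
  flag <- as.integer(vapply(f, `[`, "", 2))
  rname <- vapply(f, `[`, "", 3)
  pos <- as.integer(vapply(f, `[`, "", 4))
  cigar <- vapply(f, `[`, "", 6)
  nm <- suppressWarnings(as.integer(sub(".*\tNM:i:(-?\\d+).*", "\\1",
                                        ifelse(grepl("\tNM:i:", body), body, NA))))

  unmapped <- unique(qname[bitwAnd(flag, 4L) != 0L])
  mapped <- bitwAnd(flag, 4L) == 0L

  idx <- which(mapped)
  n <- length(idx)
  start1 <- integer(n); end1 <- integer(n)
  start2 <- rep(NA_integer_, n); end2 <- rep(NA_integer_, n)
  ok <- logical(n)
  reasons <- character(0); rejected <- character(0)
  # fast paths for the two CIGAR shapes the model produces
  simple <- grepl("^\\d+M$", cigar[idx])
  split2 <- grepl("^\\d+M\\d+N\\d+M$", cigar[idx])
  if (any(simple)) {
    w <- which(simple)
    len <- as.integer(sub("M$", "", cigar[idx][w]))
    start1[w] <- pos[idx][w] - 1L
    end1[w] <- start1[w] + len
    ok[w] <- TRUE
  }
  if (any(split2)) {
    w <- which(split2)
    m <- regmatches(cigar[idx][w],
                    regexec("^(\\d+)M(\\d+)N(\\d+)M$", cigar[idx][w]))
    l1 <- as.integer(vapply(m, `[`, "", 2))
    ln <- as.integer(vapply(m, `[`, "", 3))
    l2 <- as.integer(vapply(m, `[`, "", 4))
    start1[w] <- pos[idx][w] - 1L
    end1[w] <- start1[w] + l1
    start2[w] <- end1[w] + ln
    end2[w] <- start2[w] + l2
    ok[w] <- TRUE
  }
  for (z in which(!simple & !split2)) {
    b <- blocks_from_cigar(pos[idx][z], cigar[idx][z])
    if (is.character(b)) {
      reasons <- c(reasons, paste0("read '", qname[idx][z], "': ", b))
      rejected <- c(rejected, qname[idx][z])
      next
    }
    start1[z] <- b$starts[1]; end1[z] <- b$ends[1]
    if (length(b$starts) == 2) { start2[z] <- b$starts[2]; end2[z] <- b$ends[2] }
    ok[z] <- TRUE
  }
  if (length(reasons)) {
    warning(length(reasons), " record(s) moved to the re-alignment pool (",
            reasons[1], if (length(reasons) > 1) "; ..." else "", ")",
            call. = FALSE)
  }
  aln <- tibble(
    read_id = qname[idx][ok], rname = rname[idx][ok],
    strand = ifelse(bitwAnd(flag[idx][ok], 16L) != 0L, "-", "+"),
    start1 = start1[ok], end1 = end1[ok],
    start2 = start2[ok], end2 = end2[ok],
    mismatches = nm[idx][ok], provenance = "initial")
  rejected <- unique(rejected)

  ambiguous <- character(0)
  if (unique_only && nrow(aln) > 0) {
    multi <- unique(aln$read_id[duplicated(aln$read_id)])
    ambiguous <- multi
    aln <- aln[!aln$read_id %in% multi, , drop = FALSE]
  }
  # a read rejected on one record but mapped on another keeps its alignment
  rejected <- setdiff(rejected, aln$read_id)
  unmapped <- setdiff(unmapped, c(aln$read_id, ambiguous))
  list(alignments = aln, unmapped = unmapped, ambiguous = ambiguous,
       rejected = setdiff(rejected, ambiguous))
}

#' Write alignments to SAM
#'
#' Split alignments are encoded with an `N` gap in the CIGAR. Output records
#' are sorted by (reference, start, read id) for determinism. Tags: `NM`
#' (mismatches), `XS` (provenance), `XC` (context id, when present).
#'
#' @param alignments Alignment tibble (one row per read for a final mapping).
#' @param references Named [Biostrings::DNAStringSet] of reference sequences.
#' @param path Output path.
#' @param reads Optional tibble of reads (`read_id`, `bases`, `qualities`)
#'   used to fill the SEQ/QUAL fields; reverse-strand records are
#'   reverse-complemented to reference-forward orientation as SAM requires.
#' @param unmapped Optional character vector of read ids emitted as
#'   flag-4 records.
#' @export
write_alignments_sam <- function(alignments, references, path,
                                 reads = NULL, unmapped = NULL) {
  unknown <- setdiff(unique(alignments$rname), names(references))
  if (length(unknown)) {
    stop("alignment(s) refer to unknown reference(s): ",
         paste(unknown, collapse = ", "))
  }
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(references),
                  "\tLN:", Biostrings::width(references)))
  seq_of <- NULL
  qual_of <- NULL
  if (!is.null(reads)) {
    seq_of <- stats::setNames(reads$bases, reads$read_id)
    if (!is.null(reads$qualities)) {
      qual_of <- stats::setNames(reads$qualities, reads$read_id)
    }
  }
  recs <- character(0)
  if (nrow(alignments) > 0) {
    a <- alignments[order(alignments$rname, alignments$start1,
                          alignments$read_id, method = "radix"), ]
    cig <- mapply(cigar_from_blocks, a$start1, a$end1, a$start2, a$end2)
    seqf <- rep("*", nrow(a)); qualf <- rep("*", nrow(a))
    if (!is.null(seq_of)) {
      hit <- a$read_id %in% names(seq_of)
      seqf[hit] <- unname(seq_of[a$read_id[hit]])
      rc <- hit & a$strand == "-"
      if (any(rc)) seqf[rc] <- revcomp(seqf[rc])
      if (!is.null(qual_of)) {
        qh <- hit & !is.na(qual_of[a$read_id])
        qualf[qh] <- unname(qual_of[a$read_id[qh]])
        if (any(rc)) {
          qualf[rc & qh] <- vapply(qualf[rc & qh], function(q)
            paste(rev(strsplit(q, "")[[1]]), collapse = ""), character(1))
        }
      }
    }
    tags <- paste0("NM:i:", ifelse(is.na(a$mismatches), 0L, a$mismatches),
                   "\tXS:Z:", a$provenance)
    if ("context_id" %in% names(a)) {
      tags <- paste0(tags, "\tXC:Z:", a$context_id)
    }
    recs <- paste(a$read_id,
                  ifelse(a$strand == "-", 16L, 0L),
                  a$rname, a$start1 + 1L, 255L, cig, "*", 0L, 0L,
                  seqf, qualf, tags, sep = "\t")
  }
  urecs <- character(0)
  if (length(unmapped)) {
    us <- sort(unmapped)
    useq <- rep("*", length(us)); uq <- rep("*", length(us))
    if (!is.null(seq_of)) {
      hit <- us %in% names(seq_of)
      useq[hit] <- unname(seq_of[us[hit]])
    }
    urecs <- paste(us, 4L, "*", 0L, 0L, "*", "*", 0L, 0L, useq, uq, sep = "\t")
  }
  writeLines(c(hdr, recs, urecs), path)
  invisible(path)
}
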