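# Expression contexts: maximal clusters of mapped reads separated by at
# least d_min on the reference. Each context later gets its own re-alignment
# window and its own ambiguity resolution.

#' Cluster mapped reads into expression contexts
#'
#' Reads whose start or end positions lie within `d_min` of each other are
#' collected into the same context; equivalently, contexts are the connected
#' components of that distance relation, computed per reference with a single
#' sorted sweep. A split read's intronic gap belongs to its span, so a
#' context may bridge an unmapped stretch larger than `d_min` when that
#' stretch is the spliced-out part of a read.
#'
#' @param alignments Alignment tibble (typically the unique records of the
#'   initial mapping).
#' @param d_min Minimum separation between contexts in bp (default 10 kb).
#' @return A tibble with one row per context: `context_id`, `rname`,
#'   `start`, `end` (0-based half-open span covering all member blocks) and
#'   the member `read_ids` (list-column).
#' @export
build_contexts <- function(alignments, d_min = 10000L) {
  stopifnot(d_min > 0)
  if (nrow(alignments) == 0) {
    return(tibble(context_id = character(), rname = character(),
                  start = integer(), end = integer(), read_ids = list()))
  }
  a <- tibble(
    read_id = alignments$read_id, rname = alignments$rname,
    start = alignments$start1,
    end = outer_end(alignments$end1, alignments$end2)
  )
  a <- a[order(a$rname, a$start, a$end, method = "radix"), ]
  out <- vector("list", 0)
  for (rn in unique(a$rname)) {
    x <- a[a$rname == rn, ]
    cum_end <- cummax(x$end)
    # new cluster when the gap to everything before exceeds d_min
    brk <- c(TRUE, x$start[-1] - cum_end[-nrow(x)] > d_min)
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      m <- x[grp == g, ]
      out[[length(out) + 1]] <- tibble(
        rname = rn, start = min(m$start), end = max(m$end),
        read_ids = list(unique(m$read_id)))
    }
  }
  res <- dplyr::bind_rows(out)
  res <- res[order(res$rname, res$start, method = "radix"), ]
  dplyr::mutate(res, context_id = sprintf("ctx%04d", dplyr::row_number()),
                .before = 1)
}

#' Assign alignments to contexts
#'
#' @param alignments Alignment tibble.
#' @param contexts Context tibble from [build_contexts()].
#' @return `alignments` with a `context_id` column (NA when an alignment
#'   falls outside every context span).
#' @export
assign_contexts <- function(alignments, contexts) {
  if (nrow(alignments) == 0) {
    return(dplyr::mutate(alignments, context_id = character(0)))
  }
  ctx <- rep(NA_character_, nrow(alignments))
  ends <- outer_end(alignments$end1, alignments$end2)
  for (i in seq_len(nrow(contexts))) {
    hit <- alignments$rname == contexts$rname[i] &
      alignments$start1 >= contexts$start[i] &
      ends <= contexts$end[i]
    ctx[hit] <- contexts$context_id[i]
  }
  dplyr::mutate(alignments, context_id = ctx)
}

#' Extract the padded genomic window of a context
#'
#' @param context One row of the context tibble (or anything with `rname`,
#'   `start`, `end`).
#' @param references Named [Biostrings::DNAStringSet].
#' @param pad Extra bp on each side (clipped at the chromosome bounds);
#'   defaults to 0. The refinement pipeline pads by the read length so that
#'   junction anchors at the context edge stay alignable.
#' @return A list with `seq` (character), `offset` (genomic position of
#'   window position 0) and `rname`; window-local position `p` corresponds
#'   to genomic position `p + offset`.
#' @export
context_window <- function(context, references, pad = 0L) {
  stopifnot(pad >= 0)
  rn <- context$rname[1]
  if (!rn %in% names(references)) stop("unknown reference: ", rn)
  len <- Biostrings::width(references)[names(references) == rn]
  w0 <- max(0L, context$start[1] - as.integer(pad))
  w1 <- min(len, context$end[1] + as.integer(pad))
  list(seq = as.character(Biostrings::subseq(references[[rn]], w0 + 1L, w1)),
       offset = w0, rname = rn)
}

#' Read context-defining intervals from a BED file
#'
#' Alternative to distance-based clustering: gene annotations (or any
#' intervals) define the contexts directly, limiting refinement to those
#' regions.
#'
#' @param path BED path (first three columns used; BED is already 0-based
#'   half-open, matching the package's internal convention).
#' @return A context tibble with empty member lists (members are attached by
#'   [assign_contexts()]).
#' @export
contexts_from_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#")
  res <- tibble(rname = as.character(df[[1]]),
                start = as.integer(df[[2]]), end = as.integer(df[[3]]),
                read_ids = vector("list", nrow(df)))
  res <- res[order(res$rname, res$start, method = "radix"), ]
  dplyr::mutate(res, context_id = sprintf("ctx%04d", dplyr::row_number()),
                .before = 1)
}
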