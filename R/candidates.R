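# Candidate alignment generation within a context window.
#
# The re-aligner is an exact k-mer index with pigeonhole seed splitting: the
# direction-appropriate seed (read prefix for forward, suffix for backward)
# is cut into seed_mm + 1 equal fragments, all fragments of all reads are
# matched exactly against the window in one Aho-Corasick pass
# (Biostrings::matchPDict), and every implied placement whose full seed has
# <= seed_mm mismatches is then extended greedily until the alignment-wide
# mismatch budget would be exceeded. This reports exactly the set of seed
# hits a mismatch-tolerant index search would, because a seed with at most
# seed_mm mismatches must contain at least one exact fragment.

#' Seed length for a read of length l
#'
#' 40% of the read, rounded up, capped at 40 bp (both configurable in the
#' pipeline via `seed_fraction` / `seed_cap`).
#'
#' @param l Read length (>= 5).
#' @param fraction,cap Seed sizing rule parameters.
#' @return Integer seed length.
#' @export
seed_length <- function(l, fraction = 0.4, cap = 40L) {
  stopifnot(l >= 5)
  pmin(as.integer(ceiling(fraction * l)), as.integer(cap))
}

empty_hits <- function() {
  tibble(read_id = character(), strand = character(), direction = character(),
         q0 = integer(), matched_len = integer(), n_mm = integer(),
         mm_offsets = list(), block_start = integer(), block_end = integer(),
         read_length = integer())
}

# Pre-built pigeonhole seed index over a set of queries, reusable across
# context windows: seed fragments, their PDict, and integer-encoded queries.
seed_index <- function(queries, direction, seed_len = NULL, seed_mm = 1L,
                       seed_fraction = 0.4, seed_cap = 40L) {
  groups <- list()
  for (l in unique(nchar(queries$query))) {
    qs <- queries[nchar(queries$query) == l, ]
    sl <- if (is.null(seed_len)) seed_length(l, seed_fraction, seed_cap)
          else as.integer(seed_len)
    npiece <- seed_mm + 1L
    w0 <- sl %/% npiece
    if (w0 < 1L || sl > l) next
    base <- if (direction == "forward") 0L else l - sl
    piece_off <- base + (seq_len(npiece) - 1L) * w0
    offs_all <- rep(piece_off, each = nrow(qs))
    piece_seq <- substring(rep(qs$query, times = npiece),
                           offs_all + 1L, offs_all + w0)
    ok <- !grepl("N", piece_seq, fixed = TRUE)
    if (!any(ok)) next
    groups[[as.character(l)]] <- list(
      qs = qs, l = l, sl = sl, base = base,
      pd = Biostrings::PDict(Biostrings::DNAStringSet(piece_seq[ok])),
      qrow = rep(seq_len(nrow(qs)), times = npiece)[ok],
      piece_offs = offs_all[ok],
      qints = lapply(qs$query, seq_ints))
  }
  structure(list(direction = direction, seed_mm = seed_mm, groups = groups),
            class = "seed_index")
}

# Batch directional seed-and-extend. `queries` is a tibble with read_id,
# strand, query (window-forward oriented bases). Window-local coordinates.
# A pre-built `index` (from seed_index) makes repeated windows cheap.
seed_hits_batch <- function(queries, window, direction,
                            seed_len = NULL, seed_mm = 1L, max_mm = 4L,
                            seed_fraction = 0.4, seed_cap = 40L,
                            index = NULL) {
  if (is.null(index)) {
    if (nrow(queries) == 0 || !nzchar(window)) return(empty_hits())
    index <- seed_index(queries, direction, seed_len, seed_mm,
                        seed_fraction, seed_cap)
  }
  stopifnot(index$direction == direction)
  seed_mm <- index$seed_mm
  if (!nzchar(window)) return(empty_hits())
  w <- nchar(window)
  wint <- seq_ints(window)
  wdna <- Biostrings::DNAString(window)
  out <- vector("list", 0)
  for (grp in index$groups) {
    qs <- grp$qs; l <- grp$l; sl <- grp$sl; base <- grp$base
    if (sl > w) next
    mi <- Biostrings::startIndex(Biostrings::matchPDict(grp$pd, wdna))
    nhit <- lengths(mi)
    if (sum(nhit) == 0) next
    cand_q <- rep(grp$qrow, nhit)
    cand_p <- unlist(mi[nhit > 0]) - 1L - rep(grp$piece_offs, nhit)
    dup <- duplicated(as.numeric(cand_q) * (w + l + 1) + cand_p)
    cand_q <- cand_q[!dup]; cand_p <- cand_p[!dup]

    qints <- grp$qints
    rows <- vector("list", length(cand_q))
    nr <- 0L
    for (z in seq_along(cand_q)) {
      p0 <- cand_p[z]; r <- cand_q[z]; qi <- qints[[r]]
      if (direction == "forward") {
        if (p0 < 0L || p0 + sl > w) next
        seed_bad <- length(mm_offsets_at(qi, wint, 0L, sl, p0)) > seed_mm
        if (seed_bad) next
        avail <- min(l, w - p0)
        offs <- mm_offsets_at(qi, wint, 0L, avail, p0)
        if (length(offs) > max_mm) {
          matched <- offs[max_mm + 1L]
          offs <- offs[seq_len(max_mm)]
        } else matched <- avail
        if (matched < sl) next
        nr <- nr + 1L
        rows[[nr]] <- list(r = r, q0 = p0, matched = matched,
                           n_mm = length(offs), offs = offs,
                           bs = p0, be = p0 + matched)
      } else {
        if (p0 + l > w || p0 + base < 0L) next
        seed_bad <- length(mm_offsets_at(qi, wint, base, l, p0 + base)) > seed_mm
        if (seed_bad) next
        q_lo <- max(0L, -p0)
        offs <- mm_offsets_at(qi, wint, q_lo, l, p0 + q_lo)
        if (length(offs) > max_mm) {
          cut <- offs[length(offs) - max_mm]
          matched <- l - cut - 1L
          offs <- offs[offs > cut]
        } else matched <- l - q_lo
        if (matched < sl) next
        nr <- nr + 1L
        rows[[nr]] <- list(r = r, q0 = p0, matched = matched,
                           n_mm = length(offs), offs = offs,
                           bs = p0 + l - matched, be = p0 + l)
      }
    }
    if (nr == 0) next
    rows <- rows[seq_len(nr)]
    out[[length(out) + 1]] <- tibble(
      read_id = qs$read_id[vapply(rows, `[[`, 0L, "r")],
      strand = qs$strand[vapply(rows, `[[`, 0L, "r")],
      direction = direction,
      q0 = vapply(rows, `[[`, 0L, "q0"),
      matched_len = vapply(rows, `[[`, 0L, "matched"),
      n_mm = vapply(rows, `[[`, 0L, "n_mm"),
      mm_offsets = lapply(rows, `[[`, "offs"),
      block_start = vapply(rows, `[[`, 0L, "bs"),
      block_end = vapply(rows, `[[`, 0L, "be"),
      read_length = l)
  }
  if (length(out) == 0) empty_hits() else dplyr::bind_rows(out)
}

#' Directional seed-and-extend alignment of one read against a window
#'
#' Reports every window position where the direction-appropriate seed (read
#' prefix for `"forward"`, read suffix for `"backward"`) matches with at most
#' `seed_mm` mismatches, extended greedily until the total mismatch count
#' would exceed `max_mm`. Both read orientations are searched;
#' reverse-complement hits carry `strand == "-"`.
#'
#' @param read Read bases (character scalar).
#' @param window Context window sequence (character scalar).
#' @param direction `"forward"` (anchored at the read start) or `"backward"`
#'   (anchored at the read end).
#' @param seed_len Seed length; default [seed_length()] of the read.
#' @param seed_mm,max_mm Mismatch budgets for the seed region and the whole
#'   alignment.
#' @param read_id Identifier stored in the result.
#' @return A tibble of directional hits: `q0` (window-local position of read
#'   offset 0, possibly negative for backward hits running off the window
#'   start), `matched_len`, `n_mm`, `mm_offsets` (0-based read offsets,
#'   list-column), and the matched `block_start`/`block_end`.
#' @export
align_directional <- function(read, window,
                              direction = c("forward", "backward"),
                              seed_len = NULL, seed_mm = 1L, max_mm = 4L,
                              read_id = "read") {
  direction <- match.arg(direction)
  queries <- tibble(read_id = read_id, strand = c("+", "-"),
                    query = c(toupper(read), revcomp(toupper(read))))
  seed_hits_batch(queries, toupper(window), direction,
                  seed_len = seed_len, seed_mm = seed_mm, max_mm = max_mm)
}

empty_candidates_local <- function() {
  tibble(read_id = character(), strand = character(),
         start1 = integer(), end1 = integer(),
         start2 = integer(), end2 = integer(),
         mismatches = integer(), provenance = character())
}

#' Combine forward and backward hits into full and split candidates
#'
#' A forward hit covering the whole read yields a full candidate. A
#' (forward, backward) pair of hits of the same read and orientation yields
#' one split candidate per junction placement `k` (forward part covers read
#' offsets `[0, k)`, backward part `[k, l)`) inside the overlap of the two
#' hits, provided the implied intron length lies in
#' `[min_intron, max_intron]` and the combined mismatch count meets the
#' maximum-mismatch criterion. Duplicate block configurations are collapsed
#' keeping the minimum mismatch count.
#'
#' @param fwd_hits,bwd_hits Hit tibbles from [align_directional()] /
#'   the batch engine, same read set and window.
#' @param max_mm Maximum mismatches per alignment.
#' @param min_intron,max_intron Accepted splice-gap lengths in bp.
#' @return Candidate tibble in window-local coordinates with provenance
#'   `"realigned"`.
#' @export
combine_alignments <- function(fwd_hits, bwd_hits, max_mm = 4L,
                               min_intron = 20L, max_intron = 400000L) {
  res <- vector("list", 0)
  fulls <- dplyr::bind_rows(fwd_hits, bwd_hits)
  fulls <- fulls[fulls$matched_len == fulls$read_length &
                   fulls$n_mm <= max_mm, , drop = FALSE]
  if (nrow(fulls) > 0) {
    res[[1]] <- tibble(read_id = fulls$read_id, strand = fulls$strand,
                       start1 = fulls$q0, end1 = fulls$q0 + fulls$read_length,
                       start2 = NA_integer_, end2 = NA_integer_,
                       mismatches = fulls$n_mm, provenance = "realigned")
  }
  if (nrow(fwd_hits) > 0 && nrow(bwd_hits) > 0) {
    fk <- paste(fwd_hits$read_id, fwd_hits$strand)
    bk <- paste(bwd_hits$read_id, bwd_hits$strand)
    bsplit <- split(seq_len(nrow(bwd_hits)), bk)
    s_rid <- character(0); s_str <- character(0)
    s_s1 <- integer(0); s_e1 <- integer(0)
    s_s2 <- integer(0); s_e2 <- integer(0); s_mm <- integer(0)
    for (a in seq_len(nrow(fwd_hits))) {
      bi <- bsplit[[fk[a]]]
      if (is.null(bi)) next
      l <- fwd_hits$read_length[a]
      fo <- fwd_hits$mm_offsets[[a]]
      for (b in bi) {
        gap <- bwd_hits$q0[b] - fwd_hits$q0[a]
        if (gap < min_intron || gap > max_intron) next
        lo <- max(1L, l - bwd_hits$matched_len[b])
        hi <- min(fwd_hits$matched_len[a], l - 1L)
        if (lo > hi) next
        bo <- bwd_hits$mm_offsets[[b]]
        for (k in lo:hi) {
          mm <- sum(fo < k) + sum(bo >= k)
          if (mm > max_mm) next
          n <- length(s_s1) + 1L
          s_rid[n] <- fwd_hits$read_id[a]; s_str[n] <- fwd_hits$strand[a]
          s_s1[n] <- fwd_hits$q0[a]; s_e1[n] <- fwd_hits$q0[a] + k
          s_s2[n] <- fwd_hits$q0[a] + k + gap
          s_e2[n] <- fwd_hits$q0[a] + gap + l
          s_mm[n] <- as.integer(mm)
        }
      }
    }
    if (length(s_s1) > 0) {
      res[[length(res) + 1]] <- tibble(
        read_id = s_rid, strand = s_str, start1 = s_s1, end1 = s_e1,
        start2 = s_s2, end2 = s_e2, mismatches = s_mm,
        provenance = "realigned")
    }
  }
  if (length(res) == 0) return(empty_candidates_local())
  out <- dplyr::bind_rows(res)
  out <- out[order(out$mismatches, method = "radix"), ]
  key <- paste(out$read_id, out$strand, out$start1, out$end1,
               out$start2, out$end2)
  out <- out[!duplicated(key), , drop = FALSE]
  out[order(out$read_id, out$start1, out$end1, method = "radix"), ]
}

#' Collect potential splice sites from a candidate set
#'
#' One site per distinct `(s1, s2)` over all split candidates, where `s1` is
#' the last aligned base before the intron and `s2` the first after it. The
#' support tally `n_i` counts, for each mismatch level `i = 0..max_mm`, the
#' reads backing the site: split candidates at the site, full alignments
#' ending exactly at `s1` or starting exactly at `s2`, and partial
#' directional hits doing the same. A read counts once, at its best mismatch
#' level. The signal flag marks introns bounded by a configured
#' donor-acceptor motif in either orientation (for `GT-AG`: `GT..AG`
#' genome-forward or `CT..AC` for minus-strand transcription).
#'
#' @param candidates Candidate tibble (genomic or window-local coordinates;
#'   `window_offset` reconciles the two).
#' @param window Window sequence used for the signal check (`NULL` skips it).
#' @param window_offset Genomic position of window position 0.
#' @param hits Optional directional-hit tibble contributing partial-read
#'   support (window-local, as produced by the batch engine).
#' @param signals Character vector of donor-acceptor motifs like `"GT-AG"`.
#' @param max_mm Maximum mismatch level tallied.
#' @return A tibble of sites: `s1`, `s2`, `signal`, `tallies` (list-column,
#'   counts for mismatch levels 0..max_mm) and `n_support`.
#' @export
collect_splice_sites <- function(candidates, window = NULL,
                                 window_offset = 0L, hits = NULL,
                                 signals = "GT-AG", max_mm = 4L) {
  splits <- candidates[!is.na(candidates$start2), , drop = FALSE]
  if (nrow(splits) == 0) {
    return(tibble(s1 = integer(), s2 = integer(), signal = logical(),
                  tallies = list(), n_support = integer()))
  }
  sup <- tibble(s1 = splits$end1 - 1L, s2 = splits$start2,
                read_id = splits$read_id, mm = splits$mismatches)
  site_key <- unique(sup[c("s1", "s2")])

  fulls <- candidates[is.na(candidates$start2), , drop = FALSE]
  extra <- vector("list", 0)
  if (nrow(fulls) > 0) {
    m1 <- match(fulls$end1 - 1L, site_key$s1)
    hit1 <- !is.na(m1)
    if (any(hit1)) extra[[length(extra) + 1]] <-
      tibble(s1 = fulls$end1[hit1] - 1L, s2 = site_key$s2[m1[hit1]],
             read_id = fulls$read_id[hit1], mm = fulls$mismatches[hit1])
    m2 <- match(fulls$start1, site_key$s2)
    hit2 <- !is.na(m2)
    if (any(hit2)) extra[[length(extra) + 1]] <-
      tibble(s1 = site_key$s1[m2[hit2]], s2 = fulls$start1[hit2],
             read_id = fulls$read_id[hit2], mm = fulls$mismatches[hit2])
  }
  if (!is.null(hits) && nrow(hits) > 0) {
    part <- hits[hits$matched_len < hits$read_length, , drop = FALSE]
    if (nrow(part) > 0) {
      ge <- part$block_end + window_offset
      gs <- part$block_start + window_offset
      pf <- part$direction == "forward"
      m1 <- match(ge - 1L, site_key$s1)
      k1 <- pf & !is.na(m1)
      if (any(k1)) extra[[length(extra) + 1]] <-
        tibble(s1 = ge[k1] - 1L, s2 = site_key$s2[m1[k1]],
               read_id = part$read_id[k1], mm = part$n_mm[k1])
      m2 <- match(gs, site_key$s2)
      k2 <- !pf & !is.na(m2)
      if (any(k2)) extra[[length(extra) + 1]] <-
        tibble(s1 = site_key$s1[m2[k2]], s2 = gs[k2],
               read_id = part$read_id[k2], mm = part$n_mm[k2])
    }
  }
  sup <- dplyr::bind_rows(c(list(sup), extra))
  sup$mm <- pmin(pmax(sup$mm, 0L), max_mm)
  sup <- sup |>
    dplyr::group_by(.data$s1, .data$s2, .data$read_id) |>
    dplyr::summarise(mm = min(.data$mm), .groups = "drop")

  sites <- sup |>
    dplyr::group_by(.data$s1, .data$s2) |>
    dplyr::summarise(
      tallies = list(tabulate(.data$mm + 1L, nbins = max_mm + 1L)),
      n_support = dplyr::n(), .groups = "drop")

  sig <- rep(FALSE, nrow(sites))
  if (!is.null(window)) {
    pairs <- parse_signals(signals)
    w1 <- sites$s1 - window_offset
    w2 <- sites$s2 - window_offset
    ok <- w1 + 3L <= nchar(window) & w2 - 2L >= 1L & (w2 - w1) > 4L
    don <- substr(rep(window, nrow(sites)), w1 + 2L, w1 + 3L)
    acc <- substr(rep(window, nrow(sites)), w2 - 1L, w2)
    for (z in seq_along(pairs$donor)) {
      sig <- sig | (ok & don == pairs$donor[z] & acc == pairs$acceptor[z])
    }
  }
  sites$signal <- sig
  sites[order(sites$s1, sites$s2, method = "radix"),
        c("s1", "s2", "signal", "tallies", "n_support")]
}

#' Extend alignments across known splice sites
#'
#' For every read whose full alignment (or partial directional hit) covers
#' the donor position `s1` of a site, the alignment that splits there and
#' continues at `s2` is constructed, and symmetrically for alignments
#' covering the acceptor side. New candidates are kept when their recomputed
#' mismatch count meets the maximum-mismatch criterion; existing candidates
#' are never removed or replaced, so the candidate set grows monotonically.
#'
#' @param candidates Candidate tibble, genomic coordinates.
#' @param sites Site tibble from [collect_splice_sites()] (genomic).
#' @param window,window_offset Context window sequence and genomic offset.
#' @param queries Tibble `read_id`, `strand`, `query` giving the
#'   window-forward oriented bases of each read/orientation to test.
#' @param hits Optional directional-hit tibble (window-local) whose partial
#'   hits serve as additional anchors.
#' @param max_mm Maximum mismatches per alignment.
#' @return `candidates` plus any new rows with provenance
#'   `"splice_extended"`.
#' @export
splice_extend <- function(candidates, sites, window, window_offset = 0L,
                          queries = NULL, hits = NULL, max_mm = 4L) {
  if (nrow(sites) == 0 || is.null(queries) || nrow(queries) == 0) {
    return(candidates)
  }
  w <- nchar(window)
  wint <- seq_ints(window)
  qkey <- paste(queries$read_id, queries$strand)
  qints <- lapply(queries$query, seq_ints)
  qlen <- nchar(queries$query)

  # anchors: left-anchored (read start fixed) and right-anchored (read end
  # fixed), window-local block coordinates
  fulls <- candidates[is.na(candidates$start2), , drop = FALSE]
  anc_l <- tibble(read_id = fulls$read_id, strand = fulls$strand,
                  bs = fulls$start1 - window_offset,
                  be = fulls$end1 - window_offset)
  anc_r <- anc_l
  if (!is.null(hits) && nrow(hits) > 0) {
    hf <- hits[hits$direction == "forward", ]
    hb <- hits[hits$direction == "backward", ]
    anc_l <- dplyr::bind_rows(anc_l, tibble(
      read_id = hf$read_id, strand = hf$strand,
      bs = hf$block_start, be = hf$block_end))
    anc_r <- dplyr::bind_rows(anc_r, tibble(
      read_id = hb$read_id, strand = hb$strand,
      bs = hb$block_start, be = hb$block_end))
  }
  anc_l <- unique(anc_l); anc_r <- unique(anc_r)
  anc_l$qi <- match(paste(anc_l$read_id, anc_l$strand), qkey)
  anc_r$qi <- match(paste(anc_r$read_id, anc_r$strand), qkey)
  anc_l <- anc_l[!is.na(anc_l$qi), ]; anc_r <- anc_r[!is.na(anc_r$qi), ]

  acc_qi <- integer(0); acc_b1s <- integer(0); acc_b1e <- integer(0)
  acc_b2s <- integer(0); acc_b2e <- integer(0); acc_mm <- integer(0)
  add_cand <- function(qi, b1s, b1e, b2s, b2e) {
    if (b1s < 0L || b2e > w) return(invisible(NULL))
    mm <- count_block_mismatches(qints[[qi]], wint, c(b1s, b2s), c(b1e, b2e))
    if (mm > max_mm) return(invisible(NULL))
    acc_qi[[length(acc_qi) + 1L]] <<- qi
    acc_b1s[[length(acc_b1s) + 1L]] <<- b1s
    acc_b1e[[length(acc_b1e) + 1L]] <<- b1e
    acc_b2s[[length(acc_b2s) + 1L]] <<- b2s
    acc_b2e[[length(acc_b2e) + 1L]] <<- b2e
    acc_mm[[length(acc_mm) + 1L]] <<- as.integer(mm)
    invisible(NULL)
  }
  for (s in seq_len(nrow(sites))) {
    w1 <- sites$s1[s] - window_offset
    w2 <- sites$s2[s] - window_offset
    if (w1 < 0L || w2 > w) next
    la_i <- which(anc_l$bs <= w1 & w1 < anc_l$be)
    for (z in la_i) {
      qi <- anc_l$qi[z]; l <- qlen[qi]
      k <- w1 - anc_l$bs[z] + 1L
      if (k < 1L || k > l - 1L) next
      add_cand(qi, anc_l$bs[z], anc_l$bs[z] + k, w2, w2 + l - k)
    }
    ra_i <- which(anc_r$bs <= w2 & w2 < anc_r$be)
    for (z in ra_i) {
      qi <- anc_r$qi[z]; l <- qlen[qi]
      k2 <- anc_r$be[z] - w2
      if (k2 < 1L || k2 > l - 1L) next
      add_cand(qi, w1 + 1L - (l - k2), w1 + 1L, w2, w2 + k2)
    }
  }
  if (length(acc_qi) == 0) return(candidates)
  new <- tibble(read_id = queries$read_id[acc_qi],
                strand = queries$strand[acc_qi],
                start1 = acc_b1s + window_offset,
                end1 = acc_b1e + window_offset,
                start2 = acc_b2s + window_offset,
                end2 = acc_b2e + window_offset,
                mismatches = acc_mm, provenance = "splice_extended")
  new <- new[order(new$mismatches, method = "radix"), ]
  new <- new[!duplicated(paste(new$read_id, new$strand, new$start1,
                               new$end1, new$start2, new$end2)), ]
  have <- paste(candidates$read_id, candidates$strand, candidates$start1,
                candidates$end1, candidates$start2, candidates$end2)
  new <- new[!paste(new$read_id, new$strand, new$start1, new$end1,
                    new$start2, new$end2) %in% have, , drop = FALSE]
  dplyr::bind_rows(candidates, new)
}
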