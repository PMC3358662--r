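# Ambiguity resolution: from many candidate placements per read to exactly
# one genomic location, using splice-site evidence and read-coverage scores.

#' Drop a read from contexts where it matches much worse than its best
#'
#' A read is removed from every context in which its best candidate needs
#' more than `delta_mm` mismatches beyond its best candidate anywhere; the
#' best-matching context always survives.
#'
#' @param candidates Candidate tibble with a `context_id` column.
#' @param delta_mm Allowed excess mismatches.
#' @return The filtered candidate tibble.
#' @export
filter_by_mismatch_delta <- function(candidates, delta_mm = 2L) {
  if (nrow(candidates) == 0) return(candidates)
  best_ctx <- candidates |>
    dplyr::group_by(.data$read_id, .data$context_id) |>
    dplyr::summarise(best = min(.data$mismatches), .groups = "drop_last") |>
    dplyr::mutate(global_best = min(.data$best)) |>
    dplyr::ungroup()
  keep <- best_ctx[best_ctx$best <= best_ctx$global_best + delta_mm,
                   c("read_id", "context_id")]
  dplyr::semi_join(candidates, keep, by = c("read_id", "context_id"))
}

#' Merge full and split candidates sharing a start or end position
#'
#' Within one read and one context, candidates with the same outermost
#' genomic start or the same outermost end are treated as a single option
#' during resolution; the final full-versus-split choice is deferred to
#' [resolve_merged_endpoint_groups()].
#'
#' @param candidates Candidate tibble for one read within one context (or
#'   several reads; merging is per read).
#' @return `candidates` with an added `group_id` (unique within read).
#' @export
merge_same_endpoint <- function(candidates) {
  if (nrow(candidates) == 0) {
    return(dplyr::mutate(candidates, group_id = integer(0)))
  }
  ends <- outer_end(candidates$end1, candidates$end2)
  grp <- integer(nrow(candidates))
  for (ids in split(seq_len(nrow(candidates)), candidates$read_id)) {
    parent <- seq_along(ids)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    s <- candidates$start1[ids]; e <- ends[ids]
    for (i in seq_along(ids)[-1]) {
      for (j in seq_len(i - 1L)) {
        if (s[i] == s[j] || e[i] == e[j]) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    roots <- vapply(seq_along(ids), find, 0L)
    grp[ids] <- match(roots, sort(unique(roots)))
  }
  dplyr::mutate(candidates, group_id = grp)
}

#' Evidence score of splice sites
#'
#' The weighted support sum `lambda * sum_i w^i * n_i`, where `n_i` is the
#' number of reads supporting the site with `i` mismatches, the weight `w`
#' (default 0.3) decays exponentially with the mismatch count, and `lambda`
#' doubles the score of sites bounded by a known splice signal.
#'
#' @param sites Site tibble from [collect_splice_sites()].
#' @param lambda_signal Multiplier applied when `signal` is `TRUE`.
#' @param mm_weight Per-mismatch decay factor.
#' @return Numeric vector of evidence scores, one per site.
#' @export
evidence_score <- function(sites, lambda_signal = 2, mm_weight = 0.3) {
  if (nrow(sites) == 0) return(numeric(0))
  vapply(seq_len(nrow(sites)), function(i) {
    n <- sites$tallies[[i]]
    lam <- if (isTRUE(sites$signal[i])) lambda_signal else 1
    lam * sum(mm_weight^(seq_along(n) - 1) * n)
  }, 0)
}

#' Prune overlapping splice sites by evidence
#'
#' Two sites overlap when both `|s1 - s1'|` and `|s2 - s2'|` are smaller
#' than the read length -- sites that close together are either biologically
#' implausible or alternative split placements of the same reads. Within
#' each connected set of pairwise-overlapping sites the maximum-evidence
#' site is retained; ties go to the smaller `(s1, s2)`.
#'
#' @param sites Site tibble.
#' @param read_length Read length defining the overlap window.
#' @param lambda_signal,mm_weight Passed to [evidence_score()].
#' @return A list with `retained` and `dropped` site tibbles (both carry an
#'   `evidence` column).
#' @export
prune_overlapping_splice_sites <- function(sites, read_length,
                                           lambda_signal = 2,
                                           mm_weight = 0.3) {
  sites$evidence <- evidence_score(sites, lambda_signal, mm_weight)
  n <- nrow(sites)
  if (n == 0) return(list(retained = sites, dropped = sites[0, ]))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    if (i == 1) next
    for (j in seq_len(i - 1L)) {
      if (abs(sites$s1[i] - sites$s1[j]) < read_length &&
          abs(sites$s2[i] - sites$s2[j]) < read_length) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  keep <- logical(n)
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    best <- idx[order(-sites$evidence[idx], sites$s1[idx], sites$s2[idx])][1]
    keep[best] <- TRUE
  }
  list(retained = sites[keep, , drop = FALSE],
       dropped = sites[!keep, , drop = FALSE])
}

#' Per-position read coverage of a context
#'
#' Counts, at every position of the context window, the number of reads
#' whose candidate alignments cover it (`c_m`). A read with several
#' candidates counts once at every position in the union of its candidates;
#' intron interiors of split candidates are not covered.
#'
#' @param candidates Candidate tibble of one context (one reference).
#' @param start,end Window bounds, 0-based half-open.
#' @return An object of class `coverage_profile`: list with `window_start`,
#'   `window_end` and the integer vector `cov` (`c_m` per position).
#' @export
coverage_profile <- function(candidates, start, end) {
  stopifnot(end > start)
  cov <- integer(end - start)
  if (nrow(candidates) > 0) {
    s <- c(candidates$start1, candidates$start2[!is.na(candidates$start2)])
    e <- c(candidates$end1, candidates$end2[!is.na(candidates$end2)])
    rid <- c(candidates$read_id,
             candidates$read_id[!is.na(candidates$start2)])
    ir <- IRanges::IRanges(start = s + 1L, end = e)  # 1-based closed
    per_read <- IRanges::reduce(S4Vectors::split(ir, rid))
    flat <- unlist(per_read, use.names = FALSE)
    rc <- IRanges::coverage(IRanges::shift(flat, -start),
                            width = end - start)
    cov <- as.integer(rc)
  }
  structure(list(window_start = start, window_end = end, cov = cov),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("<coverage_profile> window [", x$window_start, ",", x$window_end,
      "), max c_m =", max(x$cov, 0L), "\n")
  invisible(x)
}

# max of cov over genomic [a, b) clipped to the profile window; 0 if empty
profile_max <- function(profile, a, b) {
  a <- max(a, profile$window_start); b <- min(b, profile$window_end)
  if (b <= a) return(0L)
  max(profile$cov[(a - profile$window_start + 1L):(b - profile$window_start)])
}

#' Coverage score of candidate alignments
#'
#' The region-weighted sum of log coverage maxima: region 1 is the aligned
#' positions themselves, region 2 everything up to `region_bounds[1]` bp
#' beyond either end of the alignment, regions 3 and 4 the next two distance
#' shells. Each region contributes `base^(4-i) * ln(max(score_i, 1))`, where
#' `score_i` is the maximum `c_m` inside region `i` -- a geometric-mean-like
#' summary that discounts distant reads and large outliers. For split
#' alignments only aligned positions plus the flanks beyond the outermost
#' ends count; the intron interior is excluded. Regions are clipped at the
#' context window.
#'
#' @param alignments Candidate tibble rows to score.
#' @param profile A [coverage_profile()] for the context.
#' @param region_bounds Outer edges of regions 2..4 in bp.
#' @param weight_base Weight ratio between adjacent regions.
#' @return Numeric vector of scores.
#' @export
coverage_score <- function(alignments, profile,
                           region_bounds = c(200L, 500L, 1000L),
                           weight_base = 2) {
  if (nrow(alignments) == 0) return(numeric(0))
  edges <- c(0L, as.integer(region_bounds))
  wts <- weight_base^(3:0)
  ends <- outer_end(alignments$end1, alignments$end2)
  vapply(seq_len(nrow(alignments)), function(i) {
    s1 <- profile_max(profile, alignments$start1[i], alignments$end1[i])
    if (!is.na(alignments$start2[i])) {
      s1 <- max(s1, profile_max(profile, alignments$start2[i],
                                alignments$end2[i]))
    }
    sc <- c(s1, vapply(1:3, function(r) {
      max(profile_max(profile, alignments$start1[i] - edges[r + 1L],
                      alignments$start1[i] - edges[r]),
          profile_max(profile, ends[i] + edges[r], ends[i] + edges[r + 1L]))
    }, 0L))
    sum(wts * log(pmax(sc, 1)))
  }, 0)
}

# score of merged endpoint groups: max over member alignments
group_scores <- function(candidates, profile, region_bounds, weight_base) {
  sc <- coverage_score(candidates, profile, region_bounds, weight_base)
  tibble(read_id = candidates$read_id, group_id = candidates$group_id,
         score = sc) |>
    dplyr::group_by(.data$read_id, .data$group_id) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop")
}

#' Assign each read a unique option within one context
#'
#' Builds the ambiguity structure (reads versus merged candidate groups) and
#' resolves it greedily in priority order of the difference between the best
#' and second-best coverage score. In `"static"` mode (the default, and the
#' fast variant) every read is resolved on the initial scores, so the
#' outcome is the per-read argmax with deterministic tie-breaking. In
#' `"dynamic"` mode the per-position counts are recomputed after each
#' fixation -- a read fixed at its best group stops covering its discarded
#' candidates -- and the remaining reads are re-scored through the
#' read-position adjacency before the next pop.
#'
#' @param candidates Candidate tibble of one context, with `group_id` from
#'   [merge_same_endpoint()].
#' @param profile [coverage_profile()] of the context.
#' @param mode `"static"` or `"dynamic"`.
#' @param region_bounds,weight_base Coverage-score parameters.
#' @return A tibble `read_id`, `group_id`, `score`, `margin` with one row
#'   per read (the chosen group).
#' @export
resolve_within_context <- function(candidates, profile, mode = "static",
                                   region_bounds = c(200L, 500L, 1000L),
                                   weight_base = 2) {
  if (nrow(candidates) == 0) {
    return(tibble(read_id = character(), group_id = integer(),
                  score = numeric(), margin = numeric()))
  }
  stopifnot(!is.null(candidates$group_id))
  pick_all <- function(cands, prof) {
    gs <- group_scores(cands, prof, region_bounds, weight_base)
    info <- cands |>
      dplyr::group_by(.data$read_id, .data$group_id) |>
      dplyr::summarise(mm = min(.data$mismatches), s = min(.data$start1),
                       .groups = "drop") |>
      dplyr::left_join(gs, by = c("read_id", "group_id"))
    info |>
      dplyr::group_by(.data$read_id) |>
      dplyr::arrange(dplyr::desc(.data$score), .data$mm, .data$s,
                     .data$group_id, .by_group = TRUE) |>
      dplyr::summarise(
        margin = ifelse(dplyr::n() > 1,
                        .data$score[1] - .data$score[2], Inf),
        group_id = .data$group_id[1], score = .data$score[1],
        .groups = "drop") |>
      dplyr::select("read_id", "group_id", "score", "margin")
  }
  if (mode == "static") {
    out <- pick_all(candidates, profile)
    return(out[order(out$read_id), ])
  }
  # dynamic: iterate pops, rebuilding the profile after each fixation
  cands <- candidates
  fixed <- tibble(read_id = character(), group_id = integer(),
                  score = numeric(), margin = numeric())
  repeat {
    live <- pick_all(cands, coverage_profile(cands, profile$window_start,
                                             profile$window_end))
    live <- live[!live$read_id %in% fixed$read_id, , drop = FALSE]
    if (nrow(live) == 0) break
    live <- live[order(-live$margin, live$read_id), ]
    top <- live[1, ]
    fixed <- dplyr::bind_rows(fixed, top)
    cands <- cands[!(cands$read_id == top$read_id &
                       cands$group_id != top$group_id), , drop = FALSE]
    if (nrow(fixed) == length(unique(candidates$read_id))) break
  }
  fixed[order(fixed$read_id), ]
}

#' Choose the concrete alignment inside a merged endpoint group
#'
#' Members of the chosen group (full and split placements sharing a start or
#' end) are re-scored over only the positions that distinguish them: aligned
#' positions not shared by all members, plus the upstream flank when the
#' starts differ and the downstream flank when the ends differ. The maximum
#' wins; ties break to fewer mismatches, then full before split, then the
#' leftmost placement.
#'
#' @param members Candidate rows of one read's chosen group.
#' @param profile Context [coverage_profile()].
#' @param region_bounds,weight_base Coverage-score parameters.
#' @return The single winning row.
#' @export
resolve_merged_endpoint_groups <- function(members, profile,
                                           region_bounds = c(200L, 500L, 1000L),
                                           weight_base = 2) {
  if (nrow(members) == 1) return(members)
  edges <- c(0L, as.integer(region_bounds))
  wts <- weight_base^(3:0)
  rngs <- lapply(seq_len(nrow(members)), function(i) {
    ir <- IRanges::IRanges(start = members$start1[i] + 1L,
                           end = members$end1[i])
    if (!is.na(members$start2[i])) {
      ir <- c(ir, IRanges::IRanges(start = members$start2[i] + 1L,
                                   end = members$end2[i]))
    }
    ir
  })
  shared <- Reduce(IRanges::intersect, rngs)
  ends <- outer_end(members$end1, members$end2)
  starts_differ <- length(unique(members$start1)) > 1
  ends_differ <- length(unique(ends)) > 1
  score <- vapply(seq_len(nrow(members)), function(i) {
    own <- IRanges::setdiff(rngs[[i]], shared)
    s1 <- if (length(own) == 0) 0L else
      max(vapply(seq_along(own), function(z)
        profile_max(profile, IRanges::start(own)[z] - 1L,
                    IRanges::end(own)[z]), 0L))
    sc <- c(s1, vapply(1:3, function(r) {
      up <- if (starts_differ)
        profile_max(profile, members$start1[i] - edges[r + 1L],
                    members$start1[i] - edges[r]) else 0L
      dn <- if (ends_differ)
        profile_max(profile, ends[i] + edges[r], ends[i] + edges[r + 1L])
      else 0L
      max(up, dn)
    }, 0L))
    sum(wts * log(pmax(sc, 1)))
  }, 0)
  is_split <- !is.na(members$start2)
  ord <- order(-score, members$mismatches, is_split, members$start1)
  members[ord[1], , drop = FALSE]
}

#' Resolve reads mapped in several contexts
#'
#' Applies the same greedy logic across contexts: each read's per-context
#' winning alignment enters with its coverage score, and the read is fixed
#' in the best-scoring context (static scores; ties break by reference name,
#' start, then context id).
#'
#' @param winners Tibble of per-context winners: alignment columns plus
#'   `context_id` and `score`.
#' @return One row per read.
#' @export
resolve_between_contexts <- function(winners) {
  if (nrow(winners) == 0) return(winners)
  winners |>
    dplyr::group_by(.data$read_id) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$rname, .data$start1,
                   .data$context_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Final expression filter
#'
#' A resolved read is emitted only when at least `min_support` other reads
#' map within `window` bp up- or downstream of it (overlapping its span
#' expanded by `window` on both sides) -- regions with fewer neighbours do
#' not suggest real expression.
#'
#' @param final Final alignment tibble (one row per read).
#' @param min_support Required number of neighbouring reads.
#' @param window Neighbourhood half-width in bp.
#' @return A list with `emitted` and `filtered` tibbles; filtered rows gain
#'   a `reason` column.
#' @export
expression_filter <- function(final, min_support = 100L, window = 1000L) {
  if (nrow(final) == 0 || min_support == 0) {
    return(list(emitted = final,
                filtered = dplyr::mutate(final[0, ], reason = character(0))))
  }
  keep <- logical(nrow(final))
  ends <- outer_end(final$end1, final$end2)
  for (rn in unique(final$rname)) {
    idx <- which(final$rname == rn)
    spans <- IRanges::IRanges(start = final$start1[idx] + 1L, end = ends[idx])
    grown <- IRanges::IRanges(
      start = pmax(1L, final$start1[idx] + 1L - window),
      end = ends[idx] + window)
    keep[idx] <- IRanges::countOverlaps(grown, spans) - 1L >= min_support
  }
  list(emitted = final[keep, , drop = FALSE],
       filtered = dplyr::mutate(final[!keep, , drop = FALSE],
                                reason = "low_expression"))
}
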