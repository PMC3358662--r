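# The three-step refinement pipeline: context identification, candidate
# extension, ambiguity resolution. One call, one unique location per
# mappable read.

load_references <- function(genome) {
  if (is.character(genome) && length(genome) == 1) read_genome_fasta(genome)
  else genome
}

load_reads <- function(reads, min_length = NULL) {
  if (is.character(reads) && length(reads) == 1) {
    read_reads_fastq(reads, min_length = min_length)
  } else reads
}

#' Refine an initial RNA-seq mapping
#'
#' Runs the full pipeline: (1) cluster the unique initial alignments into
#' expression contexts; (2) within each context, re-align the unmapped and
#' multi-mapped reads by forward/backward seed extension, combine the hits
#' into full and split candidates, collect potential splice sites and extend
#' alignments across them; (3) resolve all ambiguities with the mismatch
#' filter, splice-site pruning, coverage scoring, the within- and
#' between-context priority scheme, and the final expression filter.
#'
#' @param genome Reference FASTA path or a named
#'   [Biostrings::DNAStringSet].
#' @param initial Initial mapping SAM path (single-end), or the list
#'   returned by [read_alignments_sam()].
#' @param reads FASTQ path or tibble (`read_id`, `bases`, `qualities`).
#' @param config A [refine_config()].
#' @param out_dir Optional output directory: writes `final.sam`,
#'   `contexts.tsv`, `resolution.tsv` and `run.log`.
#' @param verbose Emit progress messages.
#' @return An object of class `refine_result`: list with `final` (one
#'   alignment row per emitted read, including `context_id` and `score`),
#'   `unmapped` (tibble `read_id`, `reason`), `contexts`, `candidates` (the
#'   full post-resolution candidate store), `sites` (retained splice sites
#'   per context) and `summary`.
#' @export
refine_reads <- function(genome, initial, reads, config = refine_config(),
                         out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "refine_config"))
  say <- function(...) if (verbose) message(...)
  log_lines <- c(paste0("# effective config"),
                 paste0(names(config), " = ",
                        vapply(config, function(v)
                          if (is.null(v)) "NULL" else
                            paste(v, collapse = ","), "")))

  refs <- load_references(genome)
  reads <- load_reads(reads, min_length = 2L * config$min_seed_len)
  sam <- if (is.character(initial) && length(initial) == 1) {
    read_alignments_sam(initial, unique_only = TRUE)
  } else initial

  missing_seq <- setdiff(
    unique(c(sam$alignments$read_id, sam$ambiguous, sam$unmapped,
             sam$rejected)), reads$read_id)
  if (length(missing_seq)) {
    stop("initial mapping refers to read id(s) absent from the reads: ",
         paste(utils::head(missing_seq, 5), collapse = ", "),
         if (length(missing_seq) > 5) " ..." else "")
  }
  bases_of <- stats::setNames(reads$bases, reads$read_id)
  len_of <- stats::setNames(nchar(reads$bases), reads$read_id)
  l_max <- if (nrow(reads)) max(nchar(reads$bases)) else 0L
  pad <- config$pad %||% l_max

  # verify the unique initial alignments against the reference; anything
  # violating the mismatch-only model joins the re-alignment pool
  aln <- sam$alignments
  pool_extra <- character(0)
  if (nrow(aln) > 0) {
    fwd <- ifelse(aln$strand == "-", revcomp(bases_of[aln$read_id]),
                  unname(bases_of[aln$read_id]))
    ref_ints <- lapply(stats::setNames(as.character(refs), names(refs)),
                       seq_ints)
    mm <- integer(nrow(aln))
    bad_len <- rep(FALSE, nrow(aln))
    for (i in seq_len(nrow(aln))) {
      st <- c(aln$start1[i], aln$start2[i]); en <- c(aln$end1[i], aln$end2[i])
      st <- st[!is.na(st)]; en <- en[!is.na(en)]
      if (sum(en - st) != nchar(fwd[i])) { bad_len[i] <- TRUE; next }
      mm[i] <- count_block_mismatches(
        seq_ints(fwd[i]), ref_ints[[aln$rname[i]]], st, en)
    }
    aln$mismatches <- mm
    drop <- bad_len | mm > config$max_mm
    pool_extra <- aln$read_id[drop]
    aln <- aln[!drop, , drop = FALSE]
  }
  pool_ids <- sort(unique(c(sam$ambiguous, sam$unmapped, sam$rejected,
                            pool_extra,
                            setdiff(reads$read_id, sam$alignments$read_id))))
  say(nrow(aln), " unique initial alignments, ", length(pool_ids),
      " reads to re-align")

  # ---- step 1: contexts -------------------------------------------------
  contexts <- if (!is.null(config$annotation_bed)) {
    contexts_from_bed(config$annotation_bed)
  } else {
    build_contexts(aln, d_min = config$d_min)
  }
  aln <- assign_contexts(aln, contexts)
  aln <- aln[!is.na(aln$context_id), , drop = FALSE]
  say(nrow(contexts), " contexts")

  # ---- step 2: candidate generation per context -------------------------
  pool_reads <- reads[reads$read_id %in% pool_ids, , drop = FALSE]
  pool_queries <- tibble(
    read_id = rep(pool_reads$read_id, 2L),
    strand = rep(c("+", "-"), each = nrow(pool_reads)),
    query = c(pool_reads$bases, revcomp(pool_reads$bases)))

  fwd_index <- bwd_index <- NULL
  if (nrow(pool_queries) > 0) {
    fwd_index <- seed_index(pool_queries, "forward",
                            seed_mm = config$seed_mm,
                            seed_fraction = config$seed_fraction,
                            seed_cap = config$seed_cap)
    bwd_index <- seed_index(pool_queries, "backward",
                            seed_mm = config$seed_mm,
                            seed_fraction = config$seed_fraction,
                            seed_cap = config$seed_cap)
  }
  ctx_cands <- vector("list", nrow(contexts))
  ctx_sites <- vector("list", nrow(contexts))
  ctx_window <- vector("list", nrow(contexts))
  for (ci in seq_len(nrow(contexts))) {
    ctx <- contexts[ci, ]
    win <- context_window(ctx, refs, pad = pad)
    ctx_window[[ci]] <- win
    fwd_hits <- if (is.null(fwd_index)) empty_hits() else
      seed_hits_batch(pool_queries, win$seq, "forward",
                      max_mm = config$max_mm, index = fwd_index)
    bwd_hits <- if (is.null(bwd_index)) empty_hits() else
      seed_hits_batch(pool_queries, win$seq, "backward",
                      max_mm = config$max_mm, index = bwd_index)
    realigned <- combine_alignments(fwd_hits, bwd_hits,
                                    max_mm = config$max_mm,
                                    min_intron = config$min_intron,
                                    max_intron = config$max_intron)
    if (nrow(realigned) > 0) {
      realigned$start1 <- realigned$start1 + win$offset
      realigned$end1 <- realigned$end1 + win$offset
      realigned$start2 <- realigned$start2 + win$offset
      realigned$end2 <- realigned$end2 + win$offset
    }
    init_ctx <- aln[aln$context_id == ctx$context_id,
                    c("read_id", "strand", "start1", "end1", "start2",
                      "end2", "mismatches", "provenance"), drop = FALSE]
    cand <- dplyr::bind_rows(init_ctx, realigned)
    hits <- dplyr::bind_rows(fwd_hits, bwd_hits)
    sites <- collect_splice_sites(cand, window = win$seq,
                                  window_offset = win$offset, hits = hits,
                                  signals = config$splice_signals,
                                  max_mm = config$max_mm)
    ext_queries <- pool_queries
    if (nrow(init_ctx) > 0) {
      uq <- unique(init_ctx[c("read_id", "strand")])
      ext_queries <- dplyr::bind_rows(ext_queries, tibble(
        read_id = uq$read_id, strand = uq$strand,
        query = ifelse(uq$strand == "-", revcomp(bases_of[uq$read_id]),
                       unname(bases_of[uq$read_id]))))
    }
    cand <- splice_extend(cand, sites, win$seq, win$offset,
                          queries = ext_queries, hits = hits,
                          max_mm = config$max_mm)
    if (nrow(cand) > 0) {
      cand$rname <- ctx$rname
      cand$context_id <- ctx$context_id
    }
    ctx_cands[[ci]] <- cand
    ctx_sites[[ci]] <- sites
  }
  candidates <- dplyr::bind_rows(ctx_cands)
  say(nrow(candidates), " candidate alignments")

  # ---- step 3: resolution ----------------------------------------------
  candidates <- filter_by_mismatch_delta(candidates, config$delta_mm)

  winners <- vector("list", nrow(contexts))
  retained_sites <- vector("list", nrow(contexts))
  for (ci in seq_len(nrow(contexts))) {
    ctx <- contexts[ci, ]
    cand <- candidates[candidates$context_id == ctx$context_id, ,
                       drop = FALSE]
    if (nrow(cand) == 0) next
    win <- ctx_window[[ci]]
    pruned <- prune_overlapping_splice_sites(
      ctx_sites[[ci]], read_length = l_max,
      lambda_signal = config$lambda_signal, mm_weight = config$mm_weight)
    retained_sites[[ci]] <- dplyr::mutate(pruned$retained,
                                          context_id = ctx$context_id)
    if (nrow(pruned$dropped) > 0) {
      bad <- paste(pruned$dropped$s1, pruned$dropped$s2)
      is_bad <- !is.na(cand$start2) &
        paste(cand$end1 - 1L, cand$start2) %in% bad
      lost <- setdiff(cand$read_id[is_bad], cand$read_id[!is_bad])
      cand <- cand[!is_bad, , drop = FALSE]
      if (length(lost) > 0 && nrow(pruned$retained) > 0) {
        # reads stranded by the pruning re-enter extension against the
        # retained sites, anchored at their discarded placements
        old <- candidates[candidates$context_id == ctx$context_id &
                            candidates$read_id %in% lost, , drop = FALSE]
        l_old <- len_of[old$read_id]
        anchors <- dplyr::bind_rows(
          tibble(read_id = old$read_id, strand = old$strand,
                 start1 = old$start1, end1 = old$start1 + l_old,
                 start2 = NA_integer_, end2 = NA_integer_,
                 mismatches = config$max_mm, provenance = "realigned"),
          tibble(read_id = old$read_id, strand = old$strand,
                 start1 = outer_end(old$end1, old$end2) - l_old,
                 end1 = outer_end(old$end1, old$end2),
                 start2 = NA_integer_, end2 = NA_integer_,
                 mismatches = config$max_mm, provenance = "realigned"))
        rescue_q <- tibble(
          read_id = rep(unique(old$read_id), 2L),
          strand = rep(c("+", "-"), each = length(unique(old$read_id))),
          query = c(bases_of[unique(old$read_id)],
                    revcomp(bases_of[unique(old$read_id)])))
        resc <- splice_extend(anchors, pruned$retained, win$seq, win$offset,
                              queries = rescue_q, max_mm = config$max_mm)
        resc <- resc[resc$provenance == "splice_extended", , drop = FALSE]
        if (nrow(resc) > 0) {
          resc$rname <- ctx$rname
          resc$context_id <- ctx$context_id
          cand <- dplyr::bind_rows(cand, resc)
        }
      }
    }
    if (nrow(cand) == 0) next
    w0 <- max(0L, ctx$start - pad)
    w1 <- ctx$end + pad
    prof <- coverage_profile(cand, w0, w1)
    cand <- merge_same_endpoint(cand)
    assign <- resolve_within_context(cand, prof,
                                     mode = config$resolution_mode,
                                     region_bounds = config$region_bounds,
                                     weight_base = config$region_weight_base)
    key <- paste(cand$read_id, cand$group_id)
    by_group <- split(seq_len(nrow(cand)), key)
    chosen_idx <- by_group[paste(assign$read_id, assign$group_id)]
    singles <- vapply(chosen_idx, length, 0L) == 1L
    picked <- vector("list", sum(!singles) + 1L)
    picked[[1]] <- cand[unlist(chosen_idx[singles]), , drop = FALSE]
    z <- 1L
    for (ids in chosen_idx[!singles]) {
      z <- z + 1L
      picked[[z]] <- resolve_merged_endpoint_groups(
        cand[ids, , drop = FALSE], prof,
        region_bounds = config$region_bounds,
        weight_base = config$region_weight_base)
    }
    win_ctx <- dplyr::bind_rows(picked)
    win_ctx$score <- coverage_score(win_ctx, prof,
                                    region_bounds = config$region_bounds,
                                    weight_base = config$region_weight_base)
    winners[[ci]] <- win_ctx
  }
  winners <- dplyr::bind_rows(winners)
  if (nrow(winners) == 0) {
    winners <- dplyr::mutate(empty_alignments(), context_id = character(0),
                             group_id = integer(0), score = numeric(0))
  }
  final <- resolve_between_contexts(winners)
  say(nrow(final), " reads resolved")

  flt <- expression_filter(final, min_support = config$min_support,
                           window = config$support_window)
  emitted <- flt$emitted
  unmapped <- dplyr::bind_rows(
    tibble(read_id = setdiff(reads$read_id, final$read_id),
           reason = "no_candidate"),
    tibble(read_id = flt$filtered$read_id,
           reason = flt$filtered$reason))
  unmapped <- unmapped[order(unmapped$read_id), ]
  say(nrow(emitted), " reads emitted, ", nrow(unmapped), " unmapped")

  summary <- tibble(
    n_reads = nrow(reads), n_unique_initial = nrow(aln),
    n_pool = length(pool_ids), n_contexts = nrow(contexts),
    n_candidates = nrow(candidates), n_resolved = nrow(final),
    n_emitted = nrow(emitted), n_filtered = nrow(flt$filtered),
    n_unmapped = nrow(unmapped))
  res <- structure(list(
    final = emitted[order(emitted$rname, emitted$start1, emitted$read_id), ],
    unmapped = unmapped, contexts = contexts, candidates = candidates,
    sites = dplyr::bind_rows(retained_sites), summary = summary,
    config = config), class = "refine_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_alignments_sam(res$final, refs, file.path(out_dir, "final.sam"),
                         reads = reads, unmapped = unmapped$read_id)
    ctx_df <- data.frame(context_id = contexts$context_id,
                         rname = contexts$rname, start = contexts$start,
                         end = contexts$end,
                         n_members = lengths(contexts$read_ids))
    utils::write.table(ctx_df, file.path(out_dir, "contexts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    diag <- candidates |>
      dplyr::count(.data$read_id, name = "n_candidates") |>
      dplyr::left_join(res$final[c("read_id", "score")], by = "read_id")
    utils::write.table(as.data.frame(diag),
                       file.path(out_dir, "resolution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c(log_lines, paste0("# ", names(summary), " = ",
                                   unlist(summary))),
               file.path(out_dir, "run.log"))
  }
  res
}

#' @export
print.refine_result <- function(x, ...) {
  cat("<refine_result>\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' Fewest-mismatches baseline assignment
#'
#' Reference point for the coverage-based resolution: each read is assigned
#' to a minimum-mismatch candidate, with uniformly random tie-breaking among
#' equally good placements.
#'
#' @param candidates Candidate tibble (any number of contexts).
#' @param seed Optional seed for the tie-breaks.
#' @return One alignment row per read.
#' @export
baseline_min_mismatch <- function(candidates, seed = NULL) {
  local_seed(seed)
  if (nrow(candidates) == 0) return(candidates)
  candidates |>
    dplyr::group_by(.data$read_id) |>
    dplyr::slice({
      idx <- which(.data$mismatches == min(.data$mismatches))
      idx[sample.int(length(idx), 1L)]
    }) |>
    dplyr::ungroup()
}
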