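# Accuracy evaluation against simulation truth: exact and relaxed true
# positives, separately for complete reads and junction-spanning reads,
# optionally broken down by gene expression level.

#' Classify predicted mappings against the truth
#'
#' A prediction is `exact` when every base is placed correctly (identical
#' block structure), `relaxed_only` when it is not exact but the outermost
#' genomic start or end matches the truth, and `fn` when the read is
#' unmapped, reported more than once, or placed with neither endpoint
#' correct.
#'
#' @param predicted Final alignment tibble (at most one row per read; any
#'   duplicated read id is guarded against and counted as `fn`).
#' @param truth Truth tibble from [simulate_reads()].
#' @return A tibble with one row per truth read: `read_id`, `gene_id`,
#'   `class` (`"complete"`/`"junction"`) and `outcome`.
#' @export
classify_predictions <- function(predicted, truth) {
  dup <- unique(predicted$read_id[duplicated(predicted$read_id)])
  if (length(dup)) {
    warning(length(dup), " read(s) predicted more than once; counted as FN")
    predicted <- predicted[!predicted$read_id %in% dup, , drop = FALSE]
  }
  p <- predicted[c("read_id", "rname", "start1", "end1", "start2", "end2")]
  names(p)[-1] <- paste0("p_", names(p)[-1])
  m <- dplyr::left_join(truth, p, by = "read_id")
  same2 <- function(a, b) (is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b)
  mapped <- !is.na(m$p_rname) & m$p_rname == m$rname
  exact <- mapped & m$p_start1 == m$start1 & m$p_end1 == m$end1 &
    same2(m$p_start2, m$start2) & same2(m$p_end2, m$end2)
  t_end <- outer_end(m$end1, m$end2)
  p_end <- outer_end(m$p_end1, m$p_end2)
  relaxed <- mapped & !exact &
    (m$p_start1 == m$start1 | (!is.na(p_end) & p_end == t_end))
  tibble(
    read_id = m$read_id, gene_id = m$gene_id,
    class = ifelse(is.na(m$start2), "complete", "junction"),
    outcome = ifelse(exact, "exact",
                     ifelse(relaxed, "relaxed_only", "fn")))
}

#' Mapping accuracy
#'
#' `TP / (TP + FN)`; `NA` when no read falls in the class.
#'
#' @param tp,fn Non-negative counts.
#' @return Numeric accuracy in `[0, 1]`.
#' @export
accuracy <- function(tp, fn) {
  stopifnot(all(tp >= 0), all(fn >= 0))
  ifelse(tp + fn == 0, NA_real_, tp / (tp + fn))
}

summarise_outcomes <- function(cls) {
  cls |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n = dplyr::n(),
      exact_tp = sum(.data$outcome == "exact"),
      relaxed_tp = sum(.data$outcome != "fn"),
      fn = sum(.data$outcome == "fn"),
      .groups = "drop") |>
    dplyr::mutate(
      exact_accuracy = accuracy(.data$exact_tp, .data$n - .data$exact_tp),
      relaxed_accuracy = accuracy(.data$relaxed_tp, .data$n - .data$relaxed_tp))
}

#' Evaluate a final mapping against simulation truth
#'
#' @param predicted Final alignment tibble.
#' @param truth Truth tibble.
#' @param genes Optional gene-model tibble; when given, genes are split into
#'   four near-equal groups by average read count per transcript base and
#'   accuracies are reported per group as well (see
#'   [coverage_binned_accuracy()]).
#' @return An object of class `eval_result`: list with `per_read`
#'   classifications, the per-class `summary` tibble and, when `genes` is
#'   given, the per-bin `bins` tibble.
#' @export
evaluate_mapping <- function(predicted, truth, genes = NULL) {
  cls <- classify_predictions(predicted, truth)
  res <- list(per_read = cls, summary = summarise_outcomes(cls),
              bins = NULL)
  if (!is.null(genes)) {
    res$bins <- coverage_binned_accuracy(cls, genes, truth)
  }
  structure(res, class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("<eval_result>\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  if (!is.null(x$bins)) {
    cat("coverage bins (1 = lowest expression):\n")
    print(as.data.frame(x$bins), row.names = FALSE)
  }
  invisible(x)
}

#' Accuracy binned by gene expression level
#'
#' Genes are ranked by average read count per transcript base (simulated
#' reads times read length over transcript length) and cut into four groups
#' of near-equal gene count (quantile cuts on the rank, stable order);
#' accuracy is then computed per group and read class.
#'
#' @param classified Per-read classification tibble from
#'   [classify_predictions()] (or an `eval_result`'s `per_read`).
#' @param genes Gene-model tibble with `gene_id` and `tx_length`.
#' @param truth Truth tibble (supplies per-gene read counts).
#' @param n_bins Number of expression groups (fewer when there are fewer
#'   genes, with a message).
#' @return A tibble: `bin`, `class`, counts and accuracies.
#' @export
coverage_binned_accuracy <- function(classified, genes, truth, n_bins = 4L) {
  counts <- truth |>
    dplyr::count(.data$gene_id, name = "n_reads")
  g <- dplyr::left_join(genes[c("gene_id", "tx_length")], counts,
                        by = "gene_id")
  g$n_reads[is.na(g$n_reads)] <- 0L
  rl <- stats::median(outer_end(truth$end1, truth$end2) - truth$start1 -
                        ifelse(is.na(truth$start2), 0L,
                               truth$start2 - truth$end1))
  g$cov_per_base <- g$n_reads * rl / g$tx_length
  nb <- min(n_bins, nrow(g))
  if (nb < n_bins) message("only ", nrow(g), " gene(s); using ", nb, " bin(s)")
  g <- g[order(g$cov_per_base, g$gene_id, method = "radix"), ]
  g$bin <- ceiling(seq_len(nrow(g)) / (nrow(g) / nb))
  cls <- dplyr::left_join(classified, g[c("gene_id", "bin")], by = "gene_id")
  cls |>
    dplyr::group_by(bin = .data$bin, class = .data$class) |>
    dplyr::summarise(
      n = dplyr::n(),
      exact_tp = sum(.data$outcome == "exact"),
      relaxed_tp = sum(.data$outcome != "fn"),
      .groups = "drop") |>
    dplyr::mutate(
      exact_accuracy = accuracy(.data$exact_tp, .data$n - .data$exact_tp),
      relaxed_accuracy = accuracy(.data$relaxed_tp, .data$n - .data$relaxed_tp))
}
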