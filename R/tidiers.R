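# broom-style tidiers for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an evaluation result
#'
#' @param x An `eval_result` from [evaluate_mapping()].
#' @param ... Unused.
#' @return The per-class summary as a tibble (one row per read class, with
#'   counts and accuracies); per-bin rows are appended when the evaluation
#'   was expression-binned.
#' @export
tidy.eval_result <- function(x, ...) {
  out <- dplyr::mutate(x$summary, bin = NA_integer_, .before = 1)
  if (!is.null(x$bins)) {
    out <- dplyr::bind_rows(out, dplyr::mutate(
      x$bins, fn = .data$n - .data$relaxed_tp))
  }
  out
}

#' @rdname tidy.eval_result
#' @return For `glance`: a one-row tibble with the four headline accuracies.
#' @export
glance.eval_result <- function(x, ...) {
  s <- x$summary
  grab <- function(cl, col) {
    v <- s[[col]][s$class == cl]
    if (length(v) == 0) NA_real_ else v
  }
  tibble(
    exact_complete = grab("complete", "exact_accuracy"),
    relaxed_complete = grab("complete", "relaxed_accuracy"),
    exact_junction = grab("junction", "exact_accuracy"),
    relaxed_junction = grab("junction", "relaxed_accuracy"))
}

#' Tidy a refinement result
#'
#' @param x A `refine_result` from [refine_reads()].
#' @param ... Unused.
#' @return For `tidy`: the final per-read assignments as a tibble. For
#'   `glance`: the one-row pipeline summary.
#' @export
tidy.refine_result <- function(x, ...) tibble::as_tibble(x$final)

#' @rdname tidy.refine_result
#' @export
glance.refine_result <- function(x, ...) x$summary
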