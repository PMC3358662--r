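# Pipeline configuration: one validated key-value list drives every module.

refine_config_defaults <- function() {
  list(
    # context identification
    d_min = 10000L,          # minimum separation between contexts (bp)
    pad = NULL,              # context window padding; NULL = read length
    annotation_bed = NULL,   # optional BED file defining contexts directly
    # candidate generation
    seed_fraction = 0.4,     # seed = ceil(seed_fraction * l) ...
    seed_cap = 40L,          # ... capped at this many bp
    seed_mm = 1L,            # mismatches tolerated inside the seed
    max_mm = 4L,             # maximum mismatches per alignment
    min_intron = 20L,        # splice gap bounds (bp)
    max_intron = 400000L,
    splice_signals = "GT-AG",# canonical donor-acceptor motifs
    min_seed_len = 10L,      # reads shorter than 2x this are rejected
    # ambiguity resolution
    delta_mm = 2L,           # allowed excess mismatches across contexts
    region_bounds = c(200L, 500L, 1000L),  # coverage-score region edges (bp)
    region_weight_base = 2,  # region i carries weight base^(4-i)
    mm_weight = 0.3,         # per-mismatch weight decay in splice evidence
    lambda_signal = 2,       # evidence multiplier for signal-bearing sites
    resolution_mode = "static",
    min_support = 100L,      # expression filter: neighbours required ...
    support_window = 1000L   # ... within this many bp up/downstream
  )
}

#' Build a validated pipeline configuration
#'
#' Unknown keys are rejected; values override the documented defaults.
#'
#' @param ... Named configuration overrides (see
#'   [refine_config_defaults()] source for the full key list, or the
#'   methods vignette for what each key controls).
#' @param yaml Optional path to a YAML file of overrides; explicit `...`
#'   arguments win over file values.
#' @return A named list with class `refine_config`.
#' @export
refine_config <- function(..., yaml = NULL) {
  cfg <- refine_config_defaults()
  overrides <- list()
  if (!is.null(yaml)) {
    overrides <- yaml::read_yaml(yaml)
    if (!is.list(overrides)) stop("config file must be a YAML mapping")
  }
  dots <- list(...)
  overrides[names(dots)] <- dots
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  with(cfg, {
    stopifnot(d_min > 0, seed_fraction > 0, seed_fraction <= 1,
              seed_cap >= 1, seed_mm >= 0, max_mm >= 0,
              min_intron >= 1, max_intron >= min_intron,
              delta_mm >= 0, length(region_bounds) == 3,
              all(diff(region_bounds) > 0),
              mm_weight > 0, mm_weight < 1, lambda_signal >= 1,
              min_support >= 0, support_window >= 0)
  })
  if (!cfg$resolution_mode %in% c("static", "dynamic")) {
    stop("resolution_mode must be 'static' or 'dynamic'")
  }
  structure(cfg, class = "refine_config")
}

#' @export
print.refine_config <- function(x, ...) {
  cat("<refine_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-18s %s\n", k,
                if (is.null(v)) "NULL" else paste(v, collapse = ", ")))
  }
  invisible(x)
}

# donor/acceptor pairs from "GT-AG"-style strings, plus their reverse
# complements (an intron on the minus strand reads CT..AC genome-forward)
parse_signals <- function(signals) {
  parts <- strsplit(signals, "-", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) stop("splice signals must look like 'GT-AG'")
  donors <- toupper(vapply(parts, `[`, "", 1))
  acceptors <- toupper(vapply(parts, `[`, "", 2))
  list(donor = c(donors, revcomp(acceptors)),
       acceptor = c(acceptors, revcomp(donors)))
}
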