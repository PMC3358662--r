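# Shared fixtures and independent brute-force oracles. Everything is built
# in code under fixed seeds; the two large simulations are cached for the
# session because several files exercise them.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

make_aln <- function(read_id, start1, end1, start2 = NA_integer_,
                     end2 = NA_integer_, rname = "chr1", strand = "+",
                     mismatches = 0L, provenance = "initial") {
  tibble::tibble(read_id = read_id, rname = rname, strand = strand,
                 start1 = as.integer(start1), end1 = as.integer(end1),
                 start2 = as.integer(start2), end2 = as.integer(end2),
                 mismatches = as.integer(mismatches),
                 provenance = provenance)
}

make_profile <- function(cov, start = 0L) {
  structure(list(window_start = as.integer(start),
                 window_end = as.integer(start) + length(cov),
                 cov = as.integer(cov)),
            class = "coverage_profile")
}

# random alignment set for SAM round trips and context fixtures
random_alignments <- function(n, ref_len = 50000L, read_len = 50L,
                              p_split = 0.4, rnames = "chr1") {
  rn <- sample(rnames, n, replace = TRUE)
  is_split <- stats::runif(n) < p_split
  s1 <- sample.int(ref_len - 2L * read_len - 1200L, n) - 1L
  l1 <- ifelse(is_split, sample(10:(read_len - 10L), n, replace = TRUE),
               read_len)
  gap <- sample(30:1000, n, replace = TRUE)
  tibble::tibble(
    read_id = sprintf("r%04d", seq_len(n)),
    rname = rn,
    strand = sample(c("+", "-"), n, replace = TRUE),
    start1 = s1, end1 = s1 + l1,
    start2 = ifelse(is_split, s1 + l1 + gap, NA_integer_),
    end2 = ifelse(is_split, s1 + l1 + gap + (read_len - l1), NA_integer_),
    mismatches = sample(0:3, n, replace = TRUE),
    provenance = "initial")
}

# O(n^2) connected components under the start/end distance relation: every
# pair is tested, the gap between two reads' outermost intervals (0 when
# they overlap) must be at most d_min
bf_contexts <- function(alignments, d_min) {
  n <- nrow(alignments)
  s <- alignments$start1
  e <- ifelse(is.na(alignments$end2), alignments$end1, alignments$end2)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    if (i == n) break
    j <- (i + 1L):n
    gap <- pmax(0L, pmax(s[i], s[j]) - pmin(e[i], e[j]))
    for (z in j[gap <= d_min & alignments$rname[j] == alignments$rname[i]]) {
      ri <- find(i); rj <- find(z)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  split(alignments$read_id, paste(alignments$rname, comp))
}

# naive directional aligner: Hamming comparison at every window offset
bf_align <- function(read, window, direction, seed_len, seed_mm = 1L,
                     max_mm = 4L) {
  l <- nchar(read); w <- nchar(window)
  q <- utf8ToInt(read); wi <- utf8ToInt(window)
  out <- list()
  if (direction == "forward") {
    for (p in 0:(w - seed_len)) {
      if (sum(q[1:seed_len] != wi[(p + 1):(p + seed_len)]) > seed_mm) next
      avail <- min(l, w - p)
      neq <- which(q[1:avail] != wi[(p + 1):(p + avail)])
      matched <- if (length(neq) > max_mm) neq[max_mm + 1L] - 1L else avail
      if (matched < seed_len) next
      out[[length(out) + 1]] <- c(p, matched, sum(neq <= matched))
    }
  } else {
    for (p in (seed_len - l):(w - l)) {   # q0 may be negative
      sb <- l - seed_len
      if (p + sb < 0 || p + l > w) next
      if (sum(q[(sb + 1):l] != wi[(p + sb + 1):(p + l)]) > seed_mm) next
      lo <- max(0L, -p)
      neq <- which(q[(lo + 1):l] != wi[(p + lo + 1):(p + l)]) + lo
      matched <- if (length(neq) > max_mm) {
        l - neq[length(neq) - max_mm]
      } else l - lo
      if (matched < seed_len) next
      out[[length(out) + 1]] <- c(p, matched, sum(neq > l - matched))
    }
  }
  if (length(out) == 0) {
    return(data.frame(q0 = integer(0), matched_len = integer(0),
                      n_mm = integer(0)))
  }
  m <- do.call(rbind, out)
  data.frame(q0 = m[, 1], matched_len = m[, 2], n_mm = m[, 3])
}

# independent evidence computation from a raw supporter table
bf_evidence <- function(supporters, signal, lambda_signal = 2,
                        mm_weight = 0.3) {
  lam <- if (signal) lambda_signal else 1
  lam * sum(mm_weight^supporters$mm)
}

# naive coverage score: scan every position of every region
bf_coverage_score <- function(aln_row, cov, win_start,
                              bounds = c(200L, 500L, 1000L), base = 2) {
  win_end <- win_start + length(cov)
  at <- function(pos) {   # c_m at genomic positions, clipped
    pos <- pos[pos >= win_start & pos < win_end]
    if (length(pos) == 0) return(0L)
    max(cov[pos - win_start + 1L])
  }
  aligned <- aln_row$start1:(aln_row$end1 - 1L)
  if (!is.na(aln_row$start2)) {
    aligned <- c(aligned, aln_row$start2:(aln_row$end2 - 1L))
  }
  s <- aln_row$start1
  e <- if (is.na(aln_row$end2)) aln_row$end1 else aln_row$end2
  edges <- c(0L, bounds)
  scores <- c(at(aligned), vapply(1:3, function(r) {
    up <- (s - edges[r + 1L]):(s - edges[r] - 1L)
    dn <- (e + edges[r]):(e + edges[r + 1L] - 1L)
    max(at(up), at(dn))
  }, 0L))
  sum(base^(3:0) * log(pmax(scores, 1)))
}

# session-cached large simulations -------------------------------------------
.fixture_cache <- new.env(parent = emptyenv())

# the standard study fixture: 20 genes, 20,000 74-bp reads, 1% uniform
# errors, degraded with p_multimap = 0.3 and p_shift = 0.3
standard_fixture <- function() {
  if (is.null(.fixture_cache$std)) {
    dir <- file.path(tempdir(), "splicerefine-std")
    sim <- simulate_dataset(out_dir = dir, n_genes = 20, n_reads = 20000,
                            read_length = 74, error_rate = 0.01,
                            error_model = "uniform", seed = 101,
                            p_drop = 0.05, p_multimap = 0.3, p_shift = 0.3,
                            p_misplace = 0.05)
    res <- suppressWarnings(refine_reads(
      sim$references, file.path(dir, "initial.sam"), sim$reads,
      config = refine_config()))
    .fixture_cache$std <- list(sim = sim, res = res, dir = dir)
  }
  .fixture_cache$std
}

# the same study conditions without sequencing errors; degraded with the
# three canonical branches only (no unique misreporting, which by contract
# is never re-aligned and so is out of scope for candidate completeness)
errorfree_fixture <- function() {
  if (is.null(.fixture_cache$ef)) {
    dir <- file.path(tempdir(), "splicerefine-ef")
    sim <- simulate_dataset(out_dir = dir, n_genes = 20, n_reads = 20000,
                            read_length = 74, error_rate = 0,
                            error_model = "uniform", seed = 202,
                            p_drop = 0.05, p_multimap = 0.3, p_shift = 0.3,
                            p_misplace = 0)
    res <- suppressWarnings(refine_reads(
      sim$references, file.path(dir, "initial.sam"), sim$reads,
      config = refine_config()))
    .fixture_cache$ef <- list(sim = sim, res = res, dir = dir)
  }
  .fixture_cache$ef
}

# a small, fast end-to-end fixture for module tests
small_fixture <- function() {
  if (is.null(.fixture_cache$small)) {
    dir <- file.path(tempdir(), "splicerefine-small")
    sim <- simulate_dataset(out_dir = dir, n_genes = 4, n_reads = 1200,
                            read_length = 74, error_rate = 0.01,
                            error_model = "uniform", seed = 303,
                            genome_length = 3e5, pseudogene_frac = 0.5)
    res <- suppressWarnings(refine_reads(
      sim$references, file.path(dir, "initial.sam"), sim$reads,
      config = refine_config(min_support = 0)))
    .fixture_cache$small <- list(sim = sim, res = res, dir = dir)
  }
  .fixture_cache$small
}
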