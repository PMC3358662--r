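# Truth-annotated synthetic data: genomes with multi-exon gene models,
# expression-weighted reads carrying positional sequencing errors, and a
# deliberately degraded initial mapping. Every downstream module is testable
# against the recorded truth without external data.

#' Simulate a genome with multi-exon gene models
#'
#' Generates a random reference sequence and places `n_genes` spliced gene
#' loci on it, pairwise separated by more than `d_min` so that the true
#' expression contexts are unambiguous. Introns carry the canonical GT..AG
#' signal in transcription orientation. For a fraction of genes an
#' intronless copy of the spliced transcript is additionally planted at a
#' distant locus (a processed-pseudogene emulation): reads from the parent
#' gene then have a second, sequence-identical placement, which is exactly
#' the multi-mapping structure coverage-based resolution has to untangle.
#'
#' @param n_genes Number of expressed genes.
#' @param genome_length Reference length in bp.
#' @param n_exons Integer range (min, max) of exons per gene.
#' @param exon_length,intron_length Length ranges (min, max) in bp.
#' @param pseudogene_frac Fraction of genes that also get an intronless
#'   transcript copy elsewhere on the genome.
#' @param d_min Minimum separation between loci in bp.
#' @param weight_log10_range Expression weights are drawn log-uniformly as
#'   `10^U(range)`; the default spans two orders of magnitude.
#' @param d_min_jitter Upper bound of the uniform extra gap added on top of
#'   `d_min` between consecutive loci.
#' @param rname Reference sequence name.
#' @param seed Optional integer seed; fixed seed gives byte-identical output.
#' @return A list with `references` (a named [Biostrings::DNAStringSet]) and
#'   `genes`, a tibble with one row per gene: `gene_id`, `rname`, `strand`,
#'   list-columns `exon_starts`/`exon_ends` (0-based half-open), `weight`,
#'   `tx_length`, and `pseudo_start`/`pseudo_end` (NA when the gene has no
#'   planted transcript copy).
#' @export
simulate_gene_models <- function(n_genes = 20, genome_length = 1e6,
                                 n_exons = c(2L, 5L),
                                 exon_length = c(150L, 400L),
                                 intron_length = c(100L, 1000L),
                                 pseudogene_frac = 0.3,
                                 d_min = 10000L,
                                 weight_log10_range = c(0, 2),
                                 d_min_jitter = 2000L,
                                 rname = "chr1", seed = NULL) {
  stopifnot(n_genes >= 1, all(exon_length > 0), all(intron_length >= 20),
            intron_length[1] >= 5)  # room for both signal dinucleotides
  genome_length <- as.integer(genome_length)
  d_min <- as.integer(d_min)
  d_min_jitter <- as.integer(d_min_jitter)
  exon_length <- as.integer(exon_length)
  intron_length <- as.integer(intron_length)
  n_exons <- as.integer(n_exons)
  local_seed(seed)

  k_pseudo <- floor(pseudogene_frac * n_genes)
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  nex <- sample(n_exons[1]:n_exons[2], n_genes, replace = TRUE)
  exlens <- lapply(nex, function(k)
    sample(exon_length[1]:exon_length[2], k, replace = TRUE))
  inlens <- lapply(nex, function(k)
    if (k > 1) sample(intron_length[1]:intron_length[2], k - 1L,
                      replace = TRUE) else integer(0))
  tx_len <- vapply(exlens, sum, 0L)
  span <- tx_len + vapply(inlens, sum, 0L)
  pseudo_for <- if (k_pseudo > 0) sort(sample(n_genes, k_pseudo)) else integer(0)

  # sequential packing: gene loci then their transcript copies, shuffled,
  # every consecutive pair separated by more than d_min
  kinds <- c(rep("gene", n_genes), rep("pseudo", length(pseudo_for)))
  owner <- c(seq_len(n_genes), pseudo_for)
  locus_span <- c(span, tx_len[pseudo_for])
  ord <- sample(length(kinds))
  gaps <- d_min + 1L + sample.int(max(1L, d_min_jitter), length(kinds),
                                  replace = TRUE)
  starts <- integer(length(kinds))
  pos <- gaps[1]
  for (i in seq_along(ord)) {
    starts[i] <- pos
    pos <- pos + locus_span[ord[i]] + if (i < length(ord)) gaps[i + 1L] else d_min
  }
  if (pos > genome_length) {
    stop("cannot place ", length(kinds), " loci: need ", pos,
         " bp but genome_length is ", genome_length)
  }

  chars <- sample(c("A", "C", "G", "T"), genome_length, replace = TRUE)

  gene_start <- integer(n_genes)
  pseudo_start <- rep(NA_integer_, n_genes)
  for (i in seq_along(ord)) {
    g <- owner[ord[i]]
    if (kinds[ord[i]] == "gene") gene_start[g] <- starts[i]
    else pseudo_start[g] <- starts[i]
  }

  exon_starts <- vector("list", n_genes)
  exon_ends <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    es <- integer(nex[g]); ee <- integer(nex[g])
    at <- gene_start[g]
    for (e in seq_len(nex[g])) {
      es[e] <- at; ee[e] <- at + exlens[[g]][e]
      at <- ee[e] + if (e < nex[g]) inlens[[g]][e] else 0L
    }
    exon_starts[[g]] <- es; exon_ends[[g]] <- ee
    # install splice signals, transcription-oriented
    if (nex[g] > 1) {
      for (e in seq_len(nex[g] - 1L)) {
        i0 <- ee[e]; i1 <- es[e + 1L]  # intron [i0, i1)
        if (strands[g] == "+") {
          chars[(i0 + 1L):(i0 + 2L)] <- c("G", "T")
          chars[(i1 - 1L):i1] <- c("A", "G")
        } else {
          chars[(i0 + 1L):(i0 + 2L)] <- c("C", "T")
          chars[(i1 - 1L):i1] <- c("A", "C")
        }
      }
    }
  }
  # transcript copies are pasted after signal installation so the copy is
  # exactly the spliced sequence
  for (g in which(!is.na(pseudo_start))) {
    tx <- unlist(lapply(seq_along(exon_starts[[g]]), function(e)
      chars[(exon_starts[[g]][e] + 1L):exon_ends[[g]][e]]))
    chars[(pseudo_start[g] + 1L):(pseudo_start[g] + length(tx))] <- tx
  }

  genes <- tibble(
    gene_id = sprintf("gene%02d", seq_len(n_genes)),
    rname = rname, strand = strands,
    exon_starts = exon_starts, exon_ends = exon_ends,
    weight = 10^stats::runif(n_genes, weight_log10_range[1],
                             weight_log10_range[2]),
    tx_length = tx_len,
    pseudo_start = pseudo_start,
    pseudo_end = pseudo_start + tx_len
  )
  refs <- Biostrings::DNAStringSet(stats::setNames(
    paste(chars, collapse = ""), rname))
  list(references = refs, genes = genes)
}

#' Sample positional offsets for sequencing errors
#'
#' The uniform model places errors uniformly over the read. The polynomial
#' model emulates quality decay towards the read end: the continuous error
#' position follows the cumulative distribution F(x) = x^3 / l^3, sampled by
#' inversion as `x = l * U^(1/3)` and floored to an offset. Duplicate offsets
#' are resampled (bounded, with an exhaustive weighted fallback).
#'
#' @param l Read length.
#' @param n_errors Number of distinct offsets to draw (`<= l`).
#' @param model `"uniform"` or `"polynomial"`.
#' @return A strictly increasing integer vector of 0-based offsets.
#' @export
sample_error_positions <- function(l, n_errors, model = c("uniform", "polynomial")) {
  model <- match.arg(model)
  stopifnot(n_errors >= 0, n_errors <= l)
  if (n_errors == 0) return(integer(0))
  if (model == "uniform") {
    return(sort(sample.int(l, n_errors) - 1L))
  }
  draw <- function(n) pmin(l - 1L, as.integer(floor(l * stats::runif(n)^(1 / 3))))
  off <- unique(draw(n_errors))
  tries <- 0L
  while (length(off) < n_errors && tries < 100L) {
    off <- unique(c(off, draw(n_errors - length(off))))
    tries <- tries + 1L
  }
  if (length(off) < n_errors) {
    pmf <- ((seq_len(l))^3 - (seq_len(l) - 1L)^3) / l^3
    rest <- setdiff(seq_len(l) - 1L, off)
    off <- c(off, sample(rest, n_errors - length(off),
                         prob = pmf[rest + 1L]))
  }
  sort(off[seq_len(n_errors)])
}

# map an interval [c1, c2) of the exon concatenation (genome-forward order)
# to genomic blocks; returns NULL when more than 2 blocks would be needed
concat_to_blocks <- function(c1, c2, exon_starts, exon_ends) {
  exlen <- exon_ends - exon_starts
  cum <- cumsum(c(0L, exlen))
  e1 <- findInterval(c1, cum, rightmost.closed = FALSE)       # 1-based exon
  e2 <- findInterval(c2 - 1L, cum, rightmost.closed = FALSE)
  if (e2 - e1 > 1L) return(NULL)
  g1 <- exon_starts[e1] + (c1 - cum[e1])
  g2 <- exon_starts[e2] + (c2 - cum[e2])
  if (e1 == e2) {
    list(start1 = g1, end1 = g2, start2 = NA_integer_, end2 = NA_integer_)
  } else {
    list(start1 = g1, end1 = exon_ends[e1], start2 = exon_starts[e2], end2 = g2)
  }
}

#' Simulate expression-weighted reads with sequencing errors
#'
#' Reads are sampled gene-by-gene proportionally to expression weight and
#' uniformly within the spliced transcript. Each read carries
#' `Binomial(l, error_rate)` substitutions at offsets drawn from the chosen
#' positional model; the substituted base always differs from the original.
#' Reads that would span more than one splice junction are redrawn, matching
#' a split-alignment model of at most one splice per read.
#'
#' @param genes,references Output of [simulate_gene_models()].
#' @param n_reads Number of reads.
#' @param read_length Read length `l` in bp.
#' @param error_rate Per-base substitution probability.
#' @param error_model Positional model, see [sample_error_positions()].
#' @param seed Optional integer seed.
#' @return A list with `reads` (tibble: `read_id`, `bases`, `qualities`) and
#'   `truth`, a tibble holding the true genomic blocks (`start1`..`end2`),
#'   `strand`, the 0-based `error_offsets` within the read (list-column) and
#'   the source `gene_id`.
#' @export
simulate_reads <- function(genes, references, n_reads, read_length = 74L,
                           error_rate = 0.01,
                           error_model = c("uniform", "polynomial"),
                           seed = NULL) {
  error_model <- match.arg(error_model)
  l <- as.integer(read_length)
  local_seed(seed)
  usable <- genes$tx_length >= l
  if (!all(usable)) {
    warning(sum(!usable), " gene(s) with transcript shorter than ", l,
            " bp skipped")
    genes <- genes[usable, , drop = FALSE]
  }
  if (nrow(genes) == 0) stop("no gene with transcript length >= ", l)
  ref_chars <- stats::setNames(as.character(references), names(references))

  gi <- sample.int(nrow(genes), n_reads, replace = TRUE, prob = genes$weight)
  bases <- character(n_reads)
  truth_rows <- vector("list", n_reads)
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"),
              N = c("A", "C", "G"))
  for (i in seq_len(n_reads)) {
    g <- gi[i]
    es <- genes$exon_starts[[g]]; ee <- genes$exon_ends[[g]]
    L <- genes$tx_length[g]
    b <- NULL
    for (try in 1:50) {
      t0 <- sample.int(L - l + 1L, 1L) - 1L
      c1 <- if (genes$strand[g] == "+") t0 else L - t0 - l
      b <- concat_to_blocks(c1, c1 + l, es, ee)
      if (!is.null(b)) break
    }
    if (is.null(b)) next  # pathological structure; leave empty, filtered below
    gseq <- substr(ref_chars[[genes$rname[g]]], b$start1 + 1L, b$end1)
    if (!is.na(b$start2)) {
      gseq <- paste0(gseq, substr(ref_chars[[genes$rname[g]]],
                                  b$start2 + 1L, b$end2))
    }
    rd <- if (genes$strand[g] == "+") gseq else revcomp(gseq)
    n_err <- stats::rbinom(1L, l, error_rate)
    offs <- sample_error_positions(l, n_err, error_model)
    if (n_err > 0) {
      ch <- strsplit(rd, "")[[1]]
      for (o in offs) ch[o + 1L] <- sample(alt[[ch[o + 1L]]], 1L)
      rd <- paste(ch, collapse = "")
    }
    bases[i] <- rd
    truth_rows[[i]] <- list(rname = genes$rname[g], strand = genes$strand[g],
                            start1 = b$start1, end1 = b$end1,
                            start2 = b$start2, end2 = b$end2,
                            error_offsets = offs, gene_id = genes$gene_id[g])
  }
  keep <- !vapply(truth_rows, is.null, TRUE)
  truth_rows <- truth_rows[keep]
  ids <- sprintf("read%06d", seq_along(truth_rows))
  truth <- tibble(
    read_id = ids,
    rname = vapply(truth_rows, `[[`, "", "rname"),
    strand = vapply(truth_rows, `[[`, "", "strand"),
    start1 = vapply(truth_rows, `[[`, 0L, "start1"),
    end1 = vapply(truth_rows, `[[`, 0L, "end1"),
    start2 = vapply(truth_rows, `[[`, 0L, "start2"),
    end2 = vapply(truth_rows, `[[`, 0L, "end2"),
    error_offsets = lapply(truth_rows, `[[`, "error_offsets"),
    gene_id = vapply(truth_rows, `[[`, "", "gene_id")
  )
  reads <- tibble(read_id = ids, bases = bases[keep],
                  qualities = NA_character_)
  list(reads = reads, truth = truth)
}

# exon-concatenation offset of genomic position g1 within a gene
genomic_to_concat <- function(g1, exon_starts, exon_ends) {
  cum <- cumsum(c(0L, exon_ends - exon_starts))
  e <- max(which(exon_starts <= g1))
  cum[e] + (g1 - exon_starts[e])
}

#' Degrade a truth mapping into an imperfect initial mapping
#'
#' Emulates the initial mapping an external read mapper would produce: each
#' read is independently dropped (left out of the SAM), reported as a
#' multi-mapping pair of records (truth plus a decoy locus), reported
#' uniquely at the decoy locus, or -- for junction reads -- emitted without
#' its splice, either as an ungapped record reading through the intron or as
#' a soft-clipped single-block record. The decoy locus is the homologous
#' position in the gene's planted transcript copy when one exists, otherwise
#' a uniform random locus.
#'
#' @param truth,reads Output of [simulate_reads()].
#' @param references Reference [Biostrings::DNAStringSet].
#' @param genes Gene-model tibble (needed for homologous decoy placement;
#'   `NULL` makes all decoys random).
#' @param p_drop,p_multimap,p_misplace,p_shift Category probabilities (the
#'   remainder is reported correctly and uniquely); `p_misplace` applies only
#'   to reads of genes with a transcript copy, `p_shift` only to junction
#'   reads.
#' @param seed Optional integer seed.
#' @param path Optional output path; mapped records are written as SAM
#'   (dropped reads are simply absent, as real mappers leave them).
#' @return Invisibly, a tibble of emitted records with columns `read_id`,
#'   `rname`, `strand`, `pos` (0-based), `cigar`, `nm` and `category`.
#' @export
degrade_to_initial_mapping <- function(truth, reads, references, genes = NULL,
                                       p_drop = 0.05, p_multimap = 0.3,
                                       p_shift = 0.3, p_misplace = 0.05,
                                       seed = NULL, path = NULL) {
  stopifnot(all(c(p_drop, p_multimap, p_shift, p_misplace) >= 0),
            all(c(p_drop, p_multimap, p_shift, p_misplace) <= 1))
  local_seed(seed)
  ref_chars <- stats::setNames(as.character(references), names(references))
  bases_of <- stats::setNames(reads$bases, reads$read_id)

  has_pseudo <- rep(FALSE, nrow(truth))
  if (!is.null(genes)) {
    pg <- genes$gene_id[!is.na(genes$pseudo_start)]
    has_pseudo <- truth$gene_id %in% pg
    gidx <- stats::setNames(seq_len(nrow(genes)), genes$gene_id)
  }
  is_junction <- !is.na(truth$start2)
  l_of <- (truth$end1 - truth$start1) +
    ifelse(is_junction, truth$end2 - truth$start2, 0L)

  u <- stats::runif(nrow(truth))
  p2 <- p_drop + p_multimap
  p3 <- p2 + ifelse(has_pseudo, p_misplace, 0)
  p4 <- p3 + ifelse(is_junction, p_shift, 0)
  category <- ifelse(u < p_drop, "drop",
              ifelse(u < p2, "multimap",
              ifelse(u < p3, "misplace",
              ifelse(u < p4, "shift", "keep"))))
  clip_side <- stats::runif(nrow(truth)) < 0.5   # shift: clip vs read-through
  decoy_at <- stats::runif(nrow(truth))          # random decoy draw, reused

  fwd_seq <- ifelse(truth$strand == "-", revcomp(bases_of[truth$read_id]),
                    bases_of[truth$read_id])

  nm_vs_ref <- function(i, starts, ends) {
    w <- ref_chars[[truth$rname[i]]]
    q <- seq_ints(fwd_seq[i])
    tot <- 0L; q0 <- 0L
    for (b in seq_along(starts)) {
      len <- ends[b] - starts[b]
      wseg <- utf8ToInt(substr(w, starts[b] + 1L, ends[b]))
      tot <- tot + sum(q[(q0 + 1L):(q0 + len)] != wseg)
      q0 <- q0 + len
    }
    tot
  }
  decoy_block <- function(i) {
    l <- l_of[i]
    if (has_pseudo[i]) {
      g <- gidx[[truth$gene_id[i]]]
      c1 <- genomic_to_concat(truth$start1[i], genes$exon_starts[[g]],
                              genes$exon_ends[[g]])
      c(genes$pseudo_start[g] + c1, genes$pseudo_start[g] + c1 + l)
    } else {
      maxs <- nchar(ref_chars[[truth$rname[i]]]) - l
      s <- as.integer(floor(decoy_at[i] * maxs))
      c(s, s + l)
    }
  }

  recs <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    cat_i <- category[i]
    if (cat_i == "drop") next
    truth_rec <- tibble(
      read_id = truth$read_id[i], rname = truth$rname[i],
      strand = truth$strand[i], pos = truth$start1[i],
      cigar = cigar_from_blocks(truth$start1[i], truth$end1[i],
                                truth$start2[i], truth$end2[i]),
      nm = length(truth$error_offsets[[i]]), category = cat_i)
    if (cat_i == "keep") {
      recs[[i]] <- truth_rec
    } else if (cat_i == "multimap") {
      d <- decoy_block(i)
      recs[[i]] <- dplyr::bind_rows(truth_rec, tibble(
        read_id = truth$read_id[i], rname = truth$rname[i],
        strand = truth$strand[i], pos = d[1],
        cigar = paste0(l_of[i], "M"),
        nm = nm_vs_ref(i, d[1], d[2]), category = cat_i))
    } else if (cat_i == "misplace") {
      d <- decoy_block(i)
      recs[[i]] <- tibble(
        read_id = truth$read_id[i], rname = truth$rname[i],
        strand = truth$strand[i], pos = d[1],
        cigar = paste0(l_of[i], "M"),
        nm = nm_vs_ref(i, d[1], d[2]), category = cat_i)
    } else {                                    # shift (junction reads)
      l1 <- truth$end1[i] - truth$start1[i]
      l2 <- truth$end2[i] - truth$start2[i]
      if (clip_side[i]) {                       # soft-clipped longer block
        if (l1 >= l2) {
          cg <- paste0(l1, "M", l_of[i] - l1, "S"); p0 <- truth$start1[i]
        } else {
          cg <- paste0(l_of[i] - l2, "S", l2, "M"); p0 <- truth$start2[i]
        }
        recs[[i]] <- tibble(read_id = truth$read_id[i], rname = truth$rname[i],
                            strand = truth$strand[i], pos = p0, cigar = cg,
                            nm = 0L, category = cat_i)
      } else {                                  # ungapped read-through
        p0 <- truth$start1[i]
        recs[[i]] <- tibble(
          read_id = truth$read_id[i], rname = truth$rname[i],
          strand = truth$strand[i], pos = p0,
          cigar = paste0(l_of[i], "M"),
          nm = nm_vs_ref(i, p0, p0 + l_of[i]), category = cat_i)
      }
    }
  }
  records <- dplyr::bind_rows(recs)
  if (nrow(records) == 0) {
    records <- tibble(read_id = character(), rname = character(),
                      strand = character(), pos = integer(),
                      cigar = character(), nm = integer(),
                      category = character())
  }
  if (!is.null(path)) {
    hdr <- c("@HD\tVN:1.6\tSO:coordinate",
             paste0("@SQ\tSN:", names(references),
                    "\tLN:", Biostrings::width(references)))
    lines <- hdr
    if (nrow(records) > 0) {
      r <- records[order(records$rname, records$pos, records$read_id,
                         method = "radix"), ]
      sq <- ifelse(r$strand == "-", revcomp(bases_of[r$read_id]),
                   unname(bases_of[r$read_id]))
      lines <- c(hdr, paste(r$read_id, ifelse(r$strand == "-", 16L, 0L),
                            r$rname, r$pos + 1L, 255L, r$cigar, "*", 0L, 0L,
                            sq, "*", paste0("NM:i:", r$nm), sep = "\t"))
    }
    writeLines(lines, path)
  }
  invisible(records)
}

#' Write / read the simulation truth table
#'
#' Plain TSV with comma-separated block coordinates and error offsets, so the
#' truth survives a round trip through files byte-identically.
#'
#' @param truth Truth tibble from [simulate_reads()].
#' @param path File path.
#' @export
write_truth_tsv <- function(truth, path) {
  df <- data.frame(
    read_id = truth$read_id, rname = truth$rname, strand = truth$strand,
    starts = ifelse(is.na(truth$start2), as.character(truth$start1),
                    paste(truth$start1, truth$start2, sep = ",")),
    ends = ifelse(is.na(truth$end2), as.character(truth$end1),
                  paste(truth$end1, truth$end2, sep = ",")),
    error_offsets = vapply(truth$error_offsets, paste, "", collapse = ","),
    gene_id = truth$gene_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  s <- strsplit(df$starts, ",", fixed = TRUE)
  e <- strsplit(df$ends, ",", fixed = TRUE)
  tibble(
    read_id = df$read_id, rname = df$rname, strand = df$strand,
    start1 = as.integer(vapply(s, `[`, "", 1)),
    end1 = as.integer(vapply(e, `[`, "", 1)),
    start2 = as.integer(vapply(s, function(x) x[2], "")),
    end2 = as.integer(vapply(e, function(x) x[2], "")),
    error_offsets = lapply(strsplit(df$error_offsets, ",", fixed = TRUE),
                           function(x) as.integer(x[nzchar(x)])),
    gene_id = df$gene_id)
}

#' Simulate a complete fixture directory
#'
#' Convenience wrapper running [simulate_gene_models()], [simulate_reads()]
#' and [degrade_to_initial_mapping()] under one seed.
#'
#' @param out_dir Optional directory; when given, writes `reference.fa`,
#'   `reads.fastq`, `truth.tsv` and `initial.sam`.
#' @param seed Integer seed controlling every stochastic choice.
#' @param n_genes,n_reads,read_length,error_rate,error_model,p_drop,p_multimap,p_shift,p_misplace
#'   Passed through to the component simulators.
#' @param ... Further arguments for [simulate_gene_models()].
#' @return A list with `references`, `genes`, `reads`, `truth`, `initial`
#'   (the degraded record tibble) and the file paths when `out_dir` is set.
#' @export
simulate_dataset <- function(out_dir = NULL, n_genes = 20, n_reads = 20000,
                             read_length = 74L, error_rate = 0.01,
                             error_model = "uniform", seed = 1L,
                             p_drop = 0.05, p_multimap = 0.3, p_shift = 0.3,
                             p_misplace = 0.05, ...) {
  seed <- as.integer(seed)
  gm <- simulate_gene_models(n_genes = n_genes, seed = seed, ...)
  sim <- simulate_reads(gm$genes, gm$references, n_reads = n_reads,
                        read_length = read_length, error_rate = error_rate,
                        error_model = error_model, seed = seed + 1L)
  paths <- NULL
  sam_path <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    sam_path <- file.path(out_dir, "initial.sam")
  }
  initial <- degrade_to_initial_mapping(
    sim$truth, sim$reads, gm$references, gm$genes,
    p_drop = p_drop, p_multimap = p_multimap, p_shift = p_shift,
    p_misplace = p_misplace, seed = seed + 2L, path = sam_path)
  if (!is.null(out_dir)) {
    fa <- file.path(out_dir, "reference.fa")
    Biostrings::writeXStringSet(gm$references, fa)
    fq <- file.path(out_dir, "reads.fastq")
    write_reads_fastq(sim$reads, fq)
    tr <- file.path(out_dir, "truth.tsv")
    write_truth_tsv(sim$truth, tr)
    paths <- list(reference = fa, reads = fq, truth = tr, initial = sam_path)
  }
  list(references = gm$references, genes = gm$genes, reads = sim$reads,
       truth = sim$truth, initial = initial, paths = paths)
}
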