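test_that("seed length is 40% of the read, capped at 40 bp", {
  expect_equal(seed_length(74), 30L)    # ceil(29.6)
  expect_equal(seed_length(100), 40L)   # cap binds
  expect_equal(seed_length(10), 4L)
  expect_error(seed_length(4))
})

test_that("directional alignment finds exact and seed-tolerant hits", {
  withr::with_seed(41, {
    win <- rand_dna(2000)
    rd <- substr(win, 501, 574)                     # 74-mer at offset 500
    h <- align_directional(rd, win, "forward")
    fh <- h[h$strand == "+", ]
    expect_true(any(fh$q0 == 500 & fh$matched_len == 74 & fh$n_mm == 0))
    hb <- align_directional(rd, win, "backward")
    expect_true(any(hb$strand == "+" & hb$q0 == 500 & hb$matched_len == 74))

    # one substitution inside the seed is tolerated
    rd1 <- rd
    substr(rd1, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(rd, 3, 3))[1]
    h1 <- align_directional(rd1, win, "forward")
    expect_true(any(h1$strand == "+" & h1$q0 == 500 & h1$n_mm == 1))

    # two substitutions inside the seed exceed seed_mm = 1
    rd2 <- rd1
    substr(rd2, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                   substr(rd, 20, 20))[1]
    h2 <- align_directional(rd2, win, "forward", seed_mm = 1)
    expect_false(any(h2$strand == "+" & h2$q0 == 500))

    # reverse-complement placement is reported on the minus strand
    rdrc <- splicerefine:::revcomp(rd)
    hrc <- align_directional(rdrc, win, "forward")
    expect_true(any(hrc$strand == "-" & hrc$q0 == 500 & hrc$n_mm == 0))
  })
})

test_that("directional alignment equals the naive Hamming scan", {
  withr::with_seed(42, {
    for (rep in 1:25) {
      win <- rand_dna(sample(300:3000, 1))
      l <- sample(c(30L, 50L, 74L), 1)
      if (runif(1) < 0.7) {             # plant the read, with mutations
        p <- sample(nchar(win) - l, 1)
        rd <- substr(win, p, p + l - 1)
        nmut <- sample(0:3, 1)
        for (m in seq_len(nmut)) {
          i <- sample(l, 1)
          substr(rd, i, i) <- sample(c("A", "C", "G", "T"), 1)
        }
      } else rd <- rand_dna(l)
      for (dir in c("forward", "backward")) {
        got <- align_directional(rd, win, dir)
        got <- got[got$strand == "+", c("q0", "matched_len", "n_mm")]
        got <- got[order(got$q0), ]
        want <- bf_align(rd, win, dir, seed_length(l))
        want <- want[order(want$q0), ]
        expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
      }
    }
  })
})

test_that("forward and backward hits combine into full and split candidates", {
  hit <- function(read_id, dir, q0, matched, offs, l = 74L) {
    tibble::tibble(read_id = read_id, strand = "+", direction = dir,
                   q0 = as.integer(q0), matched_len = as.integer(matched),
                   n_mm = length(offs), mm_offsets = list(as.integer(offs)),
                   block_start = if (dir == "forward") as.integer(q0)
                                 else as.integer(q0 + l - matched),
                   block_end = if (dir == "forward") as.integer(q0 + matched)
                               else as.integer(q0 + l),
                   read_length = l)
  }
  # full-read forward hit gives a single full candidate
  full <- combine_alignments(hit("r", "forward", 100, 74, integer(0)),
                             empty_bwd <- hit("x", "backward", 1, 74,
                                              integer(0))[0, ])
  expect_equal(nrow(full), 1L)
  expect_true(is.na(full$start2))
  expect_equal(c(full$start1, full$end1, full$mismatches), c(100, 174, 0))

  # forward matched 40 at 100, backward matched 44 ending at 1000:
  # junction point slides across the 10-position overlap [30, 40]
  fh <- hit("r", "forward", 100, 40, c(35L))      # mismatch at read offset 35
  bh <- hit("r", "backward", 926, 44, integer(0)) # covers [30, 74) to 1000
  got <- combine_alignments(fh, bh, max_mm = 4, min_intron = 20,
                            max_intron = 5000)
  got <- got[!is.na(got$start2), ]
  # brute force: enumerate every junction placement and filter by mismatches
  want <- do.call(rbind, lapply(30:73, function(k) {
    if (k > 40) return(NULL)
    mm <- sum(35 < k) + 0
    if (mm > 4) return(NULL)
    gap <- 926 - 100
    data.frame(start1 = 100, end1 = 100 + k, start2 = 100 + k + gap,
               end2 = 100 + gap + 74, mismatches = mm)
  }))
  expect_equal(nrow(got), nrow(want))
  expect_equal(got$start1, want$start1)
  expect_equal(got$end1, want$end1)
  expect_equal(got$start2, want$start2)
  expect_equal(got$mismatches, want$mismatches)
  # every placement keeps the block lengths summing to the read length
  expect_true(all((got$end1 - got$start1) + (got$end2 - got$start2) == 74))

  # exceeding the maximum mismatch criterion rejects the combination
  fh5 <- hit("r", "forward", 100, 40, c(1L, 5L, 9L, 13L, 35L))
  got5 <- combine_alignments(fh5, bh, max_mm = 4, min_intron = 20,
                             max_intron = 5000)
  expect_false(any(got5$end1 - got5$start1 > 35 & !is.na(got5$start2)))

  # intron bounds gate the pairing
  none <- combine_alignments(fh, bh, max_mm = 4, min_intron = 20,
                             max_intron = 500)
  expect_equal(nrow(none[!is.na(none$start2), ]), 0L)
})

test_that("candidate mismatch counts agree with an independent recount", {
  fx <- small_fixture()
  ref <- as.character(fx$sim$references[[1]])
  cand <- fx$res$candidates
  bases_of <- stats::setNames(fx$sim$reads$bases, fx$sim$reads$read_id)
  withr::with_seed(43, idx <- sample(nrow(cand), 300))
  for (i in idx) {
    seqf <- bases_of[[cand$read_id[i]]]
    if (cand$strand[i] == "-") seqf <- splicerefine:::revcomp(seqf)
    g <- substr(ref, cand$start1[i] + 1, cand$end1[i])
    if (!is.na(cand$start2[i])) {
      g <- paste0(g, substr(ref, cand$start2[i] + 1, cand$end2[i]))
    }
    expect_equal(sum(utf8ToInt(g) != utf8ToInt(seqf)), cand$mismatches[i])
  }
})

test_that("splice sites aggregate supporters with mismatch tallies", {
  expect_equal(nrow(collect_splice_sites(make_aln("r", 0, 74))), 0L)

  cand <- dplyr::bind_rows(
    make_aln("a", 100, 130, 500, 544, mismatches = 0),
    make_aln("b", 90, 130, 500, 534, mismatches = 1),
    make_aln("c", 95, 169, mismatches = 0))          # full, ends at s1 = 168
  sites <- collect_splice_sites(cand)
  expect_equal(nrow(sites), 1L)
  expect_equal(c(sites$s1, sites$s2), c(129L, 500L))
  expect_equal(sites$tallies[[1]], c(1L, 1L, 0L, 0L, 0L))
  expect_equal(sites$n_support, 2L)

  # a full alignment ending exactly at the donor supports the site
  cand2 <- dplyr::bind_rows(cand[1:2, ], make_aln("c", 56, 130,
                                                  mismatches = 0))
  expect_equal(collect_splice_sites(cand2)$tallies[[1]], c(2L, 1L, 0L, 0L, 0L))
})

test_that("splice-signal detection reads the intron boundary motifs", {
  withr::with_seed(45, {
    win <- paste0(rand_dna(30), "GT", rand_dna(56), "AG", rand_dna(60))
    # intron occupies [30, 90): s1 = 29 (last exonic base), s2 = 90
    cand <- make_aln("a", 10, 30, 90, 144, mismatches = 0)
    sites <- collect_splice_sites(cand, window = win, window_offset = 0L)
    expect_true(sites$signal)
    # minus-strand transcription: CT..AC genome-forward is the same signal
    win2 <- paste0(rand_dna(30), "CT", rand_dna(56), "AC", rand_dna(60))
    expect_true(collect_splice_sites(cand, window = win2,
                                     window_offset = 0L)$signal)
    # an AA..TT intron matches no configured motif
    win3 <- paste0(rand_dna(30), "AA", rand_dna(56), "TT", rand_dna(60))
    expect_false(collect_splice_sites(cand, window = win3,
                                      window_offset = 0L)$signal)
  })
})

test_that("splice extension adds the true split for reads mapped across s1", {
  withr::with_seed(44, {
    exon1 <- rand_dna(300); intron <- paste0("GT", rand_dna(200), "AG")
    exon2 <- rand_dna(300)
    win <- paste0(exon1, intron, exon2)
    # true junction: s1 = 299, s2 = 504
    rd <- paste0(substr(exon1, 261, 300), substr(exon2, 1, 34))  # 40 + 34
    # the read was initially forced into an ungapped placement over s1
    wrong <- make_aln("j", 260, 334, mismatches = 30, provenance = "initial")
    site <- tibble::tibble(s1 = 299L, s2 = 504L, signal = TRUE,
                           tallies = list(c(3L, 0L, 0L, 0L, 0L)),
                           n_support = 3L)
    queries <- tibble::tibble(read_id = "j", strand = "+", query = rd)
    out <- splice_extend(wrong, site, win, window_offset = 0L,
                         queries = queries, max_mm = 4)
    new <- out[out$provenance == "splice_extended", ]
    expect_equal(nrow(new), 1L)
    expect_equal(c(new$start1, new$end1, new$start2, new$end2),
                 c(260, 300, 504, 538))
    expect_equal(new$mismatches, 0L)
    # extension never removes candidates
    expect_true(all(paste(wrong$start1, wrong$end1) %in%
                      paste(out$start1, out$end1)))

    # no read crossing any site: nothing added
    far <- make_aln("k", 600, 674, mismatches = 0)
    out2 <- splice_extend(far, site, win, window_offset = 0L,
                          queries = tibble::tibble(
                            read_id = "k", strand = "+",
                            query = substr(win, 601, 674)), max_mm = 4)
    expect_equal(nrow(out2), 1L)

    # an extension needing more than max_mm mismatches is not added
    rd_bad <- paste0(substr(exon1, 261, 300), rand_dna(34))
    out3 <- splice_extend(wrong, site, win, window_offset = 0L,
                          queries = tibble::tibble(read_id = "j",
                                                   strand = "+",
                                                   query = rd_bad),
                          max_mm = 4)
    expect_equal(nrow(out3[out3$provenance == "splice_extended", ]), 0L)
  })
})
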