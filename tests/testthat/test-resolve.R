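cand_ctx <- function(...) {
  dplyr::bind_rows(...)
}

test_that("the mismatch-delta filter drops badly matching contexts only", {
  one <- dplyr::mutate(make_aln("r", 0, 74, mismatches = 3),
                       context_id = "A")
  expect_equal(filter_by_mismatch_delta(one, 2), one)

  two <- dplyr::bind_rows(
    dplyr::mutate(make_aln("r", 0, 74, mismatches = 0), context_id = "A"),
    dplyr::mutate(make_aln("r", 50000, 50074, mismatches = 3),
                  context_id = "B"))
  expect_equal(filter_by_mismatch_delta(two, 2)$context_id, "A")

  # boundary is inclusive: 3 <= 1 + 2 keeps both
  two$mismatches <- c(1L, 3L)
  expect_equal(filter_by_mismatch_delta(two, 2)$context_id, c("A", "B"))
})

test_that("candidates sharing a start or end merge into one group", {
  cand <- dplyr::bind_rows(
    make_aln("r", 100, 174),                    # full
    make_aln("r", 100, 130, 5000, 5044),        # split, same start
    make_aln("r", 300, 374))                    # unrelated
  g <- merge_same_endpoint(cand)
  expect_equal(g$group_id[1], g$group_id[2])
  expect_false(g$group_id[3] == g$group_id[1])

  single <- merge_same_endpoint(make_aln("r", 0, 74))
  expect_equal(single$group_id, 1L)

  # chains connect through either endpoint
  chain <- dplyr::bind_rows(
    make_aln("r", 100, 174),
    make_aln("r", 100, 150, 300, 324),          # shares start with 1
    make_aln("r", 250, 290, 300, 334))          # shares end block... no:
  # rows 2 and 3 share the outermost end only if equal; make them equal
  chain$end2[3] <- 324L
  g2 <- merge_same_endpoint(chain)
  expect_equal(length(unique(g2$group_id)), 1L)
})

test_that("evidence scores weight supporters by mismatches and signal", {
  sites <- tibble::tibble(
    s1 = c(100L, 140L), s2 = c(600L, 640L), signal = c(TRUE, FALSE),
    tallies = list(c(4L, 0L, 0L, 0L, 0L), c(2L, 0L, 0L, 0L, 0L)),
    n_support = c(4L, 2L))
  expect_equal(evidence_score(sites), c(8, 2))
  expect_equal(evidence_score(sites[2, ][0, ]), numeric(0))

  mixed <- tibble::tibble(s1 = 1L, s2 = 50L, signal = FALSE,
                          tallies = list(c(1L, 1L, 1L, 0L, 0L)),
                          n_support = 3L)
  expect_equal(evidence_score(mixed), 1 + 0.3 + 0.09)

  zero <- tibble::tibble(s1 = 1L, s2 = 50L, signal = TRUE,
                         tallies = list(integer(5)), n_support = 0L)
  expect_equal(evidence_score(zero), 0)
})

test_that("evidence matches a brute-force recount on random tallies", {
  withr::with_seed(51, {
    for (rep in 1:50) {
      mm <- sample(0:4, sample(1:20, 1), replace = TRUE)
      signal <- runif(1) < 0.5
      sites <- tibble::tibble(s1 = 1L, s2 = 500L, signal = signal,
                              tallies = list(tabulate(mm + 1L, 5)),
                              n_support = length(mm))
      expect_equal(evidence_score(sites),
                   bf_evidence(data.frame(mm = mm), signal),
                   tolerance = 1e-12)
    }
  })
})

test_that("overlapping splice sites keep only the best-supported one", {
  sites <- tibble::tibble(
    s1 = c(100L, 110L), s2 = c(600L, 610L), signal = c(TRUE, FALSE),
    tallies = list(c(4L, 0L, 0L, 0L, 0L), c(2L, 0L, 0L, 0L, 0L)),
    n_support = c(4L, 2L))
  pr <- prune_overlapping_splice_sites(sites, read_length = 74)
  expect_equal(pr$retained$s1, 100L)
  expect_equal(pr$dropped$s1, 110L)

  # far-apart sites are not overlapping
  sites$s1[2] <- 300L; sites$s2[2] <- 800L
  pr2 <- prune_overlapping_splice_sites(sites, read_length = 74)
  expect_equal(nrow(pr2$retained), 2L)

  # evidence tie breaks to the smaller (s1, s2)
  tie <- tibble::tibble(
    s1 = c(110L, 100L), s2 = c(610L, 600L), signal = c(FALSE, FALSE),
    tallies = list(c(2L, 0L, 0L, 0L, 0L), c(2L, 0L, 0L, 0L, 0L)),
    n_support = c(2L, 2L))
  expect_equal(prune_overlapping_splice_sites(tie, 74)$retained$s1, 100L)
})

test_that("coverage profiles count each read once per position", {
  # one read with two overlapping candidates, one unambiguous read
  cand <- dplyr::bind_rows(
    make_aln("a", 10, 20), make_aln("a", 15, 25), make_aln("b", 18, 22))
  prof <- coverage_profile(cand, 0L, 40L)
  expect_equal(prof$cov[11], 1L)   # position 10: a only, counted once
  expect_equal(prof$cov[19], 2L)   # position 18: union(a) + b
  expect_equal(prof$cov[26], 0L)
  # split candidates leave the intron uncovered
  prof2 <- coverage_profile(make_aln("s", 5, 10, 30, 35), 0L, 40L)
  expect_equal(sum(prof2$cov), 10L)
  expect_equal(prof2$cov[15], 0L)
})

test_that("coverage scores follow the region-weighted log rule", {
  # flat c_m = 1 everywhere: every region max is 1, score 0
  prof1 <- make_profile(rep(1L, 3000))
  a <- make_aln("r", 1000, 1074)
  expect_equal(coverage_score(a, prof1), 0)

  # region maxima (10, 5, 2, 1)
  cov <- integer(3000)
  cov[1001:1074] <- 10L; cov[1101:1200] <- 5L
  cov[1301:1400] <- 2L; cov[1601:1700] <- 1L
  prof <- make_profile(cov)
  expect_equal(coverage_score(a, prof),
               8 * log(10) + 4 * log(5) + 2 * log(2), tolerance = 1e-12)

  # doubling only the region-4 maximum adds exactly ln 2
  cov2 <- cov; cov2[1601:1700] <- 2L
  expect_equal(coverage_score(a, make_profile(cov2)) -
                 coverage_score(a, prof), log(2), tolerance = 1e-12)

  # the intron interior of a split alignment contributes nothing
  covs <- integer(3000); covs[1501:1600] <- 50L
  split_a <- make_aln("r", 1000, 1030, 1950, 1994)
  full_a <- make_aln("r", 1000, 1994)   # hypothetical ungapped span
  expect_equal(coverage_score(split_a, make_profile(covs)), 0)
  expect_gt(coverage_score(full_a, make_profile(covs)), 0)
})

test_that("coverage scores equal the naive per-position oracle", {
  withr::with_seed(52, {
    for (rep in 1:60) {
      n <- 2500L
      cov <- as.integer(rpois(n, sample(c(0.5, 3, 20), 1)))
      start <- sample(c(0L, 700L), 1)
      prof <- make_profile(cov, start)
      s1 <- start + sample(1100:1200, 1)
      if (runif(1) < 0.5) {
        a <- make_aln("r", s1, s1 + 74)
      } else {
        a <- make_aln("r", s1, s1 + 30, s1 + 30 + sample(50:400, 1), NA)
        a$end2 <- a$start2 + 44L
      }
      expect_equal(coverage_score(a, prof),
                   bf_coverage_score(a, cov, start), tolerance = 1e-9)
    }
  })
})

test_that("static resolution picks the highest-coverage option per read", {
  cov <- integer(5000)
  cov[101:300] <- 30L          # well-covered region
  cov[3101:3150] <- 2L         # sparse region
  prof <- make_profile(cov)
  cand <- merge_same_endpoint(dplyr::bind_rows(
    make_aln("amb", 150, 224),
    make_aln("amb", 3100, 3174),
    make_aln("solo", 200, 274)))
  got <- resolve_within_context(cand, prof)
  expect_equal(nrow(got), 2L)
  amb <- got[got$read_id == "amb", ]
  expect_equal(cand$start1[cand$group_id == amb$group_id &
                             cand$read_id == "amb"], 150L)
  expect_true(is.finite(amb$margin) && amb$margin > 0)
  expect_equal(got$margin[got$read_id == "solo"], Inf)
})

test_that("static resolution is invariant to candidate row order", {
  withr::with_seed(53, {
    cov <- as.integer(rpois(4000, 4))
    prof <- make_profile(cov)
    cand <- dplyr::bind_rows(lapply(1:15, function(i) {
      k <- sample(1:3, 1)
      s <- sample(seq(100L, 3600L, by = 40L), k)
      dplyr::bind_rows(lapply(s, function(x)
        make_aln(sprintf("r%02d", i), x, x + 74,
                 mismatches = sample(0:2, 1))))
    }))
    pick <- function(x) {
      g <- merge_same_endpoint(x)
      a <- resolve_within_context(g, prof)
      chosen <- dplyr::inner_join(g, a[c("read_id", "group_id")],
                                  by = c("read_id", "group_id"))
      chosen <- chosen[order(chosen$read_id, chosen$start1), ]
      chosen[c("read_id", "start1", "end1")]
    }
    base <- pick(cand)
    for (rep in 1:5) {
      expect_equal(pick(cand[sample(nrow(cand)), ]), base)
    }
  })
})

test_that("dynamic resolution reproduces the iterate-and-update loop", {
  withr::with_seed(54, {
    cov_len <- 3000L
    cand <- dplyr::bind_rows(lapply(1:20, function(i) {
      k <- sample(1:2, 1)
      s <- sample(seq(50L, 2800L, by = 15L), k)
      dplyr::bind_rows(lapply(s, function(x)
        make_aln(sprintf("r%02d", i), x, x + 74, mismatches = 0)))
    }))
    cand <- merge_same_endpoint(cand)
    prof0 <- coverage_profile(cand, 0L, cov_len)
    got <- resolve_within_context(cand, prof0, mode = "dynamic")

    # independent re-simulation of the loop with naive scoring
    live <- cand
    fixed <- list()
    while (length(fixed) < 20) {
      cv <- integer(cov_len)
      for (rid in unique(live$read_id)) {
        pos <- unique(unlist(lapply(which(live$read_id == rid), function(z)
          live$start1[z]:(live$end1[z] - 1L))))
        cv[pos + 1L] <- cv[pos + 1L] + 1L
      }
      best <- NULL
      for (rid in setdiff(sort(unique(live$read_id)), names(fixed))) {
        rows <- which(live$read_id == rid)
        sc <- vapply(rows, function(z)
          bf_coverage_score(live[z, ], cv, 0L), 0)
        gs <- tapply(sc, live$group_id[rows], max)
        mm <- tapply(live$mismatches[rows], live$group_id[rows], min)
        st <- tapply(live$start1[rows], live$group_id[rows], min)
        # documented tie-break: mismatches, then leftmost start, then group
        o <- order(-gs, mm, st, as.integer(names(gs)))
        margin <- if (length(gs) > 1) gs[o[1]] - gs[o[2]] else Inf
        if (is.null(best) || margin > best$margin) {
          best <- list(rid = rid, margin = margin,
                       group = as.integer(names(gs)[o[1]]))
        }
      }
      fixed[[best$rid]] <- best$group
      live <- live[!(live$read_id == best$rid &
                       live$group_id != best$group), ]
    }
    for (rid in names(fixed)) {
      expect_equal(got$group_id[got$read_id == rid], fixed[[rid]],
                   label = rid)
    }
  })
})

test_that("merged endpoint groups resolve by distinguishing coverage", {
  # full and split sharing a start: the split's distal block sits in a
  # 50-read exon, the full's tail crosses an unexpressed intron
  cov <- integer(8000)
  cov[1001:1100] <- 40L              # exon 1
  cov[5001:5100] <- 50L              # exon 2
  prof <- make_profile(cov)
  members <- merge_same_endpoint(dplyr::bind_rows(
    make_aln("r", 1050, 1124, mismatches = 2),
    make_aln("r", 1050, 1080, 5000, 5044, mismatches = 0)))
  expect_equal(length(unique(members$group_id)), 1L)
  win <- resolve_merged_endpoint_groups(members, prof)
  expect_false(is.na(win$start2))

  # identical distinguishing coverage: fewer mismatches wins
  flat <- make_profile(rep(3L, 8000))
  members$mismatches <- c(1L, 2L)
  win2 <- resolve_merged_endpoint_groups(members, flat)
  expect_equal(win2$mismatches, 1L)
  # singleton groups pass through
  expect_equal(resolve_merged_endpoint_groups(members[1, ], prof),
               members[1, ])
})

test_that("between-context resolution keeps the best-covered context", {
  w <- dplyr::bind_rows(
    dplyr::mutate(make_aln("r", 100, 174), context_id = "A", score = 26.2),
    dplyr::mutate(make_aln("r", 90100, 90174), context_id = "B",
                  score = 3.1),
    dplyr::mutate(make_aln("solo", 500, 574), context_id = "A",
                  score = 1))
  got <- resolve_between_contexts(w)
  expect_equal(nrow(got), 2L)
  expect_equal(got$context_id[got$read_id == "r"], "A")
  expect_equal(got$context_id[got$read_id == "solo"], "A")

  # equal scores: deterministic (reference, start) order
  w$score[2] <- 26.2
  expect_equal(resolve_between_contexts(w)$start1[1], 100L)
})

test_that("the expression filter requires min_support close neighbours", {
  stack <- dplyr::bind_rows(lapply(1:101, function(i)
    make_aln(sprintf("s%03d", i), 1000 + i, 1074 + i)))
  lone <- make_aln("lone", 500000, 500074)
  final <- dplyr::bind_rows(stack, lone)

  flt <- expression_filter(final, min_support = 100, window = 1000)
  expect_setequal(flt$emitted$read_id, stack$read_id)  # exactly 100 others
  expect_equal(flt$filtered$read_id, "lone")
  expect_equal(flt$filtered$reason, "low_expression")

  expect_equal(nrow(expression_filter(final, min_support = 0)$emitted),
               nrow(final))
  # monotone: raising the threshold never emits more reads
  counts <- vapply(c(0, 50, 100, 101, 200), function(ms)
    nrow(expression_filter(final, min_support = ms)$emitted), 0)
  expect_true(all(diff(counts) <= 0))
})
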