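test_that("stretch detection finds maximal runs and bridges single gaps", {
  lab <- worked_example_labels()
  st <- find_stretches(lab)
  expect_equal(nrow(st), 7L)
  expect_equal(st$first_window, c(4L, 31L, 70L, 89L, 117L, 132L, 156L))
  expect_equal(st$last_window, c(11L, 53L, 80L, 96L, 124L, 140L, 162L))

  # an isolated ntm inside the long run is bridged, still 7 stretches
  lab2 <- lab; lab2[40] <- "ntm"
  st2 <- find_stretches(lab2)
  expect_equal(nrow(st2), 7L)
  expect_equal(st2$first_window[2], 31L)
  expect_equal(st2$last_window[2], 53L)
  expect_equal(st2$bridged[2], "40")

  expect_equal(nrow(find_stretches(rep("ntm", 50))), 0L)
  expect_equal(nrow(find_stretches(character(0))), 0L)

  # runs of 3 separated by a 2-window gap: nothing reported
  lab3 <- rep("ntm", 20); lab3[c(3:5, 8:10)] <- "tm"
  expect_equal(nrow(find_stretches(lab3)), 0L)

  # two runs of 3 with a single gap merge only when total >= 7: 3+3 = 6 stays out
  lab4 <- rep("ntm", 20); lab4[c(3:5, 7:9)] <- "tm"
  expect_equal(nrow(find_stretches(lab4)), 0L)
  # 4+3 = 7 merges
  lab5 <- rep("ntm", 20); lab5[c(3:6, 8:10)] <- "tm"
  st5 <- find_stretches(lab5)
  expect_equal(nrow(st5), 1L)
  expect_equal(c(st5$first_window, st5$last_window), c(3L, 10L))

  # two or more consecutive ntm windows always terminate a run
  lab6 <- rep("ntm", 30); lab6[c(3:10, 13:20)] <- "tm"
  expect_equal(nrow(find_stretches(lab6)), 2L)
})

test_that("stretch spans follow the window arithmetic", {
  expect_equal(unname(stretch_span(117, 124)), c(117L, 133L))
  expect_equal(unname(stretch_span(1, 1)), c(1L, 10L))
  # a minimal 4-window run spans exactly w + 3 residues
  set.seed(2)
  for (k in sample(1:200, 25)) {
    sp <- stretch_span(k, k + 3L)
    expect_equal(sp[["span_end"]] - sp[["span_start"]] + 1L, 13L)
  }
})

test_that("hairpin splitting divides long spans into near-equal pieces", {
  expect_equal(nrow(split_stretch(117, 133)), 1L)      # length 17: unsplit
  two <- split_stretch(31, 62)                          # length 32: two pieces
  expect_equal(nrow(two), 2L)
  expect_equal(two$start, c(31L, 47L))
  expect_equal(two$end, c(46L, 62L))
  three <- split_stretch(1, 40)                         # length 40: 14+13+13
  expect_equal(three$end - three$start + 1L, c(14L, 13L, 13L))
  # pieces partition the span contiguously
  expect_equal(three$start[-1], three$end[-3] + 1L)
  expect_equal(nrow(split_stretch(1, 20)), 1L)   # single-strand reachable span
  expect_equal(nrow(split_stretch(1, 21)), 2L)   # two full windows fit
  # a fused minimal hairpin (two 6-residue strands, 3-residue turn) splits
  two_min <- split_stretch(1, 24)
  expect_equal(nrow(two_min), 2L)
  expect_equal(two_min$end - two_min$start + 1L, c(12L, 12L))
})

test_that("sub-segment enumeration matches the printed count and the oracle", {
  e <- enumerate_subsegments(117:124)
  expect_equal(nrow(e), 43L)
  expect_true(all(e$length >= 6 & e$length <= 12))
  expect_equal(e[c("start", "end")],
               oracle_enumerate(117:124)[c("start", "end")],
               ignore_attr = TRUE)

  e4 <- enumerate_subsegments(1:4)
  expect_equal(nrow(e4), 15L)

  e1 <- enumerate_subsegments(5L, len_min = 10, len_max = 10)
  expect_equal(nrow(e1), 1L)
  expect_equal(c(e1$start, e1$end), c(5L, 14L))

  expect_equal(nrow(enumerate_subsegments(integer(0))), 0L)
  # no pair satisfies an impossible filter
  expect_equal(nrow(enumerate_subsegments(1:2, len_min = 20, len_max = 25)), 0L)
})

test_that("enumeration equals brute force on 500 random stretches", {
  set.seed(44)
  for (i in 1:500) {
    k <- sample(1:10, 1)
    first <- sample(1:300, 1)
    wins <- first:(first + k - 1L)
    got <- enumerate_subsegments(wins)
    want <- oracle_enumerate(wins)
    expect_equal(got[c("start", "end")], want[c("start", "end")],
                 ignore_attr = TRUE)
  }
})

test_that("clipping to a sub-region restricts and trims candidates", {
  # windows 31..53, sub-region 31..46
  e <- enumerate_subsegments(31:53, region = c(31, 46))
  expect_true(all(e$start >= 31 & e$end <= 46))
  # all candidate termini either window termini or the region edge
  expect_true(all(e$start %in% c(31:46)))
  full <- enumerate_subsegments(31:53)
  expect_gt(nrow(full), nrow(e))
})

test_that("scoring ranks by score with midpoint and start tie-breaks", {
  seqs <- strrep("A", 200)
  cand <- enumerate_subsegments(117:124)
  zero <- flat_table(0)
  sc <- score_subsegments(cand, seqs, zero, span = c(117, 133))
  expect_true(all(sc$score == 0))
  # all tied: first candidate must be the one closest to the span midpoint
  mids <- (sc$start + sc$end) / 2
  expect_equal(abs(mids[1] - 125), min(abs(mids - 125)))

  # a Y-start bonus dominates
  tab <- flat_table(0)
  tab$score_N[tab$amino_acid == "Y"] <- 2
  seqy <- paste0(strrep("A", 119), "Y", strrep("A", 80))   # residue 120 is Y
  sc2 <- score_subsegments(cand, seqy, tab, span = c(117, 133))
  expect_equal(sc2$start[1], 120L)
  expect_equal(sc2$score[1], 2)

  # ranking equals a brute-force sort on random tables
  set.seed(55)
  for (i in 1:100) {
    rt <- preference_table(
      structure(round(runif(20, -2, 2), 2), names = AA_ALPHABET20),
      structure(round(runif(20, -2, 2), 2), names = AA_ALPHABET20))
    rs <- random_sequence(200)
    sc3 <- score_subsegments(cand, rs, rt, span = c(117, 133))
    chars <- strsplit(rs, "")[[1]]
    want <- preference_score(rt, chars[cand$start], "N") +
      preference_score(rt, chars[cand$end], "C")
    ord <- order(-want, abs((cand$start + cand$end) / 2 - 125), cand$start)
    expect_equal(sc3$score, want[ord])
    expect_equal(sc3$start, cand$start[ord])
    expect_equal(sc3$end, cand$end[ord])
  }
})

test_that("selection takes the most central of the top three positive scorers", {
  ranked <- data.frame(start = c(10, 20, 24, 30), end = c(17, 27, 31, 37),
                       length = 8, score = c(3, 2.5, 2, 1.5))
  # span centred at 26: candidate 24..31 (mid 27.5) beats 20..27 (mid 23.5)?
  pick <- select_tm(ranked, span = c(16, 36))
  mids <- abs((ranked$start[1:3] + ranked$end[1:3]) / 2 - 26)
  expect_equal(pick$start, ranked$start[1:3][which.min(mids)])

  single <- data.frame(start = 5, end = 12, length = 8, score = 0.2)
  expect_equal(select_tm(single, c(1, 20))$start, 5)

  none <- data.frame(start = 5, end = 12, length = 8, score = -1)
  expect_null(select_tm(none, c(1, 20)))
  expect_null(select_tm(none[0, ], c(1, 20)))

  # the fourth-ranked candidate is never selected even if most central
  ranked2 <- data.frame(start = c(1, 2, 3, 22), end = c(8, 9, 10, 29),
                        length = 8, score = c(4, 3, 2, 1))
  pick2 <- select_tm(ranked2, span = c(1, 50))   # span mid 25.5, near 4th
  expect_true(pick2$start %in% 1:3)
})

test_that("the worked-example stretch resolves to residues 122-129 with a constructed table", {
  # sequence: residue 122 = W, residue 129 = Y, all else A
  chars <- rep("A", 171); chars[122] <- "W"; chars[129] <- "Y"
  seqs <- paste(chars, collapse = "")
  tab <- flat_table(-3)
  tab$score_N[tab$amino_acid == "W"] <- 2
  tab$score_C[tab$amino_acid == "Y"] <- 2
  cand <- enumerate_subsegments(117:124)
  ranked <- score_subsegments(cand, seqs, tab, span = c(117, 133))
  pick <- select_tm(ranked, span = c(117, 133))
  expect_equal(c(pick$start, pick$end), c(122L, 129L))
  # its midpoint (125.5) is the closest-to-centre positive scorer
  expect_equal(pick$score, 4)
})

test_that("the full second layer reproduces the worked example's region count", {
  set.seed(60)
  seqs <- protein_seq("wx", random_sequence(171))
  lab <- worked_example_labels()
  tab <- flat_table(1)          # every candidate positive
  pred <- predict_protein(seqs, table = tab, labels = lab)
  # one region per stretch, two for the 31..62 hairpin
  expect_equal(nrow(pred), 8L)
  expect_equal(sum(pred$stretch == 2), 2L)
  expect_true(all(pred$length >= 6 & pred$length <= 12))
  # every region lies inside its stretch span
  spans <- list(c(4, 20), c(31, 62), c(70, 89), c(89, 105), c(117, 133),
                c(132, 149), c(156, 171))
  for (i in seq_len(nrow(pred))) {
    sp <- spans[[pred$stretch[i]]]
    expect_gte(pred$start[i], sp[1])
    expect_lte(pred$end[i], sp[2])
  }
  # deterministic
  expect_identical(pred, predict_protein(seqs, table = tab, labels = lab))
})

test_that("degenerate predictor inputs are handled", {
  tab <- flat_table(1)
  expect_equal(nrow(predict_protein(protein_seq("z", random_sequence(50, 1)),
                                    table = tab,
                                    labels = rep("ntm", 41))), 0L)
  expect_warning(
    out <- predict_protein(protein_seq("short", random_sequence(5, 2)),
                           table = tab),
    "shorter")
  expect_equal(nrow(out), 0L)
  # all scores negative: stretch suppressed, no prediction
  expect_message(
    none <- predict_protein(protein_seq("neg", random_sequence(60, 3)),
                            table = flat_table(-1),
                            labels = c(rep("tm", 10), rep("ntm", 41))),
    "suppressed")
  expect_equal(nrow(none), 0L)
})

test_that("reported regions are sorted, within bounds and non-overlapping", {
  corpus <- small_corpus(n = 6L, seed = 91L)
  tab <- estimate_preference_table(corpus)
  for (p in corpus) {
    win <- segment_protein(p$seq)
    # plant labels from the ground truth: windows mostly inside strands
    lab <- ifelse(vapply(seq_len(nrow(win)), function(i) {
      any(pmin(win$end[i], p$tm_regions$end) -
            pmax(win$start[i], p$tm_regions$start) + 1 >= 6)
    }, logical(1)), "tm", "ntm")
    pred <- suppressMessages(predict_protein(p$seq, table = tab, labels = lab))
    if (nrow(pred) < 2) next
    expect_true(all(diff(pred$start) > 0))
    expect_true(all(pred$start[-1] > pred$end[-nrow(pred)]))
    expect_true(all(pred$length >= 6 & pred$length <= 12))
    expect_true(all(pred$start >= 1 & pred$end <= p$seq$n))
  }
})
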