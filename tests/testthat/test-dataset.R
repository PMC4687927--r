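test_that("labeled segment extraction follows the chunking rule", {
  # one 10-residue TM range and nothing else
  p <- annotated_protein(protein_seq("solo", random_sequence(10, seed = 1)),
                         data.frame(start = 1, end = 10))
  seg <- extract_labeled_segments(p)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$label, "tm")

  # 25-residue loop chunks to 10 + 15 (trailing 5 merged back)
  expect_equal(barreltm:::.chunk_lengths(25), c(10L, 15L))
  expect_equal(barreltm:::.chunk_lengths(20), c(10L, 10L))
  expect_equal(barreltm:::.chunk_lengths(16), c(10L, 6L))
  expect_equal(barreltm:::.chunk_lengths(12), 12L)
  expect_equal(barreltm:::.chunk_lengths(8), 8L)
  expect_equal(barreltm:::.chunk_lengths(5), integer(0))

  # 171-residue protein, 8 TM ranges of 6..9 residues, loops between
  set.seed(4)
  starts <- c(10, 30, 50, 72, 95, 115, 135, 158)
  lens <- c(8, 9, 7, 6, 9, 8, 7, 6)
  ann <- data.frame(start = starts, end = starts + lens - 1)
  p8 <- annotated_protein(protein_seq("p8", random_sequence(171)), ann)
  seg8 <- extract_labeled_segments(p8)
  expect_equal(sum(seg8$label == "tm"), 8L)
  # tm segments coincide exactly with the annotation
  tmseg <- seg8[seg8$label == "tm", ]
  expect_equal(tmseg$start, ann$start)
  expect_equal(tmseg$end, ann$end)
  # ntm chunks cover only inter-range residues, lengths in 6..15
  ntm <- seg8[seg8$label == "ntm", ]
  expect_true(all(ntm$end - ntm$start + 1 >= 6))
  expect_true(all(ntm$end - ntm$start + 1 <= 15))
  for (i in seq_len(nrow(ntm))) {
    expect_false(any(ntm$start[i] <= ann$end & ntm$end[i] >= ann$start))
  }

  # invalid annotations are rejected
  expect_error(annotated_protein(protein_seq("x", random_sequence(50)),
                                 data.frame(start = c(5, 10), end = c(12, 20))),
               "overlapping")
  expect_error(annotated_protein(protein_seq("x", random_sequence(50)),
                                 data.frame(start = 45, end = 60)),
               "outside")
})

test_that("SOM split is a seed-reproducible partition covering every unit", {
  corpus <- small_corpus(n = 30L, seed = 19L)
  seg <- corpus_segments(corpus)
  expect_gt(nrow(seg), 400)

  split <- som_split(seg, val_fraction = 0.16, seed = 5)
  tr <- split$training; va <- split$validation

  # exact partition
  key <- function(d) paste(d$id, d$start, d$end)
  expect_setequal(c(key(tr), key(va)), key(seg))
  expect_length(intersect(key(tr), key(va)), 0)

  # every unit holding >= 2 samples is represented in both sets
  counts <- table(c(tr$neuron, va$neuron))
  multi <- as.integer(names(counts)[counts >= 2])
  expect_true(all(multi %in% tr$neuron))
  expect_true(all(multi %in% va$neuron))
  # singletons go to training
  single <- as.integer(names(counts)[counts == 1])
  expect_true(all(single %in% tr$neuron))

  # label-ratio balance
  ratio <- function(d) sum(d$label == "ntm") / sum(d$label == "tm")
  expect_lt(abs(ratio(tr) - ratio(seg)), 0.2)

  # determinism
  split2 <- som_split(seg, val_fraction = 0.16, seed = 5)
  expect_identical(split$training, split2$training)
  expect_identical(split$validation, split2$validation)

  # different seed gives a different partition
  split3 <- som_split(seg, val_fraction = 0.16, seed = 6)
  expect_false(identical(sort(key(split$validation)),
                         sort(key(split3$validation))))
})

test_that("SOM split hits the target validation fraction at corpus scale", {
  corpus <- generate_corpus(barrel_spec(), 180L, seed = 77L)
  seg <- corpus_segments(corpus)
  frac <- 588 / 3632
  split <- som_split(seg, val_fraction = frac, seed = 2)
  got <- nrow(split$validation) / nrow(seg)
  expect_lt(abs(got - frac), 0.02)
})

test_that("degenerate splits behave", {
  seg2 <- data.frame(id = "a", start = c(1, 11), end = c(10, 20),
                     sequence = c("ACDEFGHIKL", "ACDEFGHIKL"),
                     label = c("tm", "ntm"), stringsAsFactors = FALSE)
  sp <- som_split(seg2, som_shape = c(1, 2), seed = 1)
  expect_equal(nrow(sp$training), 1L)
  expect_equal(nrow(sp$validation), 1L)
  expect_error(som_split(seg2[1, , drop = FALSE]), "at least 2")
  expect_error(som_split(seg2, som_shape = c(1, 1)), "at least 2 units")
})
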