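# Shared fixtures and independent oracles, all built in code.

# Deterministic random sequence over the 20 standard residues.
random_sequence <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(AA_ALPHABET20, n, replace = TRUE), collapse = "")
}

# Naive double-loop pair counter: the oracle for adjacency_matrix.
oracle_pair_counts <- function(segment) {
  chars <- strsplit(segment, "", fixed = TRUE)[[1]]
  m <- matrix(0L, 20, 20, dimnames = list(AA_ALPHABET20, AA_ALPHABET20))
  for (i in seq_len(length(chars) - 1L)) {
    m[chars[i], chars[i + 1L]] <- m[chars[i], chars[i + 1L]] + 1L
  }
  m
}

# Brute-force sub-segment enumerator: loops over every (start window,
# end window) pair and applies the length filter.
oracle_enumerate <- function(tm_windows, w = 10L, len_min = 6L,
                             len_max = 12L) {
  out <- list()
  for (a in tm_windows) {
    for (b in tm_windows) {
      s <- a; e <- b + w - 1L
      len <- e - s + 1L
      if (len >= len_min && len <= len_max) {
        out[[length(out) + 1L]] <- c(s, e)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer()))
  }
  m <- unique(do.call(rbind, out))
  df <- data.frame(start = m[, 1], end = m[, 2])
  df[order(df$start, df$end), ]
}

# Independent region matcher following the exactly-one-overlap rule.
oracle_match <- function(predicted, observed) {
  np <- nrow(predicted); no <- nrow(observed)
  overlaps <- function(i, j) {
    min(predicted$end[i], observed$end[j]) -
      max(predicted$start[i], observed$start[j]) + 1L
  }
  n_hit <- integer(np)
  for (i in seq_len(np)) {
    for (j in seq_len(no)) if (overlaps(i, j) >= 1L) n_hit[i] <- n_hit[i] + 1L
  }
  TP <- 0L; consumed <- logical(no)
  for (j in seq_len(no)) {
    best <- -1L; best_ov <- 0L
    for (i in seq_len(np)) {
      if (n_hit[i] != 1L) next
      ov <- overlaps(i, j)
      if (ov >= 1L && (ov > best_ov ||
                       (ov == best_ov && best >= 1L &&
                        predicted$start[i] < predicted$start[best]))) {
        best <- i; best_ov <- ov
      }
    }
    if (best >= 1L) { TP <- TP + 1L; consumed[j] <- TRUE }
  }
  list(TP = TP, FP = np - TP, FN = sum(!consumed))
}

# Random non-overlapping region set on a sequence of length n.
random_regions <- function(n, max_regions = 8L, min_len = 2L, max_len = 14L) {
  pos <- 1L
  out <- list()
  while (pos < n - min_len && length(out) < max_regions) {
    gap <- sample(0:12, 1L)
    len <- sample(min_len:max_len, 1L)
    start <- pos + gap
    end <- start + len - 1L
    if (end > n) break
    out[[length(out) + 1L]] <- c(start, end)
    pos <- end + 2L
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

# Per-window label vector of the 162-window worked example: tm calls at
# seven runs, everything else ntm.
worked_example_labels <- function() {
  lab <- rep("ntm", 162)
  runs <- list(4:11, 31:53, 70:80, 89:96, 117:124, 132:140, 156:162)
  for (r in runs) lab[r] <- "tm"
  lab
}

# Small linearly separable descriptor set: strand-like alternating
# hydrophobic/polar 10-mers vs glycine/serine loop 10-mers.
toy_separable <- function(n_per_class = 30L, seed = 42L) {
  set.seed(seed)
  hydro <- c("V", "I", "L", "F")
  polar <- c("S", "T", "N", "Q")
  tm <- vapply(seq_len(n_per_class), function(i) {
    paste(as.vector(rbind(sample(hydro, 5, TRUE), sample(polar, 5, TRUE))),
          collapse = "")
  }, character(1))
  ntm <- vapply(seq_len(n_per_class), function(i) {
    paste(sample(c("G", "A", "D", "K"), 10, TRUE), collapse = "")
  }, character(1))
  list(x = descriptor_matrix(c(tm, ntm)),
       y = rep(c("tm", "ntm"), each = n_per_class),
       seq = c(tm, ntm))
}

# A flat preference table with every score equal to `value`.
flat_table <- function(value = 1) {
  v <- structure(rep(value, 20), names = AA_ALPHABET20)
  preference_table(v, v)
}

# Small annotated corpus for pipeline tests.
small_corpus <- function(n = 12L, seed = 7L, ...) {
  generate_corpus(barrel_spec(...), n, seed)
}
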