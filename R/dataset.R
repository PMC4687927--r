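#' An annotated beta-barrel protein
#'
#' Couples a sequence with its ground-truth transmembrane strand ranges.
#' Only the membrane-embedded residues of each strand belong to a range,
#' not the full beta-strand which may extend beyond the bilayer.
#'
#' @param seq A [protein_seq()].
#' @param tm_regions Data frame (or 2-column matrix) with `start`, `end`
#'   columns: 1-based inclusive, non-overlapping, each of length >= 2.
#' @return An `annotated_protein` object.
#' @export
annotated_protein <- function(seq, tm_regions) {
  stopifnot(inherits(seq, "protein_seq"))
  r <- as.data.frame(tm_regions)[, c("start", "end")]
  r$start <- as.integer(r$start); r$end <- as.integer(r$end)
  r <- r[order(r$start), , drop = FALSE]
  rownames(r) <- NULL
  if (nrow(r)) {
    if (any(r$start < 1L | r$end > seq$n)) {
      stop(sprintf("annotation outside sequence '%s' (1..%d)", seq$id, seq$n),
           call. = FALSE)
    }
    if (any(r$end - r$start + 1L < 2L)) {
      stop("annotated region of length < 2 in '", seq$id, "'", call. = FALSE)
    }
    if (nrow(r) > 1L && any(r$start[-1L] <= r$end[-nrow(r)])) {
      stop("overlapping annotations in '", seq$id, "'", call. = FALSE)
    }
  }
  structure(list(seq = seq, tm_regions = r), class = "annotated_protein")
}

#' @export
print.annotated_protein <- function(x, ...) {
  cat(sprintf("<annotated_protein> %s (%d aa, %d TM regions)\n",
              x$seq$id, x$seq$n, nrow(x$tm_regions)))
  invisible(x)
}

#' Extract labeled tm / ntm segments from an annotated protein
#'
#' Each annotated transmembrane range yields one `tm` segment covering
#' exactly the membrane-embedded residues. Every maximal region between
#' ranges (including the N- and C-terminal tails) is cut into consecutive
#' 10-residue chunks labeled `ntm`; a final remainder shorter than
#' `min_chunk` residues is merged into the preceding chunk, so ntm chunk
#' lengths stay within 6..15, comparable to transmembrane strand lengths.
#' A leftover region shorter than `min_chunk` with no preceding chunk is
#' discarded.
#'
#' @param protein An `annotated_protein`.
#' @param chunk Target ntm fragment length (default 10).
#' @param min_chunk Minimum stand-alone ntm fragment length (default 6).
#' @return Data frame: id, start, end, sequence, label ("tm"/"ntm"),
#'   ordered by start.
#' @export
extract_labeled_segments <- function(protein, chunk = 10L, min_chunk = 6L) {
  stopifnot(inherits(protein, "annotated_protein"))
  s <- protein$seq
  r <- protein$tm_regions
  seg <- list()
  add <- function(start, end, label) {
    seg[[length(seg) + 1L]] <<- data.frame(
      id = s$id, start = start, end = end,
      sequence = substring(s$residues, start, end),
      label = label, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(r))) add(r$start[i], r$end[i], "tm")
  # maximal non-TM intervals, tails included
  bounds <- c(0L, r$end, s$n + 1L)
  starts <- c(1L, r$end + 1L)
  ends <- c(r$start - 1L, s$n)
  for (i in seq_along(starts)) {
    a <- starts[i]; b <- ends[i]
    len <- b - a + 1L
    if (len < 1L) next
    cuts <- .chunk_lengths(len, chunk, min_chunk)
    if (!length(cuts)) next
    pos <- a
    for (cl in cuts) {
      add(pos, pos + cl - 1L, "ntm")
      pos <- pos + cl
    }
  }
  out <- do.call(rbind, seg)
  if (is.null(out)) {
    out <- data.frame(id = character(), start = integer(), end = integer(),
                      sequence = character(), label = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$start), ]
  rownames(out) <- NULL
  out
}

# Partition a region of `len` residues into chunks of `chunk`; a final
# remainder < min_chunk is merged into the preceding chunk (discarded if
# there is none).
.chunk_lengths <- function(len, chunk = 10L, min_chunk = 6L) {
  if (len < min_chunk) return(integer(0))
  k <- len %/% chunk
  rem <- len %% chunk
  lens <- rep(chunk, k)
  if (rem >= min_chunk) {
    lens <- c(lens, rem)
  } else if (rem > 0L) {
    if (k == 0L) return(integer(0))
    lens[k] <- lens[k] + rem
  }
  lens
}

#' Partition labeled segments into training and validation sets with a
#' self-organizing map
#'
#' Descriptors of all segments are mapped onto a Kohonen self-organizing
#' map; within every occupied map unit the samples are split so that both
#' output sets receive at least one sample from that unit (units holding a
#' single sample contribute it to training). This keeps the full
#' variability of the descriptor space represented on both sides, unlike a
#' plain random split.
#'
#' @param segments Data frame from [extract_labeled_segments()] (rows from
#'   several proteins may be concatenated).
#' @param som_shape Integer c(rows, cols) of the map; default sizes the map
#'   to roughly one unit per 10 samples.
#' @param val_fraction Target validation fraction (default 0.16).
#' @param seed Integer seed; the split is a pure function of
#'   (segments, som_shape, val_fraction, seed).
#' @return List with `training`, `validation` (data frames with an added
#'   `neuron` column), `som_shape`, `seed`.
#' @export
som_split <- function(segments, som_shape = NULL, val_fraction = 0.16,
                      seed = 1L) {
  n <- nrow(segments)
  if (is.null(n) || n < 2L) stop("need at least 2 segments to split", call. = FALSE)
  if (is.null(som_shape)) {
    units <- max(2L, as.integer(round(n / 10)))
    side <- max(1L, as.integer(floor(sqrt(units))))
    som_shape <- c(side, as.integer(ceiling(units / side)))
  }
  som_shape <- as.integer(som_shape)
  if (prod(som_shape) < 2L) stop("SOM must have at least 2 units", call. = FALSE)

  x <- descriptor_matrix(segments$sequence)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  grid <- class::somgrid(som_shape[1], som_shape[2], "rectangular")
  radii <- unique(pmax(1, round(seq(max(som_shape) / 2, 1, length.out = 4))))
  som <- class::batchSOM(x, grid, radii = radii)
  # nearest map unit per sample (squared Euclidean; first unit wins ties)
  d2 <- matrix(rowSums(som$codes^2), n, nrow(som$codes), byrow = TRUE) -
    2 * x %*% t(som$codes)
  neuron <- max.col(-d2, ties.method = "first")

  # largest-remainder allocation: hit the overall validation fraction while
  # drawing at least one sample per multi-member unit for each set
  units <- sort(unique(neuron))
  sizes <- vapply(units, function(u) sum(neuron == u), integer(1))
  elig <- sizes >= 2L                     # singleton units go to training
  quota <- val_fraction * sizes
  take <- ifelse(elig, pmax(1L, pmin(floor(quota), sizes - 1L)), 0L)
  target <- round(val_fraction * n)
  while (sum(take) < target && any(elig & take < sizes - 1L)) {
    rem <- ifelse(elig & take < sizes - 1L, quota - take, -Inf)
    i <- which.max(rem)
    take[i] <- take[i] + 1L
  }
  while (sum(take) > target && any(elig & take > 1L)) {
    rem <- ifelse(elig & take > 1L, quota - take, Inf)
    i <- which.min(rem)
    take[i] <- take[i] - 1L
  }
  val_idx <- integer(0)
  for (j in seq_along(units)) {
    if (take[j] == 0L) next
    members <- which(neuron == units[j])
    val_idx <- c(val_idx, sample(members, take[j]))
  }
  segments$neuron <- neuron
  list(training = segments[setdiff(seq_len(n), val_idx), , drop = FALSE],
       validation = segments[sort(val_idx), , drop = FALSE],
       som_shape = som_shape, seed = as.integer(seed))
}

#' Write a split manifest for audit
#'
#' @param split Result of [som_split()].
#' @param path Output TSV.
#' @export
write_split_manifest <- function(split, path) {
  tr <- split$training; tr$set <- "training"
  va <- split$validation; va$set <- "validation"
  m <- rbind(tr, va)
  m <- m[order(m$id, m$start), c("id", "start", "end", "label", "neuron", "set")]
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
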