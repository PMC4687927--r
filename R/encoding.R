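#' The 20 standard amino acids in alphabetical one-letter order
#'
#' Fixed ordering used for all descriptor layouts in the package: rows and
#' columns of the adjacency matrix and the row-major flattening of the
#' 400-dimensional descriptor all follow this order.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Version tag of the descriptor layout
#'
#' Embedded in trained models; prediction refuses descriptors produced under
#' a different layout.
#' @export
ENCODING_VERSION <- "aa-pair-rowmajor-1"

# Map ambiguity codes to a standard residue; X handled separately.
.AA_SUBSTITUTIONS <- c(B = "N", Z = "Q", U = "C")

#' Normalize a protein sequence to the 20-letter alphabet
#'
#' Upper-cases the sequence and resolves the common ambiguity codes
#' (B to N, Z to Q, U to C). The fully ambiguous code X is rejected unless
#' `allow_x = TRUE`, in which case X is kept and every residue pair touching
#' an X is simply not counted by the encoders.
#'
#' @param residues Character scalar, the raw sequence.
#' @param allow_x Keep X characters instead of failing.
#' @return Normalized sequence string.
#' @export
normalize_sequence <- function(residues, allow_x = FALSE) {
  stopifnot(is.character(residues), length(residues) == 1L)
  s <- toupper(gsub("[ \t*]", "", residues))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  sub <- .AA_SUBSTITUTIONS[chars]
  chars[!is.na(sub)] <- sub[!is.na(sub)]
  ok <- chars %in% AA_ALPHABET20 | (allow_x & chars == "X")
  if (!all(ok)) {
    i <- which(!ok)[1]
    stop(sprintf("unknown residue '%s' at position %d (after normalization)",
                 chars[i], i), call. = FALSE)
  }
  paste(chars, collapse = "")
}

#' Construct a protein sequence record
#'
#' @param id Identifier (free text; first whitespace-delimited token of a
#'   FASTA description line).
#' @param residues Amino-acid sequence, normalized via
#'   [normalize_sequence()].
#' @param allow_x Passed to the normalizer.
#' @return A `protein_seq` object (list with `id`, `residues`, `n`).
#' @export
protein_seq <- function(id, residues, allow_x = FALSE) {
  residues <- normalize_sequence(residues, allow_x = allow_x)
  if (nchar(residues) < 1L) stop("empty sequence for '", id, "'", call. = FALSE)
  structure(list(id = as.character(id), residues = residues,
                 n = nchar(residues)),
            class = "protein_seq")
}

#' @export
print.protein_seq <- function(x, ...) {
  cat(sprintf("<protein_seq> %s (%d aa)\n", x$id, x$n))
  invisible(x)
}

#' Cut a protein into overlapping fixed-length windows
#'
#' A protein of n residues yields n - w + 1 windows at step 1; consecutive
#' windows share w - 1 residues. Coordinates are 1-based inclusive.
#'
#' @param seq A `protein_seq`, or a plain sequence string.
#' @param w Window length (default 10, matching the membrane-spanning
#'   thickness of a beta-strand).
#' @return Data frame with columns `id`, `start`, `end`, `sequence`, one row
#'   per window, ordered by `start`.
#' @export
segment_protein <- function(seq, w = 10L) {
  if (is.character(seq)) seq <- protein_seq("unnamed", seq)
  stopifnot(inherits(seq, "protein_seq"), w >= 2L)
  n <- seq$n
  if (n < w) {
    stop(sprintf("sequence '%s' too short: %d residues, minimum %d (window length)",
                 seq$id, n, w), call. = FALSE)
  }
  starts <- seq_len(n - w + 1L)
  data.frame(id = seq$id, start = starts, end = starts + w - 1L,
             sequence = substring(seq$residues, starts, starts + w - 1L),
             stringsAsFactors = FALSE)
}

#' Amino-acid adjacency matrix of a segment
#'
#' Entry (a, b) counts how often residue a is immediately followed
#' (N-terminus to C-terminus) by residue b. Pairs are ordered, so the matrix
#' is generally asymmetric; entries sum to length - 1. Pairs touching an X
#' (only possible after `normalize_sequence(allow_x = TRUE)`) are skipped.
#'
#' @param segment Segment sequence string (length >= 2).
#' @return Integer 20 x 20 matrix with dimnames [AA_ALPHABET20].
#' @export
adjacency_matrix <- function(segment) {
  stopifnot(is.character(segment), length(segment) == 1L)
  chars <- strsplit(segment, "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (L < 2L) stop("segment too short to encode: need length >= 2", call. = FALSE)
  bad <- !(chars %in% c(AA_ALPHABET20, "X"))
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("unknown residue '%s' at position %d", chars[i], i),
         call. = FALSE)
  }
  m <- matrix(0L, 20L, 20L, dimnames = list(AA_ALPHABET20, AA_ALPHABET20))
  a <- chars[-L]; b <- chars[-1L]
  keep <- a != "X" & b != "X"
  if (any(keep)) {
    tab <- table(factor(a[keep], levels = AA_ALPHABET20),
                 factor(b[keep], levels = AA_ALPHABET20))
    m <- m + matrix(as.integer(tab), 20L, 20L,
                    dimnames = list(AA_ALPHABET20, AA_ALPHABET20))
  }
  m
}

#' 400-dimensional pair-frequency descriptor of a segment
#'
#' Row-major flattening of [adjacency_matrix()]: element 20 (i - 1) + j is
#' the count of the ordered pair (AA_i, AA_j) in alphabetical order, so the
#' first 20 entries are AA, AC, AD, ... A pure function of the segment
#' string; context in the parent protein is irrelevant.
#'
#' @inheritParams adjacency_matrix
#' @return Named integer vector of length 400 (names like "AC" = A then C).
#' @export
descriptor_vector <- function(segment) {
  m <- adjacency_matrix(segment)
  v <- as.integer(t(m))
  names(v) <- as.vector(t(outer(AA_ALPHABET20, AA_ALPHABET20, paste0)))
  v
}

#' Rowsum (plain composition) descriptor
#'
#' The 20-dimensional marginal of the adjacency matrix: entry a is the
#' number of pairs starting with residue a, i.e. essentially the residue
#' composition of the segment. Condensing away the adjacency structure loses
#' the sequence-order information the classifier feeds on; this encoding is
#' provided for comparison experiments only and is never used by the
#' default pipeline.
#'
#' @inheritParams adjacency_matrix
#' @return Named integer vector of length 20.
#' @export
rowsum_descriptor <- function(segment) {
  m <- adjacency_matrix(segment)
  v <- as.integer(rowSums(m))
  names(v) <- AA_ALPHABET20
  v
}

#' Descriptor matrix for a set of segments
#'
#' @param segments Character vector of segment strings.
#' @return Integer matrix, one row per segment, 400 columns in the fixed
#'   row-major pair order.
#' @export
descriptor_matrix <- function(segments) {
  if (length(segments) == 0L) {
    m <- matrix(integer(0), 0L, 400L)
    colnames(m) <- as.vector(t(outer(AA_ALPHABET20, AA_ALPHABET20, paste0)))
    return(m)
  }
  m <- t(vapply(segments, descriptor_vector, integer(400L),
                USE.NAMES = FALSE))
  colnames(m) <- as.vector(t(outer(AA_ALPHABET20, AA_ALPHABET20, paste0)))
  m
}

#' Export window descriptors as a dense table
#'
#' One row per window: id, start, end, then the 400 pair counts. Written as
#' TSV when `path` is given.
#'
#' @param seq A `protein_seq`.
#' @param w Window length.
#' @param path Optional output TSV path.
#' @return Data frame (invisibly when written to file).
#' @export
descriptor_table <- function(seq, w = 10L, path = NULL) {
  win <- segment_protein(seq, w)
  d <- as.data.frame(descriptor_matrix(win$sequence))
  out <- cbind(win[c("id", "start", "end")], d)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
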