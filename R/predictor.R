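#' Find stretches of consecutive tm windows
#'
#' A stretch is a maximal run of at least `min_run` consecutive windows
#' classified tm. A single isolated ntm window between two tm runs is
#' bridged (tolerated) when the merged run would contain at least
#' `bridge_min` tm windows — short runs on either side of a gap stay
#' separate. Merging is applied left to right until no further merge is
#' possible; leftover runs shorter than `min_run` are dropped.
#'
#' @param labels Character vector of per-window "tm"/"ntm" calls for one
#'   protein, aligned to the windows of [segment_protein()].
#' @param min_run Minimum number of tm windows in a reported stretch
#'   (default 4; with 10-residue windows this spans 13 residues, the room
#'   needed to place a strand of 6..12 residues).
#' @param bridge_min Minimum tm windows in a merged run for a 1-window gap
#'   to be bridged (default 7, i.e. the stretch extends beyond six).
#' @return Data frame: first_window, last_window, n_tm (count of tm
#'   windows), bridged (comma-joined gap window indices, "" if none).
#' @export
find_stretches <- function(labels, min_run = 4L, bridge_min = 7L) {
  empty <- data.frame(first_window = integer(), last_window = integer(),
                      n_tm = integer(), bridged = character(),
                      stringsAsFactors = FALSE)
  if (length(labels) == 0L) return(empty)
  is_tm <- labels == "tm"
  r <- rle(is_tm)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  runs$n_tm <- runs$end - runs$start + 1L
  runs$bridged <- vector("list", nrow(runs))
  if (nrow(runs) == 0L) return(empty)

  # left-to-right single-gap merging until fixpoint
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < nrow(runs)) {
      gap <- runs$start[i + 1L] - runs$end[i] - 1L
      if (gap == 1L && runs$n_tm[i] + runs$n_tm[i + 1L] >= bridge_min) {
        runs$bridged[[i]] <- c(runs$bridged[[i]], runs$end[i] + 1L,
                               runs$bridged[[i + 1L]])
        runs$end[i] <- runs$end[i + 1L]
        runs$n_tm[i] <- runs$n_tm[i] + runs$n_tm[i + 1L]
        runs <- runs[-(i + 1L), , drop = FALSE]
        merged <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!merged) break
  }
  runs <- runs[runs$n_tm >= min_run, , drop = FALSE]
  data.frame(first_window = runs$start, last_window = runs$end,
             n_tm = runs$n_tm,
             bridged = vapply(runs$bridged, function(b)
               paste(sort(unlist(b)), collapse = ","), character(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Residue span covered by a stretch of windows
#'
#' Windows i..j of length w cover residues i .. j + w - 1; a minimal
#' 4-window stretch therefore spans exactly 13 residues at w = 10.
#'
#' @param first_window,last_window Window indices (window i starts at
#'   residue i).
#' @param w Window length.
#' @return Integer c(span_start, span_end), 1-based inclusive.
#' @export
stretch_span <- function(first_window, last_window, w = 10L) {
  stopifnot(last_window >= first_window)
  c(span_start = as.integer(first_window),
    span_end = as.integer(last_window + w - 1L))
}

#' Split a long stretch span into hairpin sub-regions
#'
#' Beta-hairpins with tight 2-5 residue turns blur into one long run of tm
#' windows covering both strands. A span is divided as soon as two
#' sub-regions of at least one full window (10 residues) fit, i.e. at 21
#' residues or more, into max(2, floor(length / piece)) contiguous pieces
#' of near-equal length (earlier pieces at most one residue longer), each
#' refined independently — so long spans break into sub-regions of
#' approximately `piece` (13) residues, while the shortest fused hairpins
#' (two minimal strands around a tight turn, spans of 21-25 residues)
#' still split in two, which is what separates their strands downstream.
#' Spans of up to 20 residues, reachable by a single long strand, stay
#' whole.
#'
#' @param span_start,span_end Residue span of the stretch.
#' @param piece Nominal sub-region length (default 13).
#' @return Data frame with columns start, end, one row per sub-region.
#' @export
split_stretch <- function(span_start, span_end, piece = 13L) {
  len <- span_end - span_start + 1L
  stopifnot(len >= 1L)
  k <- if (len < 21L) 1L else max(2L, len %/% piece)
  if (k == 1L) {
    return(data.frame(start = as.integer(span_start),
                      end = as.integer(span_end)))
  }
  base <- len %/% k
  extra <- len %% k
  lens <- rep(base, k)
  if (extra > 0L) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  ends <- span_start - 1L + cumsum(lens)
  data.frame(start = as.integer(c(span_start, ends[-k] + 1L)),
             end = as.integer(ends))
}

#' Enumerate candidate sub-segments of a stretch
#'
#' Candidate strand boundaries are taken from the termini of the stretch's
#' constituent tm windows: starts from window first residues, ends from
#' window last residues. All (start, end) combinations whose length lies in
#' [len_min, len_max] are returned, deduplicated and ordered by (start,
#' end). When a sub-region from [split_stretch()] is given, only windows
#' overlapping it contribute termini and candidates are clipped to the
#' sub-region before the length filter.
#'
#' @param tm_windows Integer vector of tm window indices in the stretch
#'   (bridged ntm windows excluded).
#' @param w Window length.
#' @param len_min,len_max Allowed strand lengths (default 6..12).
#' @param region Optional c(start, end) sub-region to clip to.
#' @return Data frame: start, end, length.
#' @export
enumerate_subsegments <- function(tm_windows, w = 10L, len_min = 6L,
                                  len_max = 12L, region = NULL) {
  empty <- data.frame(start = integer(), end = integer(), length = integer())
  if (length(tm_windows) == 0L) return(empty)
  starts <- as.integer(tm_windows)
  ends <- starts + w - 1L
  if (!is.null(region)) {
    keep <- ends >= region[1] & starts <= region[2]
    starts <- pmax(starts[keep], region[1])
    ends <- pmin(ends[keep], region[2])
    if (!length(starts)) return(empty)
  }
  cand <- expand.grid(start = sort(unique(starts)), end = sort(unique(ends)))
  cand$length <- cand$end - cand$start + 1L
  cand <- cand[cand$length >= len_min & cand$length <= len_max, , drop = FALSE]
  cand <- unique(cand)
  cand <- cand[order(cand$start, cand$end), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Score and rank candidate sub-segments by their boundary residues
#'
#' The score of a candidate is the sum of the preference-table N-terminal
#' score of its first residue and C-terminal score of its last residue.
#' Candidates are ranked by descending score; ties break toward the
#' candidate whose midpoint is nearest the span midpoint, then toward the
#' smaller start.
#'
#' @param subsegments Data frame from [enumerate_subsegments()].
#' @param residues Full protein sequence string (candidates index into it).
#' @param table A `preference_table`.
#' @param span c(span_start, span_end) of the parent stretch or sub-region,
#'   used for the midpoint tie-break.
#' @return The input with a `score` column, ranked.
#' @export
score_subsegments <- function(subsegments, residues, table, span) {
  if (nrow(subsegments) == 0L) {
    subsegments$score <- numeric(0)
    return(subsegments)
  }
  if (max(subsegments$end) > nchar(residues)) {
    stop("sub-segment outside sequence bounds", call. = FALSE)
  }
  first <- substring(residues, subsegments$start, subsegments$start)
  last <- substring(residues, subsegments$end, subsegments$end)
  subsegments$score <- preference_score(table, first, "N") +
    preference_score(table, last, "C")
  mid <- (subsegments$start + subsegments$end) / 2
  span_mid <- (span[1] + span[2]) / 2
  ord <- order(-subsegments$score, abs(mid - span_mid), subsegments$start)
  out <- subsegments[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the reported transmembrane region from ranked candidates
#'
#' Among the top three positive-scoring candidates, the one whose midpoint
#' lies closest to the span midpoint is reported (the strand core sits at
#' the centre of the window consensus; the preference table only places its
#' boundaries). Ties break toward the higher score, then the smaller start.
#' With no positive-scoring candidate the stretch is suppressed and nothing
#' is reported.
#'
#' @param ranked Data frame from [score_subsegments()] (already ranked).
#' @param span c(span_start, span_end) of the stretch or sub-region.
#' @return One-row data frame (start, end, length, score) or NULL.
#' @export
select_tm <- function(ranked, span) {
  pos <- ranked[ranked$score > 0, , drop = FALSE]
  if (nrow(pos) == 0L) return(NULL)
  top3 <- pos[seq_len(min(3L, nrow(pos))), , drop = FALSE]
  mid <- (top3$start + top3$end) / 2
  span_mid <- (span[1] + span[2]) / 2
  ord <- order(abs(mid - span_mid), -top3$score, top3$start)
  out <- top3[ord[1L], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict transmembrane beta-strand regions of a protein
#'
#' The full two-layer pipeline: the sequence is cut into overlapping
#' w-residue windows, each window is encoded as a 400-dimensional pair
#' descriptor and classified tm/ntm, runs of tm windows become stretches,
#' long stretches are split into hairpin sub-regions, and each (sub-)region
#' is refined to a final 6-12 residue strand by boundary scoring against
#' the preference table.
#'
#' @param seq A `protein_seq` (or sequence string).
#' @param model A `btm_classifier`.
#' @param table A `preference_table`.
#' @param w Window length (default 10).
#' @param min_run,bridge_min Stretch-detection parameters
#'   ([find_stretches()]).
#' @param len_min,len_max Strand length bounds (default 6..12).
#' @param piece Hairpin sub-region size ([split_stretch()]).
#' @param labels Optional precomputed per-window label vector; bypasses the
#'   classifier (used to replay a known first-layer output).
#' @return Data frame: protein_id, start, end, length, score, stretch,
#'   sorted by start. Zero rows when nothing is predicted; a sequence
#'   shorter than w yields zero rows with a warning.
#' @export
predict_protein <- function(seq, model = NULL, table, w = 10L, min_run = 4L,
                            bridge_min = 7L, len_min = 6L, len_max = 12L,
                            piece = 13L, labels = NULL) {
  if (is.character(seq)) seq <- protein_seq("unnamed", seq)
  empty <- data.frame(protein_id = character(), start = integer(),
                      end = integer(), length = integer(), score = numeric(),
                      stretch = integer(), stringsAsFactors = FALSE)
  if (seq$n < w) {
    warning(sprintf("'%s' shorter than the window (%d < %d): no prediction",
                    seq$id, seq$n, w))
    return(empty)
  }
  win <- segment_protein(seq, w)
  if (is.null(labels)) {
    if (is.null(model)) stop("either a model or precomputed labels required",
                             call. = FALSE)
    labels <- predict_segments(model, descriptor_matrix(win$sequence))
  }
  if (length(labels) != nrow(win)) {
    stop("label vector length does not match the window count", call. = FALSE)
  }
  stretches <- find_stretches(labels, min_run = min_run,
                              bridge_min = bridge_min)
  out <- list()
  for (i in seq_len(nrow(stretches))) {
    fw <- stretches$first_window[i]; lw <- stretches$last_window[i]
    span <- stretch_span(fw, lw, w)
    bridged <- if (nzchar(stretches$bridged[i]))
      as.integer(strsplit(stretches$bridged[i], ",")[[1]]) else integer(0)
    tm_windows <- setdiff(fw:lw, bridged)
    regions <- split_stretch(span[1], span[2], piece)
    for (j in seq_len(nrow(regions))) {
      reg <- c(regions$start[j], regions$end[j])
      cand <- enumerate_subsegments(tm_windows, w, len_min, len_max,
                                    region = if (nrow(regions) > 1L) reg else NULL)
      ranked <- score_subsegments(cand, seq$residues, table, reg)
      pick <- select_tm(ranked, reg)
      if (is.null(pick)) {
        message(sprintf("stretch suppressed: no positive-scoring candidate in %s %d-%d",
                        seq$id, reg[1], reg[2]))
        next
      }
      pick$protein_id <- seq$id
      pick$stretch <- i
      out[[length(out) + 1L]] <- pick
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$start),
             c("protein_id", "start", "end", "length", "score", "stretch")]
  res <- .resolve_overlaps(res)
  rownames(res) <- NULL
  res
}

# Spans of neighbouring stretches may overlap in residue space (runs less
# than w windows apart), so regions selected independently per stretch can
# collide; the reported set must be non-overlapping. Greedy left-to-right:
# of two overlapping regions keep the higher score (earlier start on ties).
.resolve_overlaps <- function(res) {
  if (nrow(res) < 2L) return(res)
  keep <- res[1L, , drop = FALSE]
  for (i in 2L:nrow(res)) {
    last <- nrow(keep)
    if (res$start[i] <= keep$end[last]) {
      if (res$score[i] > keep$score[last]) keep[last, ] <- res[i, ]
    } else {
      keep <- rbind(keep, res[i, , drop = FALSE])
    }
  }
  keep
}

#' Predict over a list of proteins
#'
#' @param proteins Named list of `protein_seq`.
#' @inheritParams predict_protein
#' @param ... Passed to [predict_protein()].
#' @return Row-bound predictions across proteins.
#' @export
predict_corpus <- function(proteins, model, table, ...) {
  res <- lapply(proteins, function(p) predict_protein(p, model, table, ...))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
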