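#' Match predicted against observed regions with the one-to-one overlap rule
#'
#' A prediction is a true positive when it overlaps (shares at least
#' `min_overlap` residues with) exactly one observed region, and it
#' consumes that region: if several such predictions overlap the same
#' observed region, the one with the largest overlap wins (leftmost on
#' ties) and the rest count as false positives. A prediction overlapping
#' zero or two-or-more observed regions is a false positive — a single
#' call spanning both strands of a hairpin is wrong, not half right.
#' Observed regions not consumed are false negatives.
#'
#' @param predicted,observed Data frames with `start`, `end` (1-based
#'   inclusive), each internally non-overlapping.
#' @param min_overlap Minimum shared residues to count as overlapping
#'   (default 1).
#' @return List: TP, FP, FN counts and `matching`, a data frame of
#'   (pred_row, obs_row) index pairs for the true positives.
#' @export
match_regions <- function(predicted, observed, min_overlap = 1L) {
  .check_nonoverlapping(predicted, "predicted")
  .check_nonoverlapping(observed, "observed")
  np <- nrow(predicted); no <- nrow(observed)
  if (np == 0L || no == 0L) {
    return(list(TP = 0L, FP = np, FN = no,
                matching = data.frame(pred_row = integer(),
                                      obs_row = integer())))
  }
  ov <- matrix(0L, np, no)
  for (i in seq_len(np)) {
    ov[i, ] <- pmax(0L, pmin(predicted$end[i], observed$end) -
                      pmax(predicted$start[i], observed$start) + 1L)
  }
  hits <- ov >= min_overlap
  n_hit <- rowSums(hits)
  candidate <- which(n_hit == 1L)          # predictions touching exactly one
  tp_pairs <- list()
  consumed <- logical(no)
  for (j in seq_len(no)) {
    comp <- candidate[hits[candidate, j]]
    if (!length(comp)) next
    best <- comp[order(-ov[comp, j], predicted$start[comp])][1L]
    consumed[j] <- TRUE
    tp_pairs[[length(tp_pairs) + 1L]] <- c(best, j)
  }
  matching <- if (length(tp_pairs)) {
    m <- do.call(rbind, tp_pairs)
    data.frame(pred_row = m[, 1], obs_row = m[, 2])
  } else data.frame(pred_row = integer(), obs_row = integer())
  TP <- nrow(matching)
  list(TP = TP, FP = np - TP, FN = sum(!consumed), matching = matching)
}

.check_nonoverlapping <- function(df, what) {
  if (nrow(df) < 2L) return(invisible(NULL))
  df <- df[order(df$start), ]
  if (any(df$start[-1L] <= df$end[-nrow(df)])) {
    stop("overlapping regions within the ", what, " set", call. = FALSE)
  }
  invisible(NULL)
}

#' Region-level sensitivity and precision
#'
#' Sensitivity = 100 TP / (TP + FN): the share of observed strands that
#' were predicted. Precision (positive predictive value) = 100 TP /
#' (TP + FP): the share of predicted strands that are real. A zero
#' denominator yields NA (not applicable), never 0.
#'
#' @param TP,FN,FP Counts.
#' @return Percentage (full precision; render with [format_percent()]).
#' @export
sensitivity <- function(TP, FN) {
  if (TP + FN == 0) return(NA_real_)
  100 * TP / (TP + FN)
}

#' @rdname sensitivity
#' @export
precision <- function(TP, FP) {
  if (TP + FP == 0) return(NA_real_)
  100 * TP / (TP + FP)
}

#' Two-decimal percentage rendering
#' @param x Percentage or NA.
#' @return Character like "83.71", or "NA".
#' @export
format_percent <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.2f", x))
}

#' Segment overlap between predicted and observed region sets
#'
#' An SOV-style measure restricted to the transmembrane state. For every
#' matched observed/predicted pair ([match_regions()]): minov is the
#' overlap length, maxov the length of the merged extent, and the
#' allowance delta = min(observed residues outside the overlap, predicted
#' residues outside the overlap, floor(len_obs / 2), floor(minov / 2)).
#' Each pair contributes len_obs * (minov + delta) / maxov; the sum is
#' normalized by the total observed transmembrane residues, so unmatched
#' observed regions pull the score down. Identical sets score 100,
#' disjoint sets 0.
#'
#' @inheritParams match_regions
#' @return Percentage in [0, 100].
#' @export
segment_overlap <- function(predicted, observed, min_overlap = 1L) {
  m <- match_regions(predicted, observed, min_overlap)
  obs_len <- observed$end - observed$start + 1L
  total <- sum(obs_len)
  if (total == 0L) return(NA_real_)
  if (nrow(m$matching) == 0L) return(0)
  s <- 0
  for (k in seq_len(nrow(m$matching))) {
    i <- m$matching$pred_row[k]; j <- m$matching$obs_row[k]
    minov <- min(predicted$end[i], observed$end[j]) -
      max(predicted$start[i], observed$start[j]) + 1L
    maxov <- max(predicted$end[i], observed$end[j]) -
      min(predicted$start[i], observed$start[j]) + 1L
    d <- min(obs_len[j] - minov,
             (predicted$end[i] - predicted$start[i] + 1L) - minov,
             obs_len[j] %/% 2L, minov %/% 2L)
    s <- s + obs_len[j] * min(1, (minov + d) / maxov)
  }
  100 * s / total
}

#' Evaluate predictions over a corpus of proteins
#'
#' Counts are pooled over proteins; the per-protein breakdown is returned
#' alongside. Segment overlap is pooled by observed-residue weight.
#'
#' @param predicted,observed Data frames with protein_id, start, end.
#' @param min_overlap Minimum shared residues for a match.
#' @return List with `summary` (one-row data frame: known, predicted, TP,
#'   FP, FN, sensitivity, precision, segment_overlap) and `per_protein`.
#' @export
evaluate_corpus <- function(predicted, observed, min_overlap = 1L) {
  missing <- setdiff(unique(predicted$protein_id), unique(observed$protein_id))
  if (length(missing)) {
    stop("predictions for proteins with no annotations: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ids <- unique(observed$protein_id)
  rows <- lapply(ids, function(id) {
    p <- predicted[predicted$protein_id == id, , drop = FALSE]
    o <- observed[observed$protein_id == id, , drop = FALSE]
    m <- match_regions(p, o, min_overlap)
    data.frame(protein_id = id, known = nrow(o), predicted = nrow(p),
               TP = m$TP, FP = m$FP, FN = m$FN,
               sensitivity = sensitivity(m$TP, m$FN),
               precision = precision(m$TP, m$FP),
               segment_overlap = segment_overlap(p, o, min_overlap),
               obs_residues = sum(o$end - o$start + 1L),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  TP <- sum(per$TP); FP <- sum(per$FP); FN <- sum(per$FN)
  w <- per$obs_residues
  pooled_sov <- sum(per$segment_overlap * w) / sum(w)
  summary <- data.frame(known = sum(per$known), predicted = sum(per$predicted),
                        TP = TP, FP = FP, FN = FN,
                        sensitivity = sensitivity(TP, FN),
                        precision = precision(TP, FP),
                        segment_overlap = pooled_sov)
  list(summary = summary,
       per_protein = per[, setdiff(names(per), "obs_residues")])
}

#' Window-level benchmark on annotated proteins
#'
#' Classifier accuracy on fixed-length windows with unambiguous truth:
#' windows lying entirely inside an annotated transmembrane region count
#' as tm, windows not touching any region as ntm (boundary-straddling
#' windows are excluded). The ntm windows are subsampled to match the tm
#' count, so the benchmark is balanced and every window has the same
#' length — accuracy is 50% when the classifier carries no signal,
#' whatever its class bias.
#'
#' @param corpus List of `annotated_protein`.
#' @param model A `btm_classifier`.
#' @param w Window length.
#' @param seed Subsampling seed.
#' @return List: accuracy (fraction), n (windows evaluated).
#' @export
window_accuracy <- function(corpus, model, w = 10L, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  tm_seq <- character(0); ntm_seq <- character(0)
  for (p in corpus) {
    if (p$seq$n < w) next
    win <- segment_protein(p$seq, w)
    r <- p$tm_regions
    inside_any <- vapply(seq_len(nrow(win)), function(i) {
      any(win$start[i] >= r$start & win$end[i] <= r$end)
    }, logical(1))
    touches <- vapply(seq_len(nrow(win)), function(i) {
      any(win$end[i] >= r$start & win$start[i] <= r$end)
    }, logical(1))
    tm_seq <- c(tm_seq, win$sequence[inside_any])
    ntm_seq <- c(ntm_seq, win$sequence[!touches])
  }
  k <- min(length(tm_seq), length(ntm_seq))
  if (k == 0L) stop("no unambiguous windows in the corpus", call. = FALSE)
  tm_seq <- sample(tm_seq, k); ntm_seq <- sample(ntm_seq, k)
  x <- descriptor_matrix(c(tm_seq, ntm_seq))
  truth <- rep(c("tm", "ntm"), each = k)
  list(accuracy = mean(predict_segments(model, x) == truth), n = 2L * k)
}
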