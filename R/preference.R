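#' Position-specific amino-acid preference table
#'
#' Scores for the two boundary positions of a transmembrane strand: for
#' each of the 20 amino acids, `score_N` rates it at the strand's first
#' (N-terminal) residue and `score_C` at the last (C-terminal) residue.
#' Statistically preferred residues score positive; disfavoured residues
#' are penalized with a negative score. The table drives only the boundary
#' selection of the second prediction layer, never the window classifier.
#'
#' @param score_N,score_C Numeric vectors of length 20 named by
#'   [AA_ALPHABET20].
#' @return A `preference_table` (data frame: amino_acid, score_N, score_C).
#' @export
preference_table <- function(score_N, score_C) {
  for (v in list(score_N, score_C)) {
    if (!all(AA_ALPHABET20 %in% names(v)) || any(!is.finite(v))) {
      stop("scores must be finite and named by all 20 amino acids",
           call. = FALSE)
    }
  }
  structure(data.frame(amino_acid = AA_ALPHABET20,
                       score_N = as.numeric(score_N[AA_ALPHABET20]),
                       score_C = as.numeric(score_C[AA_ALPHABET20]),
                       stringsAsFactors = FALSE),
            class = c("preference_table", "data.frame"))
}

#' Estimate a boundary preference table from annotated proteins
#'
#' For each amino acid a, the N-terminal score is the log2 ratio of its
#' observed count at strand first positions to the count expected under
#' the corpus-wide residue composition, with a pseudocount on both sides;
#' C-terminal scores are computed the same way from strand last positions.
#' Scores are then centered to mean zero within each terminal so that
#' "preferred" cleanly maps to positive values.
#'
#' @param proteins List of `annotated_protein` objects (>= 1 annotated
#'   transmembrane region in total).
#' @param pseudocount Additive smoothing count (default 1).
#' @return A `preference_table`.
#' @export
estimate_preference_table <- function(proteins, pseudocount = 1) {
  if (inherits(proteins, "annotated_protein")) proteins <- list(proteins)
  regions <- 0L
  first_cnt <- last_cnt <- structure(numeric(20), names = AA_ALPHABET20)
  comp <- structure(numeric(20), names = AA_ALPHABET20)
  for (p in proteins) {
    stopifnot(inherits(p, "annotated_protein"))
    chars <- strsplit(p$seq$residues, "", fixed = TRUE)[[1]]
    tab <- table(factor(chars, levels = AA_ALPHABET20))
    comp <- comp + as.numeric(tab)
    r <- p$tm_regions
    regions <- regions + nrow(r)
    if (nrow(r)) {
      ftab <- table(factor(chars[r$start], levels = AA_ALPHABET20))
      ltab <- table(factor(chars[r$end], levels = AA_ALPHABET20))
      first_cnt <- first_cnt + as.numeric(ftab)
      last_cnt <- last_cnt + as.numeric(ltab)
    }
  }
  if (regions == 0L) {
    stop("no annotated transmembrane regions in the corpus", call. = FALSE)
  }
  freq <- comp / sum(comp)
  score <- function(obs) {
    s <- log2((obs + pseudocount) / (regions * freq + pseudocount))
    s - mean(s)
  }
  preference_table(score(first_cnt), score(last_cnt))
}

#' Score looked up at a strand boundary
#'
#' @param table A `preference_table`.
#' @param residue Single-letter amino-acid code.
#' @param terminal "N" or "C".
#' @return Numeric score.
#' @export
preference_score <- function(table, residue, terminal = c("N", "C")) {
  terminal <- match.arg(terminal)
  i <- match(residue, table$amino_acid)
  if (anyNA(i)) {
    stop("residue not in preference table: ",
         paste(residue[is.na(i)], collapse = ", "), call. = FALSE)
  }
  if (terminal == "N") table$score_N[i] else table$score_C[i]
}

#' Read / write a preference table as TSV
#'
#' The file has a header `amino_acid  score_N  score_C`, one row per amino
#' acid (all 20 required, no duplicates); lines starting with '#' are
#' ignored.
#'
#' @param path TSV file.
#' @return A `preference_table`.
#' @export
load_table <- function(path) {
  if (!file.exists(path)) stop("preference table not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = c(
                            amino_acid = "character"))
  need <- c("amino_acid", "score_N", "score_C")
  if (!all(need %in% names(df))) {
    stop("preference TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dup <- df$amino_acid[duplicated(df$amino_acid)]
  if (length(dup)) stop("duplicate preference rows: ",
                        paste(dup, collapse = ", "), call. = FALSE)
  missing <- setdiff(AA_ALPHABET20, df$amino_acid)
  if (length(missing)) stop("preference table missing rows: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  if (!is.numeric(df$score_N) || !is.numeric(df$score_C) ||
      any(!is.finite(df$score_N)) || any(!is.finite(df$score_C))) {
    bad <- df$amino_acid[!is.finite(df$score_N) | !is.finite(df$score_C)]
    stop("non-numeric score in rows: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  preference_table(structure(df$score_N, names = df$amino_acid),
                   structure(df$score_C, names = df$amino_acid))
}

#' @rdname load_table
#' @param table A `preference_table`.
#' @export
save_table <- function(table, path) {
  stopifnot(inherits(table, "preference_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' The preference table shipped with the package
#'
#' Estimated from the default synthetic beta-barrel corpus; a stand-in that
#' makes the predictor usable out of the box, not a statistic of real
#' structurally resolved proteins. Supply your own table (from
#' [estimate_preference_table()] on real annotations, or [load_table()])
#' for production use.
#'
#' @return A `preference_table`.
#' @export
default_preference_table <- function() {
  load_table(system.file("extdata", "preference_synthetic.tsv",
                         package = "barreltm", mustWork = TRUE))
}
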