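#' Read protein sequences from a FASTA file
#'
#' Standard multi-record FASTA via Biostrings; the record identifier is the
#' description line up to the first whitespace.
#'
#' @param path FASTA file.
#' @param allow_x Keep X residues (pairs touching X are not counted by the
#'   encoders).
#' @return Named list of [protein_seq()] objects.
#' @export
read_fasta <- function(path, allow_x = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  aas <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aas))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  out <- Map(function(id, s) protein_seq(id, s, allow_x = allow_x),
             ids, as.character(aas))
  names(out) <- ids
  out
}

#' Write protein sequences to FASTA
#'
#' @param proteins List of `protein_seq` (or `annotated_protein`) objects.
#' @param path Output path.
#' @export
write_fasta <- function(proteins, path) {
  seqs <- vapply(proteins, function(p) {
    if (inherits(p, "annotated_protein")) p <- p$seq
    p$residues
  }, character(1))
  ids <- vapply(proteins, function(p) {
    if (inherits(p, "annotated_protein")) p <- p$seq
    p$id
  }, character(1))
  x <- Biostrings::AAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read region annotations from TSV
#'
#' Expected columns: `protein_id`, `start`, `end`; 1-based inclusive residue
#' coordinates. Lines starting with '#' are ignored; a header line is
#' required.
#'
#' @param path TSV file.
#' @return Data frame with columns protein_id, start, end.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("region file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("protein_id", "start", "end")
  if (!all(need %in% names(df))) {
    stop("region TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(is.na(df$start) | is.na(df$end))) {
    stop("non-numeric start/end in region file ", path, call. = FALSE)
  }
  df[order(df$protein_id, df$start), need]
}

#' Write region annotations / predictions as TSV
#'
#' @param df Data frame with at least protein_id, start, end (1-based
#'   inclusive).
#' @param path Output path.
#' @export
write_regions <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert 1-based inclusive regions to BED (0-based half-open) and back
#'
#' @param df Data frame with protein_id, start, end.
#' @return Data frame in the other convention.
#' @export
regions_to_bed <- function(df) {
  data.frame(chrom = df$protein_id, chromStart = df$start - 1L,
             chromEnd = df$end, stringsAsFactors = FALSE)
}

#' @rdname regions_to_bed
#' @param bed Data frame with chrom, chromStart, chromEnd.
#' @export
bed_to_regions <- function(bed) {
  data.frame(protein_id = bed$chrom, start = bed$chromStart + 1L,
             end = bed$chromEnd, stringsAsFactors = FALSE)
}

#' Attach region annotations to sequences
#'
#' @param proteins Named list of `protein_seq` from [read_fasta()].
#' @param regions Data frame from [read_regions()].
#' @param require_all Error if a protein has no annotation rows.
#' @return Named list of [annotated_protein()] objects.
#' @export
annotate_proteins <- function(proteins, regions, require_all = TRUE) {
  ids <- names(proteins)
  missing <- setdiff(ids, unique(regions$protein_id))
  if (require_all && length(missing)) {
    stop("no annotations for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lapply(proteins, function(p) {
    r <- regions[regions$protein_id == p$id, , drop = FALSE]
    annotated_protein(p, r[c("start", "end")])
  })
}
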