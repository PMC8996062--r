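#' Read pre-miRNA sequences from FASTA
#'
#' Reads a FASTA file and canonicalizes every record: residues are
#' uppercased and `T` is mapped to `U` (miRNA FASTA is frequently
#' DNA-alphabet). Any other residue outside `A/C/G/U` is a hard error
#' naming the record and the offending character — the feature encoders'
#' denominators assume a clean four-letter alphabet. The record id is the
#' header up to the first whitespace; the remainder of the header is kept
#' as the `description` metadata column but ignored for identity.
#'
#' @param path path to a FASTA file.
#' @return an [Biostrings::RNAStringSet] named by record id, in file order.
#'   An empty file yields an empty set.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">mir-1 some description", "acgu", ">mir-2", "GGGT"), fa)
#' readRnaFasta(fa)
#' @export
readRnaFasta <- function(path) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path, call. = FALSE)
  if (file.size(path) == 0)
    return(Biostrings::RNAStringSet())
  raw <- Biostrings::readBStringSet(path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids)))
    stop("FASTA record with an empty id (header starts with whitespace)",
         call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA ids: ", paste(dup, collapse = ", "),
         call. = FALSE)
  seqs <- chartr("T", "U", toupper(as.character(raw)))
  leftovers <- gsub("[ACGU]", "", seqs)
  if (any(nzchar(leftovers))) {
    bad <- which(nzchar(leftovers))
    msgs <- vapply(bad, function(i)
      sprintf("'%s' (invalid residue '%s')", ids[i],
              substr(leftovers[i], 1, 1)), character(1))
    stop("non-A/C/G/U residue after canonicalization in record(s): ",
         paste(msgs, collapse = "; "), call. = FALSE)
  }
  if (any(!nzchar(seqs)))
    stop("empty sequence in record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  out <- Biostrings::RNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  out
}

#' Write canonical RNA sequences as FASTA
#'
#' @param sequences a named [Biostrings::RNAStringSet].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeRnaFasta <- function(sequences, path) {
  stopifnot(is(sequences, "RNAStringSet"))
  Biostrings::writeXStringSet(sequences, filepath = path)
  invisible(path)
}

#' Read a binary essentiality label table
#'
#' Reads a two-column (id, label) table — tab- or comma-delimited,
#' auto-detected — and aligns it to an already-read sequence collection.
#' Every sequence must receive exactly one label; 1 marks the essential
#' (positive) class and 0 the non-essential class.
#'
#' @param path path to the label table (no header row).
#' @param sequences the [Biostrings::RNAStringSet] the labels refer to.
#' @return a [LabeledRnaSet-class] in sequence order.
#' @export
readLabels <- function(path, sequences) {
  if (!file.exists(path))
    stop("label file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = FALSE,
                           colClasses = "character",
                           strip.white = TRUE)
  if (ncol(tab) != 2L)
    stop("label table must have exactly two columns (id, label); found ",
         ncol(tab), call. = FALSE)
  ids <- names(sequences)
  missing <- setdiff(ids, tab[[1]])
  extra <- setdiff(tab[[1]], ids)
  if (length(missing))
    stop("label table is missing id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (length(extra))
    stop("label table has unknown id(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab[[1]]))
    stop("label table has duplicate id(s): ",
         paste(unique(tab[[1]][duplicated(tab[[1]])]), collapse = ", "),
         call. = FALSE)
  lab <- tab[[2]][match(ids, tab[[1]])]
  if (!all(lab %in% c("0", "1")))
    stop("labels must be 0 or 1; found: ",
         paste(unique(setdiff(lab, c("0", "1"))), collapse = ", "),
         call. = FALSE)
  labeledRnaSet(sequences, as.integer(lab))
}

#' Write per-sequence essentiality predictions
#'
#' Tab-delimited, one row per input in input order, with a header row:
#' `id`, `score` (essentiality probability) and `label` (score thresholded
#' at the supplied cutoff). The file is written atomically
#' (write-then-rename).
#'
#' @param ids character vector of sequence ids.
#' @param scores numeric scores in \[0, 1\].
#' @param labels predicted 0/1 labels; defaults to `scores >= cutoff`.
#' @param path output path.
#' @param cutoff score threshold for the default labels.
#' @return invisibly, `path`.
#' @export
writePredictions <- function(ids, scores, labels = NULL, path,
                             cutoff = 0.5) {
  stopifnot(length(ids) == length(scores))
  if (length(scores) && (any(!is.finite(scores)) ||
                         any(scores < 0 | scores > 1)))
    stop("scores must lie in [0, 1]", call. = FALSE)
  if (is.null(labels)) labels <- as.integer(scores >= cutoff)
  stopifnot(length(labels) == length(ids), all(labels %in% c(0L, 1L)))
  df <- data.frame(id = as.character(ids), score = scores,
                   label = as.integer(labels))
  tmp <- paste0(path, ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  if (!file.rename(tmp, path))
    stop("cannot write predictions to ", path, call. = FALSE)
  invisible(path)
}

#' Write a label table for a labeled dataset
#'
#' @param dataset a [LabeledRnaSet-class].
#' @param path output path (tab-delimited id, label; no header).
#' @return invisibly, `path`.
#' @export
writeLabels <- function(dataset, path) {
  stopifnot(is(dataset, "LabeledRnaSet"))
  utils::write.table(
    data.frame(id = names(rnaSequences(dataset)), label = essLabels(dataset)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
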