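## Secondary structure handling: dot-bracket validation, MFE folding via the
## ViennaRNA RNAfold program, and the per-residue 10-category status track
## consumed by the PseDSSPC encoder. Positions are 1-based everywhere, in
## storage and in messages.

#' Validate a dot-bracket string and return its pairing table
#'
#' Accepts only the plain three-symbol dot-bracket alphabet `(`, `)`, `.`
#' (no pseudoknot dialects). Checks bracket balance and returns, for each
#' position, the 1-based index of its pairing partner, or `NA` when
#' unpaired.
#'
#' @param brackets a single dot-bracket string.
#' @param id record id used in error messages.
#' @return integer vector of partner indices (`NA` = unpaired).
#' @examples
#' dotBracketPairs("((..))")  # 6 5 NA NA 2 1
#' @export
dotBracketPairs <- function(brackets, id = "structure") {
  stopifnot(is.character(brackets), length(brackets) == 1L)
  sym <- strsplit(brackets, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(sym), c("(", ")", "."))
  if (length(bad))
    stop(sprintf("'%s': invalid structure symbol(s) %s (only '(', ')', '.')",
                 id, paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  partner <- rep(NA_integer_, length(sym))
  stack <- integer(0)
  for (i in seq_along(sym)) {
    if (sym[i] == "(") {
      stack <- c(stack, i)
    } else if (sym[i] == ")") {
      if (!length(stack))
        stop(sprintf("'%s': unbalanced brackets (unmatched ')' at position %d)",
                     id, i), call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack))
    stop(sprintf("'%s': unbalanced brackets (unmatched '(' at position %d)",
                 id, stack[1]), call. = FALSE)
  partner
}

#' Predict minimum-free-energy secondary structures with RNAfold
#'
#' Runs the ViennaRNA `RNAfold` program (engine defaults; no PostScript
#' output) on each sequence and returns the MFE dot-bracket strings.
#' Deterministic for a fixed engine version; the engine name and version
#' are attached as the `"engine"` attribute for provenance.
#'
#' @param sequences a named [Biostrings::RNAStringSet] or named character
#'   vector of RNA sequences.
#' @return named character vector of dot-bracket strings, with attribute
#'   `engine` recording the folding engine version.
#' @seealso [readDotBracket()] to supply structures from a file instead.
#' @export
foldRna <- function(sequences) {
  seqs <- stats::setNames(as.character(sequences), names(sequences))
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("sequences must be named", call. = FALSE)
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe))
    stop("RNAfold (ViennaRNA) was not found on PATH. Install ViennaRNA, ",
         "or supply structures with readDotBracket().", call. = FALSE)
  ver <- trimws(system2(exe, "--version", stdout = TRUE)[1])
  if (!length(seqs)) {
    out <- character(0)
    attr(out, "engine") <- ver
    return(out)
  }
  input <- as.vector(rbind(paste0(">", ids), unname(seqs)))
  res <- system2(exe, c("--noPS"), stdout = TRUE, input = input)
  hdr <- grep("^>", res)
  if (length(hdr) != length(seqs))
    stop("RNAfold returned ", length(hdr), " records for ", length(seqs),
         " sequences", call. = FALSE)
  db <- vapply(hdr, function(h) {
    # record: >id / sequence / structure ( energy )
    strsplit(res[h + 2L], " ", fixed = TRUE)[[1]][1]
  }, character(1))
  names(db) <- sub("^>", "", res[hdr])
  db <- db[ids]
  for (i in seq_along(db)) {
    dotBracketPairs(db[i], id = ids[i])     # re-validate engine output
    if (nchar(db[i]) != nchar(seqs[i]))
      stop(sprintf("'%s': RNAfold structure length %d != sequence length %d",
                   ids[i], nchar(db[i]), nchar(seqs[i])), call. = FALSE)
  }
  attr(db, "engine") <- ver
  db
}

#' Read dot-bracket structures from a Vienna-style file
#'
#' The file holds, per record, a `>id` line followed by one dot-bracket
#' line. Every structure is validated (balanced plain brackets, length
#' equal to the matching sequence) and structures are returned for exactly
#' the supplied sequences.
#'
#' @param path path to the structure file.
#' @param sequences named [Biostrings::RNAStringSet] (or named character)
#'   the structures belong to.
#' @return named character vector of dot-bracket strings, in sequence order.
#' @export
readDotBracket <- function(path, sequences) {
  if (!file.exists(path))
    stop("structure file not found: ", path, call. = FALSE)
  seqs <- stats::setNames(as.character(sequences), names(sequences))
  ids <- names(seqs)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr))
    stop("no '>' records in structure file ", path, call. = FALSE)
  recIds <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  if (anyDuplicated(recIds))
    stop("duplicate structure record(s): ",
         paste(unique(recIds[duplicated(recIds)]), collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(recIds, ids)
  if (length(unknown))
    stop("structure record(s) for unknown id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(ids, recIds)
  if (length(missing))
    stop("no structure record for id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  db <- vapply(seq_along(hdr), function(i) {
    stopLine <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines)
    body <- lines[(hdr[i] + 1L):stopLine]
    if (hdr[i] + 1L > stopLine)
      stop(sprintf("'%s': record has no structure line", recIds[i]),
           call. = FALSE)
    trimws(paste(body, collapse = ""))
  }, character(1))
  names(db) <- recIds
  db <- db[ids]
  for (i in seq_along(db)) {
    dotBracketPairs(db[i], id = ids[i])
    if (nchar(db[i]) != nchar(seqs[i]))
      stop(sprintf("'%s': structure length %d != sequence length %d",
                   ids[i], nchar(db[i]), nchar(seqs[i])), call. = FALSE)
  }
  db
}

#' Default pseudo-energy lookup for structural statuses
#'
#' The PseDSSPC correlation tiers only consume squared differences of a
#' per-status energy `e(t)`, so any fixed lookup defines a reproducible
#' feature. The shipped default assigns 0 to the four unpaired statuses
#' and negative pseudo-energies to the six paired statuses, graded by
#' base-pair strength (hydrogen-bond count): `|G-C| > |A-U| > |G-U|`.
#' Override any entry by passing a modified copy to [assignStatus()] or
#' [statusEnergy()].
#'
#' @return named numeric vector over the 10 status categories.
#' @examples
#' defaultEnergyTable()
#' @export
defaultEnergyTable <- function() {
  c(A = 0, C = 0, G = 0, U = 0,
    "A-U" = -2, "U-A" = -2,
    "G-C" = -3, "C-G" = -3,
    "G-U" = -1, "U-G" = -1)
}

checkEnergyTable <- function(table) {
  if (!is.numeric(table) || is.null(names(table)) ||
      !all(STATUS_LEVELS %in% names(table)))
    stop("energy table must be a numeric vector named by all 10 statuses: ",
         paste(STATUS_LEVELS, collapse = ", "), call. = FALSE)
  table[STATUS_LEVELS]
}

#' Pseudo energy of a structural status
#'
#' @param status character vector of status categories.
#' @param table energy lookup, see [defaultEnergyTable()].
#' @return numeric energies.
#' @export
statusEnergy <- function(status, table = defaultEnergyTable()) {
  table <- checkEnergyTable(table)
  bad <- setdiff(unique(status), STATUS_LEVELS)
  if (length(bad))
    stop("unknown status categor(ies): ", paste(bad, collapse = ", "),
         call. = FALSE)
  unname(table[status])
}

#' Derive the per-residue structural status track
#'
#' An unpaired residue's status is its own nucleotide; a paired residue's
#' status is `X-Y` where `X` is its nucleotide and `Y` the nucleotide at
#' its partner position (so the partner of an `X-Y` position is a `Y-X`
#' position). Only the six canonical/wobble pair categories
#' `A-U, U-A, G-C, C-G, G-U, U-G` are admitted; any other pair — which an
#' MFE engine never emits, but a hand-written structure file might — is
#' an error identifying the positions.
#'
#' @param seq an RNA sequence (character or `RNAString`).
#' @param brackets its dot-bracket structure.
#' @param energyTable per-status energy lookup ([defaultEnergyTable()]).
#' @param id record id for messages.
#' @return a [StatusTrack-class].
#' @examples
#' assignStatus("GAAC", "(..)")
#' @export
assignStatus <- function(seq, brackets, energyTable = defaultEnergyTable(),
                         id = "sequence") {
  s <- toupper(as.character(seq))
  if (nchar(s) != nchar(brackets))
    stop(sprintf("'%s': structure length %d != sequence length %d",
                 id, nchar(brackets), nchar(s)), call. = FALSE)
  base <- strsplit(s, "", fixed = TRUE)[[1]]
  if (!all(base %in% RNA_BASES))
    stop(sprintf("'%s': sequence contains non-A/C/G/U residues", id),
         call. = FALSE)
  partner <- dotBracketPairs(brackets, id = id)
  status <- base
  paired <- which(!is.na(partner))
  if (length(paired)) {
    status[paired] <- paste0(base[paired], "-", base[partner[paired]])
    bad <- paired[!status[paired] %in% STATUS_LEVELS]
    if (length(bad))
      stop(sprintf(
        "'%s': non-canonical predicted pair(s) at position(s) %s (%s)",
        id, paste(bad, collapse = ", "),
        paste(unique(status[bad]), collapse = ", ")), call. = FALSE)
  }
  new("StatusTrack", status = status,
      energy = statusEnergy(status, energyTable))
}
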