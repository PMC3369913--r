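#' @keywords internal
"_PACKAGE"

# Alphabets. Ambiguity codes are legal residents of a sequence; whether they
# count as data is decided downstream (distance module treats them as missing).
NT_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N", "-", "?")
AA_CHARS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*", "-", "?")

alphabet_chars <- function(alphabet) {
  switch(match.arg(alphabet, c("nt", "aa")), nt = NT_CHARS, aa = AA_CHARS)
}

#' Create a sequence record
#'
#' A record is a taxon/clone label plus an aligned (or unaligned) sequence
#' over a declared alphabet. Sequences are stored uppercase; in nucleotide
#' input `U` is converted to `T` (GenBank mRNA entries use U).
#'
#' @param id Unique taxon/clone label (non-empty string).
#' @param sequence Sequence string; gaps `-` and missing `?`/`N`/`X` are kept.
#' @param alphabet `"nt"` or `"aa"`.
#' @param description Optional full header text.
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, sequence, alphabet = "nt", description = id) {
  alphabet <- match.arg(alphabet, c("nt", "aa"))
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("empty sequence for record '", id, "'")
  if (alphabet == "nt") sequence <- gsub("U", "T", sequence, fixed = TRUE)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), alphabet_chars(alphabet))
  if (length(bad) > 0L) {
    stop("illegal ", alphabet, " character(s) ", paste(bad, collapse = ", "),
         " in record '", id, "'")
  }
  structure(list(id = id, sequence = sequence, alphabet = alphabet,
                 description = description),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s [%s, %d sites]\n", x$id, x$alphabet,
              nchar(x$sequence)))
  invisible(x)
}

#' Read a FASTA file
#'
#' Parses FASTA into a list of [seq_record]s. Record ids are the first
#' whitespace-delimited header token; the full header is kept as the
#' description. Sequences are uppercased and validated against the declared
#' alphabet; format problems are reported with the offending line number.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nt"` or `"aa"`.
#' @return List of `seq_record`, in file order. An empty file gives `list()`.
#' @export
read_fasta <- function(path, alphabet = "nt") {
  alphabet <- match.arg(alphabet, c("nt", "aa"))
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(list())
  if (!startsWith(trimws(lines[nonblank[1L]]), ">")) {
    stop("FASTA format error at line ", nonblank[1L],
         ": sequence data before first header")
  }
  # seqinr does the actual parse; the line scan above and the per-record
  # validation below exist to localize errors.
  parsed <- seqinr::read.fasta(path, seqtype = if (alphabet == "nt") "DNA" else "AA",
                               as.string = TRUE, forceDNAtolower = FALSE,
                               whole.header = TRUE)
  headers <- vapply(parsed, function(s) attr(s, "Annot"), character(1L))
  ids <- sub("^>", "", headers)
  ids <- vapply(strsplit(trimws(ids), "\\s+"), `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  records <- vector("list", length(parsed))
  header_lines <- which(startsWith(trimws(lines), ">"))
  for (i in seq_along(parsed)) {
    rec <- tryCatch(
      seq_record(ids[[i]], as.character(parsed[[i]]), alphabet,
                 description = sub("^>\\s*", "", headers[[i]])),
      error = function(e) {
        stop("FASTA format error near line ", header_lines[[i]], ": ",
             conditionMessage(e), call. = FALSE)
      })
    records[[i]] <- rec
  }
  records
}

#' Write records to FASTA
#'
#' @param records List of [seq_record] or an [aligned_set].
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "aligned_set")) records <- records$records
  seqinr::write.fasta(
    sequences = lapply(records, function(r) r$sequence),
    names = vapply(records, function(r) r$id, character(1L)),
    file.out = path, as.string = TRUE, nbchar = width)
  invisible(path)
}

#' Build an aligned sequence set
#'
#' Container for fixed-length aligned homeobox fragments: all records must
#' share the same length L (the "number of sites" of a divergence analysis)
#' and the same alphabet.
#'
#' @param records Non-empty list of [seq_record].
#' @return An object of class `aligned_set` with elements `records`,
#'   `length` (L, in sites) and `alphabet`.
#' @export
build_aligned_set <- function(records) {
  if (length(records) == 0L) stop("cannot build an aligned set from 0 records")
  stopifnot(all(vapply(records, inherits, logical(1L), "seq_record")))
  ids <- vapply(records, function(r) r$id, character(1L))
  if (anyDuplicated(ids)) {
    stop("duplicate ids in aligned set: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  alphabets <- unique(vapply(records, function(r) r$alphabet, character(1L)))
  if (length(alphabets) > 1L) stop("mixed alphabets in aligned set")
  lens <- vapply(records, function(r) nchar(r$sequence), integer(1L))
  if (length(unique(lens)) > 1L) {
    off <- ids[lens != lens[[1L]]]
    stop("alignment length mismatch; offending ids: ",
         paste(off, collapse = ", "))
  }
  structure(list(records = records, length = lens[[1L]], alphabet = alphabets),
            class = "aligned_set")
}

#' @export
print.aligned_set <- function(x, ...) {
  cat(sprintf("<aligned_set> %d records x %d sites (%s)\n",
              length(x$records), x$length, x$alphabet))
  invisible(x)
}

#' @export
length.aligned_set <- function(x) length(x$records)

#' Taxon ids of an aligned set
#' @param x An [aligned_set].
#' @return Character vector of record ids, in order.
#' @export
set_ids <- function(x) vapply(x$records, function(r) r$id, character(1L))

#' Sequence character matrix of an aligned set
#' @param x An [aligned_set].
#' @return Character matrix, rows = taxa (named), columns = sites.
#' @export
as_char_matrix <- function(x) {
  stopifnot(inherits(x, "aligned_set"))
  m <- do.call(rbind, lapply(x$records,
                             function(r) strsplit(r$sequence, "")[[1L]]))
  rownames(m) <- set_ids(x)
  m
}

#' Read a taxon-to-group assignment table
#'
#' TSV with columns `taxon_id`, `group`, `super_label`; the super-label is the
#' binary insect / non-insect classification used by the rate comparison.
#'
#' @param path Path to the TSV.
#' @return An object of class `group_assignment`: a data.frame with those
#'   three columns, validated (unique taxa, known super-labels).
#' @export
read_group_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("taxon_id", "group", "super_label")
  if (!all(need %in% names(df))) {
    stop("group table must have columns: ", paste(need, collapse = ", "))
  }
  group_assignment(df$taxon_id, df$group, df$super_label)
}

#' Construct a group assignment
#'
#' @param taxon_id Character vector of taxon ids (unique).
#' @param group Group label per taxon (e.g. "Insecta", "Mammalia Hox-A").
#' @param super_label `"insect"` or `"non-insect"` per taxon.
#' @return A `group_assignment` data.frame.
#' @export
group_assignment <- function(taxon_id, group, super_label) {
  df <- data.frame(taxon_id = as.character(taxon_id),
                   group = as.character(group),
                   super_label = as.character(super_label),
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no groups: assignment table is empty")
  if (anyDuplicated(df$taxon_id)) {
    stop("taxon listed twice: ",
         paste(unique(df$taxon_id[duplicated(df$taxon_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(df$super_label), c("insect", "non-insect"))
  if (length(bad) > 0L) {
    stop("unknown super_label(s): ", paste(bad, collapse = ", "),
         " (expected 'insect' or 'non-insect')")
  }
  class(df) <- c("group_assignment", "data.frame")
  df
}

#' Members of a group
#' @param groups A `group_assignment`.
#' @param group_label Group to look up.
#' @return Character vector of taxon ids.
#' @export
group_members <- function(groups, group_label) {
  groups$taxon_id[groups$group == group_label]
}
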