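# Sequence records and FASTA I/O.
#
# All RNA is stored with U (any T on input is normalized); coordinates are
# 1-based throughout, as in the rest of the R ecosystem.

RNA_ALPHABET <- c("A", "C", "G", "U", "N")
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
EDITING_STATUSES <- c("pan_edited", "partially_edited", "nonedited", "unknown")

#' Create a coding-sequence record
#'
#' A `cds_record` holds one mitochondrial coding sequence (cryptogene or
#' edited mRNA) in the RNA alphabet, together with the metadata used by the
#' composition, walk and editing analyses.  Any `T` in `seq` is normalized
#' to `U`; characters outside `A`, `C`, `G`, `U`, `N` are rejected.
#'
#' @param id Record identifier.
#' @param seq RNA sequence (character scalar; `T` accepted and converted).
#' @param species,gene Metadata labels; default `"unknown"`.
#' @param frame_offset Number of bases (0--2) before the first full codon.
#' @param editing_status One of `"pan_edited"`, `"partially_edited"`,
#'   `"nonedited"`, `"unknown"`.
#' @return An object of class `cds_record`.
#' @examples
#' cds_record("x", "ATGTTA", species = "Tb", gene = "COX3")
#' @export
cds_record <- function(id, seq, species = "unknown", gene = "unknown",
                       frame_offset = 0L, editing_status = "unknown") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(seq), length(seq) == 1L)
  frame_offset <- as.integer(frame_offset)
  if (is.na(frame_offset) || frame_offset < 0L || frame_offset > 2L)
    stop("'frame_offset' must be 0, 1 or 2", call. = FALSE)
  editing_status <- match.arg(editing_status, EDITING_STATUSES)
  seq <- toupper(seq)
  seq <- gsub("T", "U", seq, fixed = TRUE)
  bad <- which(!strsplit(seq, "", fixed = TRUE)[[1]] %in% RNA_ALPHABET)
  if (length(bad))
    stop(sprintf("record '%s': illegal character '%s' at position %d",
                 id, substr(seq, bad[1], bad[1]), bad[1]), call. = FALSE)
  structure(list(id = id, species = species, gene = gene, seq = seq,
                 frame_offset = frame_offset,
                 editing_status = editing_status),
            class = "cds_record")
}

#' Create a protein record
#'
#' @param id Record identifier.
#' @param seq Amino acid sequence over the 20-letter alphabet plus `X`
#'   (unknown residue).
#' @param source_cds_id Optional id of the CDS this protein was translated
#'   from.
#' @return An object of class `protein_record`.
#' @export
protein_record <- function(id, seq, source_cds_id = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) < 1L)
    stop(sprintf("record '%s': empty protein sequence", id), call. = FALSE)
  bad <- which(!strsplit(seq, "", fixed = TRUE)[[1]] %in% c(AA_ALPHABET, "X"))
  if (length(bad))
    stop(sprintf("record '%s': illegal amino acid '%s' at position %d",
                 id, substr(seq, bad[1], bad[1]), bad[1]), call. = FALSE)
  structure(list(id = id, seq = seq, source_cds_id = source_cds_id),
            class = "protein_record")
}

#' @export
print.cds_record <- function(x, ...) {
  cat(sprintf("<cds_record> %s  %s/%s  %s  %d nt  frame %d\n",
              x$id, x$species, x$gene, x$editing_status,
              nchar(x$seq), x$frame_offset))
  invisible(x)
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s  %d aa\n", x$id, nchar(x$seq)))
  invisible(x)
}

# Split a record's sequence into single characters.
seq_chars <- function(record) strsplit(record$seq, "", fixed = TRUE)[[1]]

#' Read sequence records from a FASTA file
#'
#' Reads a (wrapped or unwrapped) multi-record FASTA file.  Headers in the
#' pipe-delimited dialect `id|species|gene|status` populate the record
#' metadata; any other header becomes the record id with metadata set to
#' `"unknown"`.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"rna"` for [cds_record()]s (T normalized to U) or
#'   `"protein"` for [protein_record()]s.
#' @return A list of `cds_record` or `protein_record` objects (empty list
#'   for an empty file).
#' @export
read_fasta <- function(path, alphabet = c("rna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop(sprintf("malformed FASTA '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  if (length(set) == 0L) return(list())
  headers <- names(set)
  seqs <- unname(as.character(set))
  lapply(seq_along(set), function(i) {
    fields <- strsplit(headers[i], "|", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    if (alphabet == "rna") {
      if (length(fields) == 4L && fields[4] %in% EDITING_STATUSES)
        cds_record(fields[1], seqs[i], species = fields[2], gene = fields[3],
                   editing_status = fields[4])
      else
        cds_record(fields[1], seqs[i])
    } else {
      protein_record(fields[1], seqs[i])
    }
  })
}

#' Write sequence records to a FASTA file
#'
#' CDS records are written with the pipe-delimited header
#' `id|species|gene|status`; protein records with the bare id.  A
#' read-write-read round trip preserves id and sequence exactly.
#'
#' @param records List of `cds_record` or `protein_record` objects.
#' @param path Output file path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    header <- if (inherits(rec, "cds_record"))
      paste(rec$id, rec$species, rec$gene, rec$editing_status, sep = "|")
    else rec$id
    writeLines(paste0(">", header), con)
    n <- nchar(rec$seq)
    starts <- seq(1L, n, by = width)
    writeLines(substring(rec$seq, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Codon-position index lists for a CDS
#'
#' Partitions the retained codon span of a record into the indices of the
#' first, second and third codon positions.  The span starts at
#' `frame_offset + 1` and ends at the last complete codon; a trailing
#' partial codon is dropped with a warning.
#'
#' @param record A [cds_record()].
#' @return A list with integer vectors `pos1`, `pos2`, `pos3` (1-based
#'   sequence indices).
#' @export
codon_position_indices <- function(record) {
  stopifnot(inherits(record, "cds_record"))
  len <- nchar(record$seq)
  start <- record$frame_offset + 1L
  n_codon <- (len - record$frame_offset) %/% 3L
  if (n_codon < 1L)
    stop(sprintf("record '%s': no complete codon after frame offset %d",
                 record$id, record$frame_offset), call. = FALSE)
  dropped <- len - record$frame_offset - 3L * n_codon
  if (dropped > 0L)
    warning(sprintf("record '%s': trailing partial codon of %d base(s) dropped",
                    record$id, dropped), call. = FALSE)
  first <- start + 3L * (seq_len(n_codon) - 1L)
  list(pos1 = first, pos2 = first + 1L, pos3 = first + 2L)
}

#' Export record metadata as a data frame
#'
#' @param records List of `cds_record` objects.
#' @return A data frame with one row per record (id, species, gene,
#'   editing status, length, frame offset).
#' @export
record_metadata <- function(records) {
  data.frame(
    id = vapply(records, `[[`, "", "id"),
    species = vapply(records, `[[`, "", "species"),
    gene = vapply(records, `[[`, "", "gene"),
    editing_status = vapply(records, `[[`, "", "editing_status"),
    length = vapply(records, function(r) nchar(r$seq), 0L),
    frame_offset = vapply(records, `[[`, 0L, "frame_offset"),
    stringsAsFactors = FALSE
  )
}
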