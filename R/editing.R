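# Inference of inserted/deleted Us from cryptogene / edited-mRNA pairs.
#
# The non-U characters of the two sequences are the anchors: U-insertion /
# U-deletion editing leaves them identical and in the same order, so the
# whole alignment problem reduces to comparing the U runs between
# consecutive anchors.

#' Align a cryptogene to its fully edited mRNA
#'
#' Matches the non-U characters of the two sequences one-to-one in order
#' (the anchors) and compares the U run between each pair of consecutive
#' anchors (including the runs before the first and after the last
#' anchor).  A run with more Us in the edited mRNA than in the cryptogene
#' contains insertions; the (rarer) converse contains deletions.  At most
#' one of the two can be nonzero per run, by construction.
#'
#' @param cryptogene,edited [cds_record()]s.  Removing every U from both
#'   must give identical strings; otherwise the pair is not explainable by
#'   U editing and an error reports the first mismatching anchor in both
#'   coordinate systems.
#' @return An object of class `editing_alignment`: `runs` (data frame with
#'   one row per anchor gap: `run`, `crypto_u`, `edited_u`, `n_inserted`,
#'   `n_deleted`, `edited_start`), `edited_u_positions` (list of the
#'   1-based edited-mRNA coordinates of the U slots in each run),
#'   `total_inserted`, `total_deleted`, and the two record ids.
#' @examples
#' crypto <- cds_record("c", "GAGGG")
#' edited <- cds_record("e", "GUAGUUGGG")
#' anchor_align(crypto, edited)
#' @export
anchor_align <- function(cryptogene, edited) {
  stopifnot(inherits(cryptogene, "cds_record"), inherits(edited, "cds_record"))
  cc <- seq_chars(cryptogene)
  ec <- seq_chars(edited)
  c_anchor <- which(cc != "U")
  e_anchor <- which(ec != "U")
  c_core <- cc[c_anchor]
  e_core <- ec[e_anchor]
  n_min <- min(length(c_core), length(e_core))
  mismatch <- which(c_core[seq_len(n_min)] != e_core[seq_len(n_min)])
  if (length(mismatch) || length(c_core) != length(e_core)) {
    k <- if (length(mismatch)) mismatch[1] else n_min + 1L
    cpos <- if (k <= length(c_anchor)) c_anchor[k] else nchar(cryptogene$seq) + 1L
    epos <- if (k <= length(e_anchor)) e_anchor[k] else nchar(edited$seq) + 1L
    stop(sprintf(paste0("editing-incompatible pair '%s' / '%s': non-U anchors ",
                        "differ at anchor %d (cryptogene position %d, ",
                        "edited position %d)"),
                 cryptogene$id, edited$id, k, cpos, epos), call. = FALSE)
  }
  n_anchor <- length(c_anchor)
  # run boundaries: gap g lies between anchor g-1 and anchor g (g = 1 is
  # the run before the first anchor, g = n_anchor + 1 the run after the last)
  run_u <- function(anchors, len) {
    bounds <- c(0L, anchors, len + 1L)
    starts <- bounds[seq_len(n_anchor + 1L)] + 1L
    ends <- bounds[-1L] - 1L
    list(starts = starts, counts = pmax(ends - starts + 1L, 0L))
  }
  cr <- run_u(c_anchor, length(cc))
  er <- run_u(e_anchor, length(ec))
  n_ins <- pmax(er$counts - cr$counts, 0L)
  n_del <- pmax(cr$counts - er$counts, 0L)
  edited_u_positions <- lapply(seq_len(n_anchor + 1L), function(g) {
    if (er$counts[g] == 0L) integer(0)
    else seq.int(er$starts[g], length.out = er$counts[g])
  })
  runs <- data.frame(run = seq_len(n_anchor + 1L),
                     crypto_u = cr$counts, edited_u = er$counts,
                     n_inserted = n_ins, n_deleted = n_del,
                     edited_start = er$starts)
  structure(list(cryptogene_id = cryptogene$id, edited_id = edited$id,
                 anchors = data.frame(crypto = c_anchor, edited = e_anchor),
                 runs = runs,
                 edited_u_positions = edited_u_positions,
                 edited_frame_offset = edited$frame_offset,
                 edited_length = length(ec),
                 total_inserted = sum(n_ins), total_deleted = sum(n_del)),
            class = "editing_alignment")
}

#' @export
print.editing_alignment <- function(x, ...) {
  cat(sprintf("<editing_alignment> %s -> %s: %d anchors, %d inserted U, %d deleted U\n",
              x$cryptogene_id, x$edited_id, nrow(x$anchors),
              x$total_inserted, x$total_deleted))
  invisible(x)
}

#' Codon-position counts of inserted Us
#'
#' Within each anchor gap the genomic (cryptogene-encoded) Us and the
#' inserted Us are indistinguishable from sequence alone; a placement
#' convention decides which edited-mRNA U slots count as inserted.  Under
#' `genomic_left` the genomic Us occupy the 5'-most slots of the run (so
#' insertions are the 3'-most slots); `genomic_right` is the mirror image.
#' Each inserted slot takes the codon position of its edited-mRNA
#' coordinate.
#'
#' @param alignment An [anchor_align()] result.
#' @param placement `"genomic_left"` (default) or `"genomic_right"`.
#' @return Integer vector of length 3: inserted-U counts at codon
#'   positions 1, 2, 3 of the edited mRNA (insertions landing beyond the
#'   last complete codon are ignored).
#' @export
inserted_by_codon_position <- function(alignment,
                                       placement = c("genomic_left",
                                                     "genomic_right")) {
  stopifnot(inherits(alignment, "editing_alignment"))
  placement <- match.arg(placement)
  frame <- alignment$edited_frame_offset
  n_codon <- (alignment$edited_length - frame) %/% 3L
  if (n_codon < 1L)
    stop("edited record has no complete codon in frame", call. = FALSE)
  span_end <- frame + 3L * n_codon
  counts <- c(0L, 0L, 0L)
  for (g in seq_len(nrow(alignment$runs))) {
    n_ins <- alignment$runs$n_inserted[g]
    if (n_ins == 0L) next
    slots <- alignment$edited_u_positions[[g]]
    ins_slots <- if (placement == "genomic_left")
      slots[seq.int(length(slots) - n_ins + 1L, length(slots))]
    else slots[seq_len(n_ins)]
    ins_slots <- ins_slots[ins_slots > frame & ins_slots <= span_end]
    if (!length(ins_slots)) next
    cp <- ((ins_slots - frame - 1L) %% 3L) + 1L
    counts <- counts + tabulate(cp, nbins = 3L)
  }
  counts
}

#' Chi-square test of homogeneity of inserted Us across codon positions
#'
#' Tests the inserted-U counts at the three codon positions against a
#' uniform expectation (equal site weights), on 2 degrees of freedom.
#'
#' @param counts Integer vector of 3 inserted-U counts.
#' @return A `test_result`; degenerate (statistic 0, p 1, flagged) when
#'   all counts are zero.
#' @export
inserted_homogeneity_test <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3L)
  res <- homogeneity_test(counts, site_counts = rep(max(sum(counts), 1), 3))
  res$test_name <- "inserted-U homogeneity across codon positions"
  res
}

#' Per-gene inserted-U report
#'
#' For each (cryptogene, edited) pair: inserted and total Us by codon
#' position of the edited CDS and the homogeneity p-value -- the
#' machine-readable version of an inserted-U survey, under both placement
#' conventions.
#'
#' @param pairs List of `list(cryptogene =, edited =)` pairs.
#' @return Data frame with one row per pair.
#' @export
editing_report <- function(pairs) {
  rows <- lapply(pairs, function(pr) {
    aln <- anchor_align(pr$cryptogene, pr$edited)
    ins_l <- inserted_by_codon_position(aln, "genomic_left")
    ins_r <- inserted_by_codon_position(aln, "genomic_right")
    tot <- u_content_by_position(pr$edited)
    ht <- inserted_homogeneity_test(ins_l)
    data.frame(gene = pr$edited$gene, edited_id = pr$edited$id,
               cryptogene_id = pr$cryptogene$id,
               inserted_pos1 = ins_l[1], inserted_pos2 = ins_l[2],
               inserted_pos3 = ins_l[3],
               inserted_pos1_right = ins_r[1], inserted_pos2_right = ins_r[2],
               inserted_pos3_right = ins_r[3],
               total_u_pos1 = tot$u_counts[1], total_u_pos2 = tot$u_counts[2],
               total_u_pos3 = tot$u_counts[3],
               total_inserted = aln$total_inserted,
               total_deleted = aln$total_deleted,
               homogeneity_p = ht$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
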