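# Cumulative +/-1 nucleotide walks and cumulative hydropathy profiles.

#' Kyte-Doolittle hydropathy scale
#'
#' The standard per-residue hydropathy index; positive values are
#' hydrophobic.  The unknown residue `X` contributes 0 wherever the scale
#' is applied.
#'
#' @format Named numeric vector over the 20 amino acids.
#' @export
kyte_doolittle <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Cumulative nucleotide walk
#'
#' Walks along a sequence adding +1 at every occurrence of `target` and -1
#' at every other base (including `N`), so that a positive slope marks a
#' region enriched in the target base.  The walk can be restricted to one
#' codon position, in which case only the bases at that position (in
#' ascending order) are stepped over; the reported `positions_used` are the
#' absolute 1-based coordinates, so per-position walks can be plotted
#' against mRNA position.
#'
#' @param record A [cds_record()].
#' @param target Target base (default `"U"`).
#' @param codon_position Optional codon position (1, 2 or 3) to restrict
#'   the walk to.
#' @return An object of class `walk_series` with elements `target`,
#'   `positions_used` (absolute coordinates), `s` (cumulative walk values,
#'   same length), `codon_position` and `sequence_id`.
#' @export
nucleotide_walk <- function(record, target = "U", codon_position = NULL) {
  stopifnot(inherits(record, "cds_record"))
  if (!is.character(target) || length(target) != 1L ||
      !target %in% RNA_ALPHABET)
    stop("'target' must be one of A, C, G, U, N", call. = FALSE)
  chars <- seq_chars(record)
  if (is.null(codon_position)) {
    positions <- seq_along(chars)
  } else {
    if (!codon_position %in% 1:3)
      stop("'codon_position' must be 1, 2 or 3", call. = FALSE)
    positions <- codon_position_indices(record)[[codon_position]]
  }
  x <- ifelse(chars[positions] == target, 1L, -1L)
  structure(list(target = target,
                 positions_used = positions,
                 s = cumsum(x),
                 codon_position = codon_position,
                 sequence_id = record$id),
            class = "walk_series")
}

#' @export
print.walk_series <- function(x, ...) {
  cat(sprintf("<walk_series> %s  target %s%s  n=%d  final=%d\n",
              x$sequence_id, x$target,
              if (is.null(x$codon_position)) ""
              else sprintf("  codon position %d", x$codon_position),
              length(x$s), if (length(x$s)) x$s[length(x$s)] else 0L))
  invisible(x)
}

#' Export a walk series as a data frame
#'
#' @param walk A `walk_series`.
#' @return Data frame with columns `rank` (step number within the walk),
#'   `position` (absolute 1-based mRNA coordinate) and `s`.
#' @export
walk_as_data_frame <- function(walk) {
  stopifnot(inherits(walk, "walk_series"))
  data.frame(rank = seq_along(walk$s), position = walk$positions_used,
             s = walk$s)
}

#' Cumulative Kyte-Doolittle hydropathy profile
#'
#' Per-residue Kyte-Doolittle scores and their running sum, with an mRNA
#' coordinate per residue (first base of the codon, `3*(i-1) + 1`) so that
#' hydropathy profiles can be drawn on the same axis as nucleotide walks.
#' `X` residues contribute 0.
#'
#' @param protein A [protein_record()].
#' @return An object of class `hydropathy_profile` with `residue_scores`,
#'   `cumulative` and `mrna_coordinates` (all of protein length).
#' @export
cumulative_hydropathy <- function(protein) {
  stopifnot(inherits(protein, "protein_record"))
  chars <- strsplit(protein$seq, "", fixed = TRUE)[[1]]
  scores <- unname(kyte_doolittle[chars])
  scores[is.na(scores)] <- 0          # X
  structure(list(residue_scores = scores,
                 cumulative = cumsum(scores),
                 mrna_coordinates = 3L * (seq_along(scores) - 1L) + 1L,
                 sequence_id = protein$id),
            class = "hydropathy_profile")
}

#' @export
print.hydropathy_profile <- function(x, ...) {
  cat(sprintf("<hydropathy_profile> %s  %d residues  cumulative end %.1f\n",
              x$sequence_id, length(x$cumulative),
              x$cumulative[length(x$cumulative)]))
  invisible(x)
}
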