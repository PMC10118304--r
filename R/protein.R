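# Translation, hydrophobic / order-disorder composition, hydrophobic
# surveys and coevolution-matrix pair summaries.

#' Hydrophobic amino acid set
#'
#' F, L, I, V, M, W and Y -- the set used for hydrophobic fractions,
#' cluster analysis and coevolving-pair classification.
#' @export
HYDROPHOBIC_SET <- c("F", "L", "I", "V", "M", "W", "Y")

#' Default order/disorder classification of amino acids
#'
#' Order-promoting residues are common in regular secondary structure (C
#' is included because it forms disulfide bonds); disorder-promoting
#' residues are typical of unstructured regions; the rest are ambiguous.
#' @format Named list with character vectors `order`, `disorder`,
#'   `ambiguous`.
#' @export
ORDER_DISORDER_CLASSES <- list(
  order = c("W", "C", "F", "I", "Y", "V", "L", "N"),
  disorder = c("A", "R", "G", "Q", "S", "P", "E", "K"),
  ambiguous = c("D", "H", "M", "T")
)

#' Translate a CDS
#'
#' Codon-by-codon translation of the retained codon span under a genetic
#' code table.  Default table 4 (mold/protozoan/coelenterate
#' mitochondrial), in which UGA codes for tryptophan, as in kinetoplastid
#' mitochondria.  Codons containing `N` translate to `X`; a terminal stop
#' codon is dropped; an internal stop is an error unless
#' `allow_internal_stops` is set, in which case it becomes `X`.
#'
#' @param record A [cds_record()].
#' @param code_table Genetic code id as understood by
#'   [Biostrings::getGeneticCode()] (default `"4"`).
#' @param allow_internal_stops Translate internal stops as `X` instead of
#'   erroring.
#' @return A [protein_record()] with `source_cds_id` set.
#' @export
translate_cds <- function(record, code_table = "4",
                          allow_internal_stops = FALSE) {
  stopifnot(inherits(record, "cds_record"))
  code <- Biostrings::getGeneticCode(as.character(code_table))
  idx <- codon_position_indices(record)
  chars <- seq_chars(record)
  codons <- paste0(chars[idx$pos1], chars[idx$pos2], chars[idx$pos3])
  dna <- gsub("U", "T", codons, fixed = TRUE)
  aa <- unname(code[dna])
  aa[grepl("N", codons, fixed = TRUE)] <- "X"
  stops <- which(aa == "*")
  if (length(stops)) {
    if (stops[length(stops)] == length(aa)) {
      aa <- aa[-length(aa)]
      stops <- stops[-length(stops)]
    }
    if (length(stops)) {
      if (!allow_internal_stops)
        stop(sprintf("record '%s': internal stop codon at codon %d",
                     record$id, stops[1]), call. = FALSE)
      aa[stops] <- "X"
    }
  }
  protein_record(paste0(record$id, "_aa"), paste(aa, collapse = ""),
                 source_cds_id = record$id)
}

#' Hydrophobic fraction of a protein
#'
#' Fraction of residues belonging to the hydrophobic set; `X` residues are
#' excluded from the denominator.
#'
#' @param protein A [protein_record()].
#' @param hydrophobic_set Character vector of hydrophobic residues
#'   (default [HYDROPHOBIC_SET]).
#' @return A fraction in `[0, 1]`.
#' @export
hydrophobic_fraction <- function(protein, hydrophobic_set = HYDROPHOBIC_SET) {
  stopifnot(inherits(protein, "protein_record"))
  chars <- strsplit(protein$seq, "", fixed = TRUE)[[1]]
  known <- chars != "X"
  if (!any(known))
    stop(sprintf("record '%s': all residues unknown", protein$id),
         call. = FALSE)
  sum(chars[known] %in% hydrophobic_set) / sum(known)
}

#' Rank proteins by hydrophobic fraction
#'
#' Computes the hydrophobic fraction of every protein, the mean and SD
#' over the set, and dense descending ranks (ties share a rank).
#'
#' @param proteins List of at least two [protein_record()]s with unique
#'   ids.
#' @param queries Optional ids to report in `query_ranks`.
#' @param hydrophobic_set Hydrophobic residue set.
#' @return An object of class `survey_ranking`: data frame `table` (id,
#'   fraction, rank), `mean`, `sd`, and named `query_ranks`.
#' @export
survey_rank <- function(proteins, queries = NULL,
                        hydrophobic_set = HYDROPHOBIC_SET) {
  if (length(proteins) < 2L)
    stop("at least two proteins are required", call. = FALSE)
  ids <- vapply(proteins, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate protein id '%s'", ids[duplicated(ids)][1]),
         call. = FALSE)
  frac <- vapply(proteins, hydrophobic_fraction, 0,
                 hydrophobic_set = hydrophobic_set)
  rank_of <- match(frac, sort(unique(frac), decreasing = TRUE))
  tab <- data.frame(id = ids, fraction = frac, rank = rank_of,
                    stringsAsFactors = FALSE)
  query_ranks <- NULL
  if (!is.null(queries)) {
    missing <- setdiff(queries, ids)
    if (length(missing))
      stop(sprintf("query id '%s' not in the protein set", missing[1]),
           call. = FALSE)
    query_ranks <- stats::setNames(rank_of[match(queries, ids)], queries)
  }
  structure(list(table = tab, mean = mean(frac), sd = stats::sd(frac),
                 query_ranks = query_ranks),
            class = "survey_ranking")
}

#' @export
print.survey_ranking <- function(x, ...) {
  cat(sprintf("<survey_ranking> %d proteins  mean %.3f +/- %.3f\n",
              nrow(x$table), x$mean, x$sd))
  if (!is.null(x$query_ranks))
    for (q in names(x$query_ranks))
      cat(sprintf("  %s: fraction %.3f, rank %d\n", q,
                  x$table$fraction[x$table$id == q], x$query_ranks[[q]]))
  invisible(x)
}

#' Amino acid composition by order/disorder class
#'
#' Per-letter frequencies over the 20 standard amino acids (summing to 1;
#' `X` excluded and reported separately) and class totals under a
#' classification map.
#'
#' @param protein A [protein_record()].
#' @param classification Named list of character vectors covering all 20
#'   amino acids (default [ORDER_DISORDER_CLASSES]).
#' @param hydrophobic_set Set used for the additional `hydrophobic` total.
#' @return An object of class `composition_table` with `frequencies`
#'   (named, 20 letters), `class_totals`, `hydrophobic_total`,
#'   `x_fraction` and `n_residues`.
#' @export
composition_by_class <- function(protein,
                                 classification = ORDER_DISORDER_CLASSES,
                                 hydrophobic_set = HYDROPHOBIC_SET) {
  stopifnot(inherits(protein, "protein_record"))
  if (length(classification) == 0L)
    stop("empty classification", call. = FALSE)
  covered <- sort(unique(unlist(classification)))
  if (!setequal(covered, AA_ALPHABET))
    stop("classification must cover exactly the 20 standard amino acids",
         call. = FALSE)
  chars <- strsplit(protein$seq, "", fixed = TRUE)[[1]]
  unknown <- setdiff(chars, c(AA_ALPHABET, "X"))
  if (length(unknown))
    stop(sprintf("unknown letter '%s'", unknown[1]), call. = FALSE)
  known <- chars[chars != "X"]
  if (!length(known))
    stop(sprintf("record '%s': all residues unknown", protein$id),
         call. = FALSE)
  counts <- table(factor(known, levels = AA_ALPHABET))
  freq <- as.numeric(counts) / length(known)
  names(freq) <- AA_ALPHABET
  class_totals <- vapply(classification,
                         function(members) sum(freq[members]), 0)
  structure(list(frequencies = freq,
                 class_totals = class_totals,
                 hydrophobic_total = sum(freq[hydrophobic_set]),
                 x_fraction = mean(chars == "X"),
                 n_residues = length(chars)),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat(sprintf("<composition_table> %d residues  %s  hydrophobic %.3f\n",
              x$n_residues,
              paste(sprintf("%s %.3f", names(x$class_totals),
                            x$class_totals), collapse = "  "),
              x$hydrophobic_total))
  invisible(x)
}

#' Summarize short-range coevolving site pairs
#'
#' Counts the unordered site pairs `(i, j)` with `i < j`, sequence
#' separation `j - i <= max_dist` and coevolution score strictly above
#' `threshold`, and the fraction of those pairs in which both residues are
#' hydrophobic.
#'
#' @param matrix Square symmetric score matrix, one row/column per
#'   residue.
#' @param protein The [protein_record()] the matrix refers to (length must
#'   equal the matrix dimension).
#' @param threshold Score threshold (strict `>`; default 0.8).
#' @param max_dist Maximum sequence separation (inclusive; default 5).
#' @param hydrophobic_set Hydrophobic residue set.
#' @return An object of class `coevolution_summary` with `n_pairs`,
#'   `hydrophobic_pair_fraction` (`NA` when no pair qualifies), and the
#'   data frame `pairs`.
#' @export
coevolution_pair_summary <- function(matrix, protein, threshold = 0.8,
                                     max_dist = 5L,
                                     hydrophobic_set = HYDROPHOBIC_SET) {
  stopifnot(inherits(protein, "protein_record"))
  matrix <- as.matrix(matrix)
  n <- nchar(protein$seq)
  if (nrow(matrix) != n || ncol(matrix) != n)
    stop(sprintf("matrix is %dx%d but protein has %d residues",
                 nrow(matrix), ncol(matrix), n), call. = FALSE)
  if (max(abs(matrix - t(matrix))) > 1e-6)
    stop("score matrix is not symmetric", call. = FALSE)
  chars <- strsplit(protein$seq, "", fixed = TRUE)[[1]]
  i <- rep(seq_len(n), times = n)
  j <- rep(seq_len(n), each = n)
  keep <- i < j & (j - i) <= max_dist & matrix[cbind(i, j)] > threshold
  pi <- i[keep]; pj <- j[keep]
  both_h <- chars[pi] %in% hydrophobic_set & chars[pj] %in% hydrophobic_set
  pairs <- data.frame(i = pi, j = pj, score = matrix[cbind(pi, pj)],
                      both_hydrophobic = both_h)
  structure(list(n_pairs = length(pi),
                 hydrophobic_pair_fraction =
                   if (length(pi)) mean(both_h) else NA_real_,
                 threshold = threshold, max_dist = max_dist,
                 pairs = pairs),
            class = "coevolution_summary")
}

#' @export
print.coevolution_summary <- function(x, ...) {
  cat(sprintf("<coevolution_summary> %d pairs (score > %g, separation <= %d)%s\n",
              x$n_pairs, x$threshold, x$max_dist,
              if (is.na(x$hydrophobic_pair_fraction)) ""
              else sprintf("; %.0f%% both hydrophobic",
                           100 * x$hydrophobic_pair_fraction)))
  invisible(x)
}

#' Read a coevolution score matrix
#'
#' Whitespace-delimited numeric text, one matrix row per line.
#'
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_score_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}
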