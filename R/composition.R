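# Codon-position U-content statistics and chi-square tests.

#' Construct a chi-square test result
#'
#' Internal container shared by all tests in the package.
#'
#' @param statistic Chi-square statistic.
#' @param df Degrees of freedom.
#' @param p P-value.
#' @param observed,expected Count tables the statistic was computed from.
#' @param test_name Human-readable test label.
#' @param degenerate Flag for degenerate inputs (e.g. no target counts).
#' @return An object of class `test_result`.
#' @keywords internal
test_result <- function(statistic, df, p, observed, expected, test_name,
                        degenerate = FALSE) {
  structure(list(statistic = statistic, df = df, p = p,
                 observed = observed, expected = expected,
                 test_name = test_name, degenerate = degenerate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: X-squared = %.4g, df = %d, p = %.4g%s%s\n",
              x$test_name, x$statistic, x$df, x$p,
              if (nzchar(significance_stars(x$p)))
                paste0(" ", significance_stars(x$p)) else "",
              if (isTRUE(x$degenerate)) "  [degenerate]" else ""))
  invisible(x)
}

#' Significance stars for a p-value
#'
#' `*` for p < 0.05, `**` for p < 0.01, `***` for p < 0.001, `""` otherwise.
#'
#' @param p P-value(s).
#' @return Character vector of stars.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) "" else if (pi < 0.001) "***"
    else if (pi < 0.01) "**" else if (pi < 0.05) "*" else ""
  }, "")
}

#' U content by codon position
#'
#' Counts the sites and the U occurrences at each codon position over the
#' retained codon span.  `N` sites count as sites but never as U.
#'
#' @param record A [cds_record()].
#' @param target Base to count (default `"U"`).
#' @return An object of class `position_counts` with integer vectors
#'   `u_counts`, `site_counts` (length 3) and numeric `proportions`.
#' @export
u_content_by_position <- function(record, target = "U") {
  stopifnot(inherits(record, "cds_record"))
  idx <- codon_position_indices(record)
  chars <- seq_chars(record)
  u_counts <- vapply(idx, function(i) sum(chars[i] == target), 0L)
  site_counts <- vapply(idx, length, 0L)
  structure(list(u_counts = unname(u_counts),
                 site_counts = unname(site_counts),
                 proportions = unname(u_counts / site_counts),
                 target = target),
            class = "position_counts")
}

#' @export
print.position_counts <- function(x, ...) {
  cat(sprintf("<position_counts> %s: %d/%d  %d/%d  %d/%d (%.3f %.3f %.3f)\n",
              x$target, x$u_counts[1], x$site_counts[1], x$u_counts[2],
              x$site_counts[2], x$u_counts[3], x$site_counts[3],
              x$proportions[1], x$proportions[2], x$proportions[3]))
  invisible(x)
}

#' Standard deviation of windowed U proportions
#'
#' Cuts the sequence into consecutive non-overlapping windows (default 30
#' bases, the trailing remainder dropped), computes the U proportion in
#' each window and returns the population standard deviation across
#' windows -- both overall and stratified by codon position (windows are
#' cut on the raw sequence; within each window the bases belonging to each
#' codon position contribute to that position's proportion).
#'
#' @param record A [cds_record()].
#' @param window Window size in bases (default 30; must be >= 3).
#' @param target Base whose proportion is tracked (default `"U"`).
#' @return A list with `overall` (SD of whole-window proportions),
#'   `by_position` (length-3 SD vector), `n_windows` and the per-window
#'   proportions in `window_proportions`.
#' @export
windowed_u_sd <- function(record, window = 30L, target = "U") {
  stopifnot(inherits(record, "cds_record"))
  window <- as.integer(window)
  if (is.na(window) || window < 3L)
    stop("'window' must be an integer >= 3", call. = FALSE)
  len <- nchar(record$seq)
  if (len < window)
    stop(sprintf("record '%s': sequence (%d nt) shorter than window (%d)",
                 record$id, len, window), call. = FALSE)
  n_win <- len %/% window
  if (len %% window != 0L)
    warning(sprintf("record '%s': trailing %d base(s) beyond the last full window dropped",
                    record$id, len %% window), call. = FALSE)
  chars <- seq_chars(record)
  win_id <- rep(seq_len(n_win), each = window)
  used <- seq_len(n_win * window)
  is_u <- chars[used] == target
  prop <- tapply(is_u, win_id, mean)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  # codon-position strata within each window (any partial-codon condition
  # is already covered by the window-remainder warning above)
  idx <- suppressWarnings(codon_position_indices(record))
  by_pos <- vapply(1:3, function(cp) {
    in_pos <- intersect(idx[[cp]], used)
    props <- tapply(chars[in_pos] == target,
                    ((in_pos - 1L) %/% window) + 1L, mean)
    pop_sd(as.numeric(props))
  }, 0)
  list(overall = pop_sd(as.numeric(prop)),
       by_position = by_pos,
       n_windows = n_win,
       window_proportions = as.numeric(prop))
}

#' Chi-square test of homogeneous U distribution across codon positions
#'
#' Goodness-of-fit test of the null hypothesis that U occurrences are
#' distributed over the three codon positions proportionally to the number
#' of sites in each position (equal thirds when the retained span is a
#' multiple of 3).  With 2 degrees of freedom the p-value has the closed
#' form `exp(-statistic / 2)`.
#'
#' @param u_counts Either a `position_counts` object or an integer vector
#'   of 3 U counts.
#' @param site_counts Integer vector of 3 site totals (ignored when
#'   `u_counts` is a `position_counts`).
#' @return A `test_result` with `df = 2`.  When the total U count is zero
#'   the result is degenerate (`statistic = 0`, `p = 1`, flagged).
#' @export
homogeneity_test <- function(u_counts, site_counts = NULL) {
  if (inherits(u_counts, "position_counts")) {
    site_counts <- u_counts$site_counts
    u_counts <- u_counts$u_counts
  }
  u_counts <- as.numeric(u_counts)
  site_counts <- as.numeric(site_counts)
  stopifnot(length(u_counts) == 3L, length(site_counts) == 3L)
  if (any(site_counts <= 0))
    stop("all site totals must be positive", call. = FALSE)
  if (any(u_counts > site_counts))
    stop("U counts cannot exceed site totals", call. = FALSE)
  total <- sum(u_counts)
  expected <- total * site_counts / sum(site_counts)
  if (total == 0)
    return(test_result(0, 2L, 1, u_counts, expected,
                       "U homogeneity across codon positions",
                       degenerate = TRUE))
  stat <- sum((u_counts - expected)^2 / expected)
  test_result(stat, 2L, stats::pchisq(stat, df = 2L, lower.tail = FALSE),
              u_counts, expected, "U homogeneity across codon positions")
}

# 2x2 chi-square without continuity correction, shared by the species
# comparison and the structure-stratum comparisons.
chisq_2x2 <- function(tab, test_name) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop(sprintf("%s: degenerate 2x2 table (zero marginal)", test_name),
         call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  test_result(stat, 1L, stats::pchisq(stat, df = 1L, lower.tail = FALSE),
              tab, expected, test_name)
}

#' Chi-square comparison of U proportions between two species
#'
#' Compares the whole-CDS U content of two records (2x2 table of U
#' vs. non-U by species) with a chi-square test on one degree of freedom,
#' without continuity correction.  Significance stars are attached via
#' [significance_stars()].  The test is symmetric in its arguments.
#'
#' @param record_a,record_b [cds_record()]s (no alignment required).
#' @param target Base compared (default `"U"`).
#' @return A `test_result` with an additional `stars` element.
#' @export
species_vs_reference_test <- function(record_a, record_b, target = "U") {
  stopifnot(inherits(record_a, "cds_record"), inherits(record_b, "cds_record"))
  count <- function(r) {
    chars <- seq_chars(r)
    n_u <- sum(chars == target)
    c(n_u, length(chars) - n_u)
  }
  tab <- rbind(count(record_a), count(record_b))
  dimnames(tab) <- list(c(record_a$id, record_b$id),
                        c(target, paste0("non-", target)))
  res <- chisq_2x2(tab, sprintf("U proportion: %s vs %s",
                                record_a$id, record_b$id))
  res$stars <- significance_stars(res$p)
  res
}

#' Per-gene composition report
#'
#' The machine-readable version of a U-content survey: for each record,
#' the whole-CDS U proportion, its windowed SD, the per-position
#' proportions, the homogeneity test, and (when a reference id is given)
#' the chi-square comparison against the reference record with stars.
#'
#' @param records List of [cds_record()]s.
#' @param reference_id Optional id of the reference record for pairwise
#'   comparisons.
#' @param window Window size for the SD (default 30).
#' @return A data frame with one row per record.
#' @export
composition_report <- function(records, reference_id = NULL, window = 30L) {
  ref <- NULL
  if (!is.null(reference_id)) {
    hit <- which(vapply(records, `[[`, "", "id") == reference_id)
    if (length(hit) != 1L)
      stop(sprintf("reference id '%s' not found exactly once", reference_id),
           call. = FALSE)
    ref <- records[[hit]]
  }
  rows <- lapply(records, function(rec) {
    pc <- u_content_by_position(rec)
    ht <- homogeneity_test(pc)
    sdres <- windowed_u_sd(rec, window = window)
    row <- data.frame(
      id = rec$id, species = rec$species, gene = rec$gene,
      u_proportion = sum(pc$u_counts) / sum(pc$site_counts),
      u_sd_window = sdres$overall,
      u_pos1 = pc$proportions[1], u_pos2 = pc$proportions[2],
      u_pos3 = pc$proportions[3],
      homogeneity_chisq = ht$statistic, homogeneity_p = ht$p,
      stringsAsFactors = FALSE
    )
    if (!is.null(ref) && rec$id != ref$id) {
      st <- species_vs_reference_test(rec, ref)
      row$vs_reference_chisq <- st$statistic
      row$vs_reference_p <- st$p
      row$vs_reference_stars <- st$stars
    } else if (!is.null(ref)) {
      row$vs_reference_chisq <- NA_real_
      row$vs_reference_p <- NA_real_
      row$vs_reference_stars <- ""
    }
    row
  })
  do.call(rbind, rows)
}
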