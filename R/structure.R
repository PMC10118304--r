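# Solvent-accessible surface area (Shrake-Rupley), exposure and interface
# classification, and site-wise hydrophobicity comparisons between aligned
# homologs.

#' Element radii used for SASA (Angstrom)
#' @export
ELEMENT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

#' Maximum accessible surface area per residue type (Angstrom^2)
#'
#' Theoretical maxima (Tien et al. 2013) used to normalize absolute SASA
#' into relative SASA.
#' @export
MAX_ASA <- c(ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0,
             CYS = 167.0, GLN = 225.0, GLU = 223.0, GLY = 104.0,
             HIS = 224.0, ILE = 197.0, LEU = 201.0, LYS = 236.0,
             MET = 224.0, PHE = 240.0, PRO = 159.0, SER = 155.0,
             THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

AA_321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Build a structure model from an atom table
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resid`
#'   (3-letter code), `elety`, `element`, `x`, `y`, `z` and optionally
#'   `radius` (assigned from [ELEMENT_RADII] when absent).
#' @param default_radius Radius for elements not in [ELEMENT_RADII]
#'   (warns when used).
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, default_radius = 1.70) {
  needed <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z")
  missing <- setdiff(needed, names(atoms))
  if (length(missing))
    stop(sprintf("atom table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (nrow(atoms) == 0L) stop("empty atom table", call. = FALSE)
  if (is.null(atoms$radius)) {
    atoms$radius <- unname(ELEMENT_RADII[atoms$element])
    unknown <- unique(atoms$element[is.na(atoms$radius)])
    if (length(unknown)) {
      warning(sprintf("element(s) %s not in radius table; using default %.2f A",
                      paste(unknown, collapse = ", "), default_radius),
              call. = FALSE)
      atoms$radius[is.na(atoms$radius)] <- default_radius
    }
  }
  if (any(atoms$radius <= 0)) stop("atom radii must be positive", call. = FALSE)
  atoms$aa1 <- unname(AA_321[atoms$resid])
  structure(list(atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  res <- unique(paste(x$atoms$chain, x$atoms$resno))
  cat(sprintf("<structure_model> %d atom(s), %d residue(s), chain(s) %s\n",
              nrow(x$atoms), length(res),
              paste(sort(unique(x$atoms$chain)), collapse = ", ")))
  invisible(x)
}

#' Read a structure from a PDB or mmCIF file
#'
#' Wraps [bio3d::read.pdb()] / [bio3d::read.cif()], keeps protein `ATOM`
#' records (waters and other heteroatoms are skipped unless
#' `keep_hetero`), drops hydrogens, and assigns element-based radii.
#'
#' @param path Path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param keep_hetero Keep non-water HETATM records.
#' @param default_radius Radius for unknown elements.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, keep_hetero = FALSE, default_radius = 1.70) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  pdb <- if (is_cif) bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- pdb$atom
  keep <- at$type == "ATOM"
  if (keep_hetero) keep <- keep | (at$type == "HETATM" & at$resid != "HOH")
  at <- at[keep, , drop = FALSE]
  element <- at$elesy
  if (is.null(element) || all(is.na(element)) || all(element == ""))
    element <- substr(gsub("[^A-Za-z].*", "", at$elety), 1L, 1L)
  at <- at[toupper(element) != "H", , drop = FALSE]
  element <- toupper(element[toupper(element) != "H"])
  if (nrow(at) == 0L) stop(sprintf("no usable atoms in %s", path), call. = FALSE)
  structure_model(data.frame(chain = at$chain, resno = at$resno,
                             resid = at$resid, elety = at$elety,
                             element = element,
                             x = at$x, y = at$y, z = at$z,
                             stringsAsFactors = FALSE),
                  default_radius = default_radius)
}

# Evenly distributed points on the unit sphere (Fibonacci spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  y <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - y^2, 0))
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  cbind(r * cos(phi), y, r * sin(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the structure by sampling `n_points` evenly
#' distributed points on each atom's extended sphere (radius + probe); a
#' point is accessible when it lies outside every other atom's extended
#' sphere.  Residue SASA is the sum over its atoms; relative SASA divides
#' by the residue-type maximum in [MAX_ASA].
#'
#' @param model A [structure_model()].
#' @param probe Probe radius in Angstrom (default 1.4).
#' @param n_points Sphere sample points per atom (default 960; must be
#'   >= 10).
#' @param exposure_threshold Relative SASA above which a residue is
#'   flagged exposed (strict `>`; default 0.30).
#' @return An object of class `sasa_result`: `residues` data frame
#'   (`chain`, `resno`, `resid`, `aa1`, `sasa`, `rel_sasa`, `exposed`),
#'   `atom_sasa` vector, `total` and the parameters used.
#' @export
sasa <- function(model, probe = 1.4, n_points = 960L,
                 exposure_threshold = 0.30) {
  stopifnot(inherits(model, "structure_model"))
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 10L)
    stop("'n_points' must be at least 10", call. = FALSE)
  at <- model$atoms
  n <- nrow(at)
  xyz <- cbind(at$x, at$y, at$z)
  ext <- at$radius + probe
  pts <- sphere_points(n_points)
  atom_sasa <- numeric(n)
  # neighbor search on squared distances
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (ext[i] + ext)^2 & seq_len(n) != i)
    if (!length(nb)) {
      atom_sasa[i] <- 4 * pi * ext[i]^2
      next
    }
    p <- pts * ext[i]
    p[, 1] <- p[, 1] + xyz[i, 1]
    p[, 2] <- p[, 2] + xyz[i, 2]
    p[, 3] <- p[, 3] + xyz[i, 3]
    free <- rep(TRUE, n_points)
    for (j in nb) {
      idx <- which(free)
      if (!length(idx)) break
      dj2 <- (p[idx, 1] - xyz[j, 1])^2 + (p[idx, 2] - xyz[j, 2])^2 +
        (p[idx, 3] - xyz[j, 3])^2
      free[idx[dj2 < ext[j]^2]] <- FALSE
    }
    atom_sasa[i] <- 4 * pi * ext[i]^2 * sum(free) / n_points
  }
  key <- paste(at$chain, at$resno, sep = "\r")
  agg <- rowsum(atom_sasa, key, reorder = FALSE)
  first <- !duplicated(key)
  residues <- data.frame(chain = at$chain[first], resno = at$resno[first],
                         resid = at$resid[first], aa1 = at$aa1[first],
                         sasa = agg[match(key[first], rownames(agg)), 1],
                         stringsAsFactors = FALSE)
  residues$rel_sasa <- residues$sasa / unname(MAX_ASA[residues$resid])
  residues$exposed <- !is.na(residues$rel_sasa) &
    residues$rel_sasa > exposure_threshold
  rownames(residues) <- NULL
  structure(list(residues = residues, atom_sasa = atom_sasa,
                 total = sum(atom_sasa), probe = probe,
                 n_points = n_points,
                 exposure_threshold = exposure_threshold),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> %d residue(s), total %.1f A^2, %d exposed (> %.0f%%)\n",
              nrow(x$residues), x$total, sum(x$residues$exposed),
              100 * x$exposure_threshold))
  invisible(x)
}

#' Exposure flags for a SASA result
#'
#' A residue is exposed when its relative SASA is strictly above the
#' threshold (default 0.30).
#'
#' @param sasa_result A [sasa()] result.
#' @param threshold Relative-SASA threshold (strict `>`).
#' @return Logical vector, one flag per residue.
#' @export
classify_exposure <- function(sasa_result, threshold = 0.30) {
  stopifnot(inherits(sasa_result, "sasa_result"))
  res <- sasa_result$residues
  bad <- which(is.na(res$rel_sasa))
  if (length(bad))
    stop(sprintf("residue type '%s' (chain %s, residue %s) has no max-ASA reference",
                 res$resid[bad[1]], res$chain[bad[1]], res$resno[bad[1]]),
         call. = FALSE)
  res$rel_sasa > threshold
}

subset_chain <- function(model, chains) {
  at <- model$atoms[model$atoms$chain %in% chains, , drop = FALSE]
  if (nrow(at) == 0L)
    stop(sprintf("chain(s) %s not present", paste(chains, collapse = ", ")),
         call. = FALSE)
  structure(list(atoms = at), class = "structure_model")
}

#' Interface residues by SASA reduction
#'
#' Computes each chain's SASA in isolation and in the two-chain complex;
#' a residue whose SASA drops by more than `eps` upon complex formation
#' lies at the contact surface.  The small `eps` (default 0.1 A^2) guards
#' against point-sampling noise.
#'
#' @param model A [structure_model()] containing both chains.
#' @param chain_a,chain_b Distinct chain identifiers.
#' @param probe,n_points SASA parameters (see [sasa()]).
#' @param eps Minimum SASA reduction (A^2) to flag a residue.
#' @return An object of class `interface_map`: list with per-chain data
#'   frames (`resno`, `resid`, `sasa_alone`, `sasa_complex`, `delta_sasa`,
#'   `interface`).
#' @export
interface_sites <- function(model, chain_a, chain_b, probe = 1.4,
                            n_points = 960L, eps = 0.1) {
  stopifnot(inherits(model, "structure_model"))
  if (identical(chain_a, chain_b))
    stop("'chain_a' and 'chain_b' must differ", call. = FALSE)
  ma <- subset_chain(model, chain_a)
  mb <- subset_chain(model, chain_b)
  mab <- subset_chain(model, c(chain_a, chain_b))
  sa <- sasa(ma, probe, n_points)
  sb <- sasa(mb, probe, n_points)
  sab <- sasa(mab, probe, n_points)
  per_chain <- function(alone, chain) {
    comp <- sab$residues[sab$residues$chain == chain, , drop = FALSE]
    stopifnot(identical(alone$residues$resno, comp$resno))
    delta <- alone$residues$sasa - comp$sasa
    data.frame(resno = alone$residues$resno, resid = alone$residues$resid,
               aa1 = alone$residues$aa1,
               sasa_alone = alone$residues$sasa, sasa_complex = comp$sasa,
               delta_sasa = delta, interface = delta > eps,
               stringsAsFactors = FALSE)
  }
  out <- list(per_chain(sa, chain_a), per_chain(sb, chain_b))
  names(out) <- c(chain_a, chain_b)
  structure(c(out, list(eps = eps)), class = "interface_map")
}

#' @export
print.interface_map <- function(x, ...) {
  chains <- setdiff(names(x), "eps")
  cat(sprintf("<interface_map> %s\n",
              paste(vapply(chains, function(ch)
                sprintf("chain %s: %d interface residue(s)",
                        ch, sum(x[[ch]]$interface)), ""),
                collapse = "; ")))
  invisible(x)
}

#' Align two homologous proteins (helper for synthetic tests)
#'
#' Global alignment with BLOSUM62, gap open 11 / extend 1, returning the
#' aligned (non-gap) site pairs.  Intended for simulated data; for real
#' homolog comparisons supply the curated alignment directly.
#'
#' @param query,subject [protein_record()]s.
#' @return Data frame with columns `qpos`, `spos` (1-based).
#' @export
align_homologs <- function(query, subject) {
  stopifnot(inherits(query, "protein_record"),
            inherits(subject, "protein_record"))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query$seq), Biostrings::AAString(subject$seq),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "global")
  qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  qpos <- cumsum(qa != "-")
  spos <- cumsum(sa != "-")
  keep <- qa != "-" & sa != "-"
  data.frame(qpos = qpos[keep], spos = spos[keep])
}

#' Read a two-column paired-index alignment file
#'
#' @param path TSV with columns `qpos` and `spos`.
#' @return Data frame with integer `qpos`, `spos`.
#' @export
read_alignment_pairs <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("qpos", "spos") %in% names(d)))
  data.frame(qpos = as.integer(d$qpos), spos = as.integer(d$spos))
}

#' Site-wise hydrophobicity-increase comparison between homologs
#'
#' For each aligned site pair, flags a hydrophobicity increase when the
#' query residue's Kyte-Doolittle value is strictly greater than the
#' subject residue's.  Sites are then stratified by a per-query-site flag
#' (e.g. exposed vs. non-exposed, or interface vs. non-interface) and the
#' increase rates of the two strata are compared by a 2x2 chi-square test
#' without continuity correction.  An optional per-site editing flag is
#' compared across the same strata.
#'
#' @param query,subject [protein_record()]s.
#' @param alignment Data frame of aligned pairs (`qpos`, `spos`); gapped
#'   sites are simply absent.
#' @param strata Logical vector over query positions (TRUE = first
#'   stratum).
#' @param strata_names Length-2 labels, `c(TRUE-stratum, FALSE-stratum)`.
#' @param edited_flags Optional logical vector over query positions
#'   marking edited codons.
#' @return An object of class `site_comparison`: per-pair data frame
#'   `sites`, per-stratum `fractions`, 2x2 `contingency`, `test`
#'   (a `test_result`, or `NULL` with a warning when a stratum is empty),
#'   and, when `edited_flags` is given, `editing_fractions` and
#'   `editing_test`.
#' @export
compare_hydrophobicity <- function(query, subject, alignment, strata,
                                   strata_names = c("exposed", "nonexposed"),
                                   edited_flags = NULL) {
  stopifnot(inherits(query, "protein_record"),
            inherits(subject, "protein_record"))
  qchars <- strsplit(query$seq, "", fixed = TRUE)[[1]]
  schars <- strsplit(subject$seq, "", fixed = TRUE)[[1]]
  if (any(alignment$qpos < 1L | alignment$qpos > length(qchars)) ||
      any(alignment$spos < 1L | alignment$spos > length(schars)))
    stop("alignment indexes outside the proteins", call. = FALSE)
  if (length(strata) != length(qchars))
    stop("'strata' must have one flag per query residue", call. = FALSE)
  kd <- function(ch) {
    v <- unname(kyte_doolittle[ch])
    v[is.na(v)] <- 0
    v
  }
  increase <- kd(qchars[alignment$qpos]) > kd(schars[alignment$spos])
  in_stratum <- strata[alignment$qpos]
  sites <- data.frame(qpos = alignment$qpos, spos = alignment$spos,
                      query_aa = qchars[alignment$qpos],
                      subject_aa = schars[alignment$spos],
                      increase = increase, stratum = in_stratum)
  fractions <- c(mean(increase[in_stratum]), mean(increase[!in_stratum]))
  names(fractions) <- strata_names
  make_test <- function(flag, label) {
    if (!any(in_stratum) || all(in_stratum)) {
      warning(sprintf("%s: empty stratum; test skipped", label),
              call. = FALSE)
      return(NULL)
    }
    tab <- rbind(c(sum(flag & in_stratum), sum(!flag & in_stratum)),
                 c(sum(flag & !in_stratum), sum(!flag & !in_stratum)))
    dimnames(tab) <- list(strata_names, c("yes", "no"))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      warning(sprintf("%s: degenerate table; test skipped", label),
              call. = FALSE)
      return(NULL)
    }
    chisq_2x2(tab, label)
  }
  test <- make_test(increase, sprintf("hydrophobicity increase by %s/%s",
                                      strata_names[1], strata_names[2]))
  out <- list(sites = sites, fractions = fractions,
              contingency = if (is.null(test)) NULL else test$observed,
              test = test)
  if (!is.null(edited_flags)) {
    if (length(edited_flags) != length(qchars))
      stop("'edited_flags' must have one flag per query residue",
           call. = FALSE)
    ed <- edited_flags[alignment$qpos]
    out$editing_fractions <- stats::setNames(
      c(mean(ed[in_stratum]), mean(ed[!in_stratum])), strata_names)
    out$editing_test <- make_test(ed, sprintf("editing frequency by %s/%s",
                                              strata_names[1],
                                              strata_names[2]))
  }
  structure(out, class = "site_comparison")
}

#' @export
print.site_comparison <- function(x, ...) {
  cat(sprintf("<site_comparison> increase %.1f%% (%s) vs %.1f%% (%s)%s\n",
              100 * x$fractions[1], names(x$fractions)[1],
              100 * x$fractions[2], names(x$fractions)[2],
              if (is.null(x$test)) ""
              else sprintf(", p = %.3g", x$test$p)))
  invisible(x)
}

#' Write a structure model as a PDB file
#'
#' @param model A [structure_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(at)),
    ifelse(nchar(at$elety) < 4, paste0(" ", at$elety), at$elety),
    at$resid, at$chain, at$resno, at$x, at$y, at$z, at$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
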