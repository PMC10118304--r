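# Seeded generators of synthetic editing pairs, diverged sequence sets and
# toy two-chain structures, with recorded ground truth.

#' Parameters for the editing-pair simulator
#'
#' Defaults emulate a pan-edited mitochondrial mRNA: a G-rich, U-poor
#' cryptogene into which editing inserts roughly one U per anchor gap in
#' short geometric runs, yielding an edited CDS with slightly more than
#' half of its bases U, about 90 percent of which are inserted; a small
#' fraction of genomic Us is deleted.
#'
#' @param cds_length Cryptogene length in codons (default 150).
#' @param base_composition Named probabilities for A, C, G, U in the
#'   cryptogene (default `c(A = .30, C = .15, G = .45, U = .10)`).
#' @param insertion_rate Expected inserted Us per anchor gap (default
#'   1.1).
#' @param run_length_geom Success probability of the geometric run-length
#'   distribution (mean run length `1/run_length_geom`; default 0.5).
#' @param deletion_rate Per-genomic-U deletion probability, applied only
#'   in runs without insertions (default 0.05).
#' @param position_bias Optional length-3 weights biasing inserted Us
#'   toward codon positions 1--3 of the edited mRNA.  When set, the
#'   generator produces a fully pan-edited pair (see
#'   [simulate_editing_pair()]).
#' @param seed Integer seed (required; generators are pure functions of
#'   their parameters and seed).
#' @return An object of class `editing_sim_params`.
#' @export
editing_sim_params <- function(cds_length = 150L,
                               base_composition = c(A = 0.30, C = 0.15,
                                                    G = 0.45, U = 0.10),
                               insertion_rate = 1.1,
                               run_length_geom = 0.5,
                               deletion_rate = 0.05,
                               position_bias = NULL,
                               seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  stopifnot(cds_length >= 1L, insertion_rate >= 0, deletion_rate >= 0,
            deletion_rate <= 1, run_length_geom > 0, run_length_geom <= 1)
  base_composition <- base_composition[c("A", "C", "G", "U")]
  if (anyNA(base_composition) || abs(sum(base_composition) - 1) > 1e-9)
    stop("'base_composition' must be probabilities for A, C, G, U summing to 1",
         call. = FALSE)
  if (!is.null(position_bias)) {
    stopifnot(length(position_bias) == 3L, all(position_bias >= 0),
              sum(position_bias) > 0)
    position_bias <- position_bias / sum(position_bias)
  }
  structure(list(cds_length = as.integer(cds_length),
                 base_composition = base_composition,
                 insertion_rate = insertion_rate,
                 run_length_geom = run_length_geom,
                 deletion_rate = deletion_rate,
                 position_bias = position_bias,
                 seed = as.integer(seed)),
            class = "editing_sim_params")
}

# codon position of 1-based coordinates within a frame-0 CDS span,
# NA beyond the last complete codon
codon_position_of <- function(pos, len) {
  cp <- ((pos - 1L) %% 3L) + 1L
  cp[pos > 3L * (len %/% 3L)] <- NA_integer_
  cp
}

#' Simulate a cryptogene / edited-mRNA pair with known editing events
#'
#' Without `position_bias`: draws a cryptogene from `base_composition`,
#' then for each anchor gap either inserts a geometric run of Us (3' of
#' any genomic Us in the gap, i.e. the `genomic_left` placement
#' convention) or deletes genomic Us at `deletion_rate`; the edited mRNA
#' is the result.  With `position_bias`: draws the edited mRNA directly,
#' placing U at each site with probability proportional to the bias at
#' that codon position (scaled to the overall U proportion implied by
#' `base_composition`), and removes every U to form the cryptogene, so
#' that all Us are inserted and the inserted-U codon-position distribution
#' follows the bias exactly.
#'
#' At most one of insertion/deletion occurs per anchor gap, and the truth
#' is recorded in the `genomic_left` convention, so [anchor_align()] plus
#' [inserted_by_codon_position()] can recover every event.
#'
#' @param params An [editing_sim_params()] object.
#' @return List with `cryptogene` and `edited` [cds_record()]s and
#'   `truth`: per-run `n_inserted`/`n_deleted`, `inserted_positions`
#'   (edited coordinates), `inserted_by_position` (3 counts over complete
#'   codons of the edited CDS), `total_inserted`, `total_deleted`.
#' @export
simulate_editing_pair <- function(params) {
  stopifnot(inherits(params, "editing_sim_params"))
  set.seed(params$seed)
  if (is.null(params$position_bias)) {
    core <- sample(names(params$base_composition),
                   3L * params$cds_length, replace = TRUE,
                   prob = params$base_composition)
    # runs of Us delimited by non-U anchors; gap g precedes anchor g
    anchors <- which(core != "U")
    n_gap <- length(anchors) + 1L
    p_run <- min(params$insertion_rate * params$run_length_geom, 1)
    has_run <- stats::runif(n_gap) < p_run
    run_len <- integer(n_gap)
    run_len[has_run] <- stats::rgeom(sum(has_run),
                                     params$run_length_geom) + 1L
    bounds <- c(0L, anchors, length(core) + 1L)
    edited_chunks <- vector("list", n_gap)
    run_ins <- integer(n_gap)
    run_del <- integer(n_gap)
    for (g in seq_len(n_gap)) {
      genomic_u <- bounds[g + 1L] - bounds[g] - 1L
      if (run_len[g] > 0L) {
        run_ins[g] <- run_len[g]
        n_u <- genomic_u + run_len[g]
      } else {
        run_del[g] <- stats::rbinom(1L, genomic_u, params$deletion_rate)
        n_u <- genomic_u - run_del[g]
      }
      edited_chunks[[g]] <- c(rep("U", n_u),
                              if (g <= length(anchors)) core[anchors[g]])
    }
    edited_chars <- unlist(edited_chunks)
    # edited coordinates of inserted slots: 3'-most n_inserted U slots per run
    ins_pos <- integer(0)
    offset <- 0L
    for (g in seq_len(n_gap)) {
      n_u <- sum(edited_chunks[[g]] == "U")
      if (run_ins[g] > 0L)
        ins_pos <- c(ins_pos,
                     offset + seq.int(n_u - run_ins[g] + 1L, n_u))
      offset <- offset + length(edited_chunks[[g]])
    }
    crypto_seq <- paste(core, collapse = "")
    edited_seq <- paste(edited_chars, collapse = "")
  } else {
    n_sites <- 3L * params$cds_length
    # overall U level of the edited CDS implied by the insertion rate:
    # one anchor gap per non-U site, insertion_rate inserted Us per gap
    p_u0 <- params$base_composition[["U"]]
    ins_per_site <- params$insertion_rate * (1 - p_u0)
    p_u_mean <- min((p_u0 + ins_per_site) / (1 + ins_per_site), 0.9)
    p_u <- pmin(3 * p_u_mean * params$position_bias, 0.95)
    cp <- ((seq_len(n_sites) - 1L) %% 3L) + 1L
    is_u <- stats::runif(n_sites) < p_u[cp]
    others <- params$base_composition[c("A", "C", "G")]
    edited_chars <- ifelse(is_u, "U",
                           sample(c("A", "C", "G"), n_sites, replace = TRUE,
                                  prob = others / sum(others)))
    ins_pos <- which(edited_chars == "U")
    run_ins <- NULL; run_del <- NULL
    edited_seq <- paste(edited_chars, collapse = "")
    crypto_seq <- paste(edited_chars[edited_chars != "U"], collapse = "")
    if (nchar(crypto_seq) == 0L)
      stop("degenerate simulation: cryptogene has no anchors", call. = FALSE)
  }
  edited_len <- nchar(edited_seq)
  cp_ins <- codon_position_of(ins_pos, edited_len)
  truth <- list(run_inserted = run_ins, run_deleted = run_del,
                inserted_positions = ins_pos,
                inserted_by_position = tabulate(cp_ins[!is.na(cp_ins)],
                                                nbins = 3L),
                total_inserted = length(ins_pos),
                total_deleted = if (is.null(run_del)) 0L else sum(run_del))
  list(cryptogene = cds_record(sprintf("sim%08d_crypto", params$seed),
                               crypto_seq, species = "synthetic",
                               gene = "SIM", editing_status = "pan_edited"),
       edited = cds_record(sprintf("sim%08d_edited", params$seed),
                           edited_seq, species = "synthetic", gene = "SIM",
                           editing_status = "pan_edited"),
       truth = truth)
}

#' Parameters for the divergence simulator
#'
#' @param n_species Number of diverged sequences to generate (default 20).
#' @param rates Per-site substitution probabilities for codon positions
#'   1--3 (default `c(0.1, 0.1, 0.1)`).
#' @param purifying_strength Factor by which the second-position rate is
#'   divided, emulating purifying selection on the hydrophobicity-carrying
#'   position (default 10).
#' @param seed Integer seed (required).
#' @return An object of class `divergence_sim_params`.
#' @export
divergence_sim_params <- function(n_species = 20L,
                                  rates = c(0.1, 0.1, 0.1),
                                  purifying_strength = 10,
                                  seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  stopifnot(n_species >= 1L, length(rates) == 3L, all(rates >= 0),
            purifying_strength >= 1)
  structure(list(n_species = as.integer(n_species), rates = rates,
                 purifying_strength = purifying_strength,
                 seed = as.integer(seed)),
            class = "divergence_sim_params")
}

#' Simulate independently diverged species from a root CDS
#'
#' Each species substitutes each site independently with the rate of its
#' codon position (second-position rate divided by `purifying_strength`);
#' a substituted base is replaced by one of the other three, uniformly.
#'
#' @param root A [cds_record()].
#' @param params A [divergence_sim_params()] object.
#' @return List of `n_species` [cds_record()]s.
#' @export
simulate_divergence <- function(root, params) {
  stopifnot(inherits(root, "cds_record"),
            inherits(params, "divergence_sim_params"))
  set.seed(params$seed)
  chars <- seq_chars(root)
  idx <- codon_position_indices(root)
  rate <- rep(0, length(chars))
  eff <- params$rates
  eff[2] <- eff[2] / params$purifying_strength
  for (cp in 1:3) rate[idx[[cp]]] <- eff[cp]
  bases <- c("A", "C", "G", "U")
  lapply(seq_len(params$n_species), function(s) {
    hit <- stats::runif(length(chars)) < rate
    out <- chars
    if (any(hit)) {
      out[hit] <- vapply(chars[hit], function(b)
        sample(setdiff(bases, b), 1L), "")
    }
    cds_record(sprintf("%s_sp%02d", root$id, s), paste(out, collapse = ""),
               species = sprintf("species_%02d", s), gene = root$gene,
               frame_offset = root$frame_offset)
  })
}

#' Build a toy two-chain complex with known contact residues
#'
#' Two idealized poly-alanine chains, one interaction-center sphere per
#' residue.  Chain A runs along the z axis; the first
#' `round(contact_fraction * min(n_a, n_b))` residues of chain B lie 3
#' Angstrom from the matching block of chain A, and the rest of chain B
#' veers away perpendicular to A.  The geometry keeps every cross-chain
#' atom pair either well inside or well outside the SASA occlusion radius,
#' so the recorded ground-truth contact set (residues with any other-chain
#' atom within `r_i + r_j + 2 * probe`) is unambiguous.
#'
#' @param n_residues_a,n_residues_b Chain sizes (>= 3).
#' @param contact_fraction Fraction of the shorter chain in contact, in
#'   `(0, 1]` (default 0.3).
#' @param seed Integer seed (kept in the output for provenance; the
#'   construction is deterministic).
#' @param probe Probe radius used to define the occlusion ground truth.
#' @return List with `model` (a [structure_model()]) and `truth`: per
#'   chain, the residue numbers in contact.
#' @export
make_toy_complex <- function(n_residues_a, n_residues_b,
                             contact_fraction = 0.3, seed = 1L,
                             probe = 1.4) {
  stopifnot(n_residues_a >= 3L, n_residues_b >= 3L)
  if (contact_fraction <= 0 || contact_fraction > 1)
    stop("'contact_fraction' must be in (0, 1]", call. = FALSE)
  spacing <- 3.8
  k <- max(1L, round(contact_fraction * min(n_residues_a, n_residues_b)))
  k <- min(k, n_residues_a, n_residues_b)
  ax <- data.frame(chain = "A", resno = seq_len(n_residues_a),
                   resid = "ALA", elety = "CA", element = "C",
                   x = 0, y = 0, z = spacing * (seq_len(n_residues_a) - 1L),
                   stringsAsFactors = FALSE)
  # chain B: contact block parallel to the start of chain A at 3 A, the
  # remainder walking away along +x
  bz <- spacing * (seq_len(k) - 1L)
  bx <- rep(3.0, k)
  if (n_residues_b > k) {
    m <- seq_len(n_residues_b - k)
    bx <- c(bx, 3.0 + spacing * m)
    bz <- c(bz, rep(spacing * (k - 1L), length(m)))
  }
  bt <- data.frame(chain = "B", resno = seq_len(n_residues_b),
                   resid = "ALA", elety = "CA", element = "C",
                   x = bx, y = 0, z = bz, stringsAsFactors = FALSE)
  model <- structure_model(rbind(ax, bt))
  at <- model$atoms
  cutoff <- 2 * (at$radius[1] + probe)
  a_idx <- which(at$chain == "A")
  b_idx <- which(at$chain == "B")
  d <- sqrt(outer(at$x[a_idx], at$x[b_idx], "-")^2 +
              outer(at$y[a_idx], at$y[b_idx], "-")^2 +
              outer(at$z[a_idx], at$z[b_idx], "-")^2)
  in_band <- abs(d - cutoff) < 0.3
  if (any(in_band))
    stop("toy geometry places an atom pair too close to the occlusion cutoff",
         call. = FALSE)
  truth <- list(A = at$resno[a_idx][apply(d < cutoff, 1, any)],
                B = at$resno[b_idx][apply(d < cutoff, 2, any)])
  list(model = model, truth = truth, seed = as.integer(seed),
       contact_cutoff = cutoff)
}
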