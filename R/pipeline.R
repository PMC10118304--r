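# Pipeline orchestration: subcommands with a declarative config, a run
# manifest and deterministic text outputs.

usage_error <- function(msg) {
  stop(structure(class = c("panedit_usage_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Build a run configuration
#'
#' Defaults reproduce the analysis conventions used throughout the
#' package: 30-base windows, a 0.30 relative-SASA exposure threshold, the
#' hydrophobic set F, L, I, V, M, W, Y, genetic code table 4 and
#' Shrake-Rupley SASA at 960 points with a 1.4 Angstrom probe.
#'
#' @param ... Named fields overriding the defaults; typical fields are
#'   `input` (FASTA/PDB path), `input_crypto`/`input_edited` (editing
#'   pairs), `reference_id`, `chain_a`/`chain_b`, `matrix` (score-matrix
#'   path), and any generator parameter.
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed for subcommands that draw random numbers.
#' @return A list of class `run_config`.
#' @export
run_config <- function(..., out_dir = "panedit_out", seed = 1L) {
  cfg <- list(window = 30L, exposure_threshold = 0.30,
              hydrophobic_set = HYDROPHOBIC_SET, code_table = "4",
              probe = 1.4, n_points = 960L, interface_eps = 0.1,
              coevolution_threshold = 0.8, coevolution_max_dist = 5L,
              out_dir = out_dir, seed = as.integer(seed))
  override <- list(...)
  cfg[names(override)] <- override
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys override [run_config()] defaults.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) usage_error(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(x == round(x) & abs(x) < 1e15,
                format(x, scientific = FALSE, trim = TRUE),
                sprintf("%.6f", x)))
}

write_tsv <- function(d, path) {
  num <- vapply(d, is.numeric, TRUE)
  d[num] <- lapply(d[num], fmt_num)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_manifest <- function(cfg, subcommand, inputs, outputs) {
  manifest <- list(
    subcommand = subcommand,
    inputs = inputs,
    parameters = cfg[setdiff(names(cfg), "out_dir")],
    outputs = basename(unlist(outputs)),
    package_version = as.character(utils::packageVersion("panedit")),
    seed = cfg$seed)
  path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

require_field <- function(cfg, field, subcommand) {
  if (is.null(cfg[[field]]))
    usage_error(sprintf("subcommand '%s' requires config field '%s'",
                        subcommand, field))
  cfg[[field]]
}

#' Run a pipeline subcommand
#'
#' Dispatches one analysis stage and writes its deterministic TSV/JSON
#' outputs, plus a run manifest (inputs, parameters, package version,
#' seed), under `cfg$out_dir`.  Re-running with the same configuration
#' reproduces byte-identical outputs.
#'
#' Subcommands: `walk` (U walks, overall and per codon position),
#' `composition` (per-record U-content report), `editing` (inserted-U
#' report from cryptogene/edited pairs), `protein` (hydrophobic fractions,
#' class composition, optional coevolution summary), `hca` (cluster
#' tables), `sasa` (per-residue SASA/exposure), `compare` (interface map
#' between two chains), `simulate` (write a synthetic editing pair and its
#' truth).
#'
#' @param subcommand One of the names above.
#' @param cfg A [run_config()] (or path handled by [read_run_config()]).
#' @return Invisibly, the list of files written.  Configuration problems
#'   signal a `panedit_usage_error`.
#' @export
run_pipeline <- function(subcommand, cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  known <- c("walk", "composition", "editing", "protein", "hca", "sasa",
             "compare", "simulate")
  if (length(subcommand) != 1L || !subcommand %in% known)
    usage_error(sprintf("unknown subcommand '%s' (expected one of: %s)",
                        paste(subcommand, collapse = ","),
                        paste(known, collapse = ", ")))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- list()
  outputs <- list()
  emit <- function(d, name) {
    p <- file.path(cfg$out_dir, name)
    outputs[[length(outputs) + 1L]] <<- write_tsv(d, p)
  }
  if (subcommand == "walk") {
    path <- require_field(cfg, "input", subcommand)
    inputs$input <- path
    records <- read_fasta(path, "rna")
    rows <- do.call(rbind, lapply(records, function(rec) {
      overall <- walk_as_data_frame(nucleotide_walk(rec))
      overall$codon_position <- 0L
      per <- lapply(1:3, function(cp) {
        d <- walk_as_data_frame(nucleotide_walk(rec, codon_position = cp))
        d$codon_position <- cp
        d
      })
      d <- rbind(overall, do.call(rbind, per))
      d$id <- rec$id
      d
    }))
    emit(rows[, c("id", "codon_position", "rank", "position", "s")],
         "walks.tsv")
  } else if (subcommand == "composition") {
    path <- require_field(cfg, "input", subcommand)
    inputs$input <- path
    records <- read_fasta(path, "rna")
    emit(composition_report(records, reference_id = cfg$reference_id,
                            window = cfg$window), "composition.tsv")
  } else if (subcommand == "editing") {
    cpath <- require_field(cfg, "input_crypto", subcommand)
    epath <- require_field(cfg, "input_edited", subcommand)
    inputs$input_crypto <- cpath
    inputs$input_edited <- epath
    crypto <- read_fasta(cpath, "rna")
    edited <- read_fasta(epath, "rna")
    if (length(crypto) != length(edited))
      usage_error("cryptogene and edited FASTA files have different record counts")
    pairs <- Map(function(c, e) list(cryptogene = c, edited = e),
                 crypto, edited)
    emit(editing_report(pairs), "editing.tsv")
    aln <- anchor_align(crypto[[1]], edited[[1]])
    p <- file.path(cfg$out_dir, "alignment.json")
    jsonlite::write_json(
      list(cryptogene_id = aln$cryptogene_id, edited_id = aln$edited_id,
           total_inserted = aln$total_inserted,
           total_deleted = aln$total_deleted, runs = aln$runs),
      p, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    outputs[[length(outputs) + 1L]] <- p
  } else if (subcommand == "protein") {
    path <- require_field(cfg, "input", subcommand)
    inputs$input <- path
    prots <- read_fasta(path, "protein")
    frac <- vapply(prots, hydrophobic_fraction, 0,
                   hydrophobic_set = cfg$hydrophobic_set)
    comp <- lapply(prots, composition_by_class)
    d <- data.frame(id = vapply(prots, `[[`, "", "id"),
                    hydrophobic_fraction = frac,
                    order = vapply(comp, function(x) x$class_totals[["order"]], 0),
                    disorder = vapply(comp, function(x)
                      x$class_totals[["disorder"]], 0),
                    ambiguous = vapply(comp, function(x)
                      x$class_totals[["ambiguous"]], 0))
    if (length(prots) >= 2L) {
      sr <- survey_rank(prots, hydrophobic_set = cfg$hydrophobic_set)
      d$rank <- sr$table$rank
    }
    emit(d, "protein.tsv")
    if (!is.null(cfg$matrix)) {
      inputs$matrix <- cfg$matrix
      m <- read_score_matrix(cfg$matrix)
      cs <- coevolution_pair_summary(m, prots[[1]],
                                     threshold = cfg$coevolution_threshold,
                                     max_dist = cfg$coevolution_max_dist,
                                     hydrophobic_set = cfg$hydrophobic_set)
      emit(cs$pairs, "coevolution_pairs.tsv")
    }
  } else if (subcommand == "hca") {
    path <- require_field(cfg, "input", subcommand)
    inputs$input <- path
    prots <- read_fasta(path, "protein")
    rows <- do.call(rbind, lapply(prots, function(p) {
      cl <- detect_clusters(p, hydrophobic_set = cfg$hydrophobic_set)
      if (nrow(cl$cluster_table) == 0L) return(NULL)
      d <- cl$cluster_table
      d$members <- vapply(cl$clusters, paste, "", collapse = ",")
      d$id <- p$id
      d[, c("id", "cluster", "start", "end", "size", "members")]
    }))
    if (is.null(rows))
      rows <- data.frame(id = character(0), cluster = integer(0),
                         start = integer(0), end = integer(0),
                         size = integer(0), members = character(0))
    emit(rows, "hca_clusters.tsv")
  } else if (subcommand == "sasa") {
    path <- require_field(cfg, "input", subcommand)
    inputs$input <- path
    model <- read_structure(path)
    res <- sasa(model, probe = cfg$probe, n_points = cfg$n_points,
                exposure_threshold = cfg$exposure_threshold)
    emit(res$residues, "sasa.tsv")
  } else if (subcommand == "compare") {
    path <- require_field(cfg, "input", subcommand)
    chain_a <- require_field(cfg, "chain_a", subcommand)
    chain_b <- require_field(cfg, "chain_b", subcommand)
    inputs$input <- path
    model <- read_structure(path)
    im <- interface_sites(model, chain_a, chain_b, probe = cfg$probe,
                          n_points = cfg$n_points, eps = cfg$interface_eps)
    for (ch in c(chain_a, chain_b))
      emit(im[[ch]], sprintf("interface_chain_%s.tsv", ch))
  } else if (subcommand == "simulate") {
    params <- editing_sim_params(
      cds_length = if (is.null(cfg$cds_length)) 150L else cfg$cds_length,
      seed = cfg$seed)
    sim <- simulate_editing_pair(params)
    fa_c <- file.path(cfg$out_dir, "cryptogene.fasta")
    fa_e <- file.path(cfg$out_dir, "edited.fasta")
    write_fasta(list(sim$cryptogene), fa_c)
    write_fasta(list(sim$edited), fa_e)
    tj <- file.path(cfg$out_dir, "truth.json")
    jsonlite::write_json(sim$truth, tj, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    outputs <- c(outputs, list(fa_c, fa_e, tj))
  }
  outputs[[length(outputs) + 1L]] <- write_manifest(cfg, subcommand,
                                                    inputs, outputs)
  invisible(unlist(outputs))
}
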