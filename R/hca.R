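# Hydrophobic cluster analysis: a protein drawn on a duplicated
# alpha-helical net (3.6 residues per turn) with hydrophobic clusters
# delimited by a separation rule with proline breaks.

# Symbol classes used on the net, in priority order.
hca_class_of <- function(chars, hydrophobic_set = HYDROPHOBIC_SET) {
  cls <- rep("other", length(chars))
  cls[chars %in% hydrophobic_set] <- "hydrophobic"
  cls[chars == "P"] <- "P"
  cls[chars %in% c("S", "T")] <- "ST"
  cls[chars == "G"] <- "G"
  cls[chars %in% c("D", "E")] <- "acidic"
  cls[chars %in% c("Q", "N")] <- "amide"
  cls[chars %in% c("R", "K", "H")] <- "basic"
  cls
}

#' Place a protein on the duplicated alpha-helical net
#'
#' Assigns each residue an x coordinate (its sequence index) and a
#' y coordinate given by its helical phase (3.6 residues per turn,
#' expressed as a fraction of a turn); the net is duplicated vertically
#' (second copy at `phase + 1`) so that clusters wrapping around the helix
#' stay visually contiguous.  Each residue also carries a symbol class:
#' hydrophobic, `P` (proline, drawn as a star), `ST` (threonine/serine,
#' squares), `G` (glycine, diamonds), acidic (D/E), amide (Q/N), basic
#' (R/K/H) or other.
#'
#' @param protein A [protein_record()] of length >= 2.
#' @param hydrophobic_set Hydrophobic residue set.
#' @return An object of class `hca_net` whose `coords` data frame has one
#'   row per residue: `residue`, `aa`, `x`, `phase` (in turns, `[0, 1)`),
#'   `y1`, `y2` (the two net copies) and `class`.
#' @export
build_net <- function(protein, hydrophobic_set = HYDROPHOBIC_SET) {
  stopifnot(inherits(protein, "protein_record"))
  chars <- strsplit(protein$seq, "", fixed = TRUE)[[1]]
  if (length(chars) < 2L)
    stop("protein must have at least 2 residues", call. = FALSE)
  i <- seq_along(chars)
  phase <- ((i - 1) / 3.6) %% 1
  coords <- data.frame(residue = i, aa = chars, x = i, phase = phase,
                       y1 = phase, y2 = phase + 1,
                       class = hca_class_of(chars, hydrophobic_set),
                       stringsAsFactors = FALSE)
  structure(list(coords = coords, residues_per_turn = 3.6,
                 sequence_id = protein$id),
            class = "hca_net")
}

#' @export
print.hca_net <- function(x, ...) {
  cat(sprintf("<hca_net> %s  %d residues on a duplicated %.1f-residue/turn net\n",
              x$sequence_id, nrow(x$coords), x$residues_per_turn))
  invisible(x)
}

#' Delimit hydrophobic clusters
#'
#' Two hydrophobic residues are connected when their sequence separation
#' is at most `max_gap` and no breaker residue (proline by default) lies
#' strictly between them; clusters are the connected components of that
#' relation.  Hydrophilic gaps are the maximal runs of at least
#' `min_gap_run` consecutive non-hydrophobic residues.
#'
#' @param protein A [protein_record()].
#' @param hydrophobic_set Hydrophobic residue set.
#' @param max_gap Maximum sequence separation joining two hydrophobic
#'   residues (default 4).
#' @param breakers Residues that always interrupt a cluster (default
#'   `"P"`).
#' @param min_gap_run Minimum length of a reported hydrophilic gap
#'   (default 4).
#' @return An object of class `hca_clusters`: `clusters` (list of 1-based
#'   residue index vectors, hydrophobic members only), `cluster_table`
#'   (id, start, end, size), and `hydrophilic_gaps` (data frame start,
#'   end, length).
#' @export
detect_clusters <- function(protein, hydrophobic_set = HYDROPHOBIC_SET,
                            max_gap = 4L, breakers = "P",
                            min_gap_run = 4L) {
  stopifnot(inherits(protein, "protein_record"))
  chars <- strsplit(protein$seq, "", fixed = TRUE)[[1]]
  hydro <- which(chars %in% hydrophobic_set)
  clusters <- list()
  if (length(hydro)) {
    breaker_pos <- which(chars %in% breakers)
    current <- hydro[1]
    if (length(hydro) > 1L) for (k in 2:length(hydro)) {
      a <- hydro[k - 1L]; b <- hydro[k]
      broken <- (b - a) > max_gap ||
        any(breaker_pos > a & breaker_pos < b)
      if (broken) {
        clusters[[length(clusters) + 1L]] <- current
        current <- b
      } else {
        current <- c(current, b)
      }
    }
    clusters[[length(clusters) + 1L]] <- current
  }
  # hydrophilic gaps: maximal runs of non-hydrophobic residues
  is_h <- chars %in% hydrophobic_set
  r <- rle(!is_h)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_gap_run
  gaps <- data.frame(start = starts[keep], end = ends[keep],
                     length = r$lengths[keep])
  cluster_table <- if (length(clusters))
    data.frame(cluster = seq_along(clusters),
               start = vapply(clusters, min, 0L),
               end = vapply(clusters, max, 0L),
               size = lengths(clusters))
  else data.frame(cluster = integer(0), start = integer(0),
                  end = integer(0), size = integer(0))
  structure(list(clusters = clusters, cluster_table = cluster_table,
                 hydrophilic_gaps = gaps, max_gap = max_gap,
                 breakers = breakers, sequence_id = protein$id),
            class = "hca_clusters")
}

#' @export
print.hca_clusters <- function(x, ...) {
  cat(sprintf("<hca_clusters> %s  %d cluster(s), %d hydrophilic gap(s) >= 4\n",
              x$sequence_id, length(x$clusters), nrow(x$hydrophilic_gaps)))
  invisible(x)
}

#' Distance from annotated sites to the nearest cluster boundary
#'
#' For overlay annotations (e.g. substituted sites or sites under
#' purifying selection), reports each site's distance to the nearest
#' hydrophobic-cluster start or end (0 when the site is itself a
#' boundary; `NA` when there are no clusters).
#'
#' @param clusters An [detect_clusters()] result.
#' @param sites Integer vector of 1-based residue indices.
#' @return Data frame with `site` and `boundary_distance`.
#' @export
site_boundary_distances <- function(clusters, sites) {
  stopifnot(inherits(clusters, "hca_clusters"))
  bounds <- c(clusters$cluster_table$start, clusters$cluster_table$end)
  d <- if (length(bounds))
    vapply(sites, function(s) min(abs(s - bounds)), 0)
  else rep(NA_real_, length(sites))
  data.frame(site = sites, boundary_distance = d)
}

#' Plot a hydrophobic cluster net
#'
#' Draws the duplicated helical net with the usual symbol conventions
#' (stars for prolines, squares for T/S, diamonds for G, red acidic/amide,
#' blue basic letters, hydrophobic residues in green) and shades cluster
#' extents.  Optional per-residue annotation flags are drawn as open
#' boxes.
#'
#' @param net A [build_net()] result.
#' @param clusters Optional [detect_clusters()] result for the same
#'   protein.
#' @param annotations Optional logical vector (protein length) of sites
#'   to box.
#' @param file Optional SVG file path; when given the plot is written
#'   there.
#' @return The net, invisibly.
#' @export
plot_hca <- function(net, clusters = NULL, annotations = NULL, file = NULL) {
  stopifnot(inherits(net, "hca_net"))
  if (!is.null(file)) {
    grDevices::svg(file, width = max(7, nrow(net$coords) / 10), height = 4)
    on.exit(grDevices::dev.off())
  }
  co <- net$coords
  col_of <- c(hydrophobic = "darkgreen", P = "black", ST = "grey30",
              G = "grey30", acidic = "red", amide = "red", basic = "blue",
              other = "grey50")
  pch_of <- c(hydrophobic = 19, P = 8, ST = 15, G = 18, acidic = NA,
              amide = NA, basic = NA, other = NA)
  graphics::plot(NA, xlim = range(co$x), ylim = c(0, 2), xlab = "residue",
                 ylab = "helical phase (turns)",
                 main = net$sequence_id)
  for (copy in c("y1", "y2")) {
    y <- co[[copy]]
    sym <- !is.na(pch_of[co$class])
    if (any(sym))
      graphics::points(co$x[sym], y[sym], pch = pch_of[co$class[sym]],
                       col = col_of[co$class[sym]], cex = 0.8)
    if (any(!sym))
      graphics::text(co$x[!sym], y[!sym], co$aa[!sym],
                     col = col_of[co$class[!sym]], cex = 0.6)
  }
  if (!is.null(clusters) && length(clusters$clusters))
    for (cl in clusters$clusters)
      graphics::rect(min(cl) - 0.4, 0, max(cl) + 0.4, 2,
                     border = NA, col = grDevices::adjustcolor("yellow", 0.2))
  if (!is.null(annotations)) {
    ann <- which(annotations)
    graphics::rect(ann - 0.4, -0.05, ann + 0.4, 2.05, border = "purple")
  }
  invisible(net)
}
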