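# Mapping per-residue scores onto a 3D structure: minimal PDB ATOM-record
# I/O (fixed-width per the PDB format), B-factor normalization, and
# single-linkage spatial clustering of significant residues.

#' Read Calpha residue sites from a PDB file
#'
#' Parses ATOM records of a PDB-format file and returns one site per
#' residue bearing a Calpha atom: residue number, chain, Calpha
#' coordinates and B-factor.  Alternate locations are resolved to the
#' highest-occupancy record; insertion codes are rejected, since residue
#' numbering between NMR tables and structure is by plain author residue
#' number.
#'
#' @param path PDB file path.
#' @param chain Chain identifier; default takes the first chain in the
#'   file.
#' @return Data frame (class `residue_sites`) with columns `residue_id`,
#'   `chain_id`, `residue_name`, `x`, `y`, `z`, `b_factor`.
#' @export
read_structure <- function(path, chain = NULL) {
  lines <- readLines(path)
  atoms <- lines[startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")]
  if (length(atoms) == 0L) stop("input error: no ATOM records in ", path)
  name <- trimws(substr(atoms, 13, 16))
  ca <- atoms[name == "CA" & startsWith(atoms, "ATOM  ")]
  if (length(ca) == 0L) stop("input error: no Calpha ATOM records in ", path)
  df <- data.frame(
    altloc = substr(ca, 17, 17),
    residue_name = trimws(substr(ca, 18, 20)),
    chain_id = substr(ca, 22, 22),
    residue_id = as.integer(substr(ca, 23, 26)),
    icode = trimws(substr(ca, 27, 27)),
    x = as.numeric(substr(ca, 31, 38)),
    y = as.numeric(substr(ca, 39, 46)),
    z = as.numeric(substr(ca, 47, 54)),
    occupancy = suppressWarnings(as.numeric(substr(ca, 55, 60))),
    b_factor = suppressWarnings(as.numeric(substr(ca, 61, 66))),
    stringsAsFactors = FALSE)
  if (any(nzchar(df$icode)))
    stop("input error: insertion codes are not supported (residues ",
         paste(unique(df$residue_id[nzchar(df$icode)]), collapse = ", "),
         "); renumber the structure first")
  if (is.null(chain)) chain <- df$chain_id[1]
  df <- df[df$chain_id == chain, ]
  if (nrow(df) == 0L) stop("input error: chain '", chain, "' not found")
  # altloc: keep the highest-occupancy record per residue
  df$occupancy[is.na(df$occupancy)] <- 1
  df <- df[order(df$residue_id, -df$occupancy), ]
  df <- df[!duplicated(df$residue_id), ]
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z)))
    stop("input error: non-finite coordinates")
  out <- df[, c("residue_id", "chain_id", "residue_name",
                "x", "y", "z", "b_factor")]
  rownames(out) <- NULL
  class(out) <- c("residue_sites", "data.frame")
  out
}

#' Normalize B-factors to per-chain z-scores
#'
#' `z = (B - mean(B)) / sd(B)` over the provided sites, the standard
#' normalization before comparing temperature factors across structures.
#'
#' @param sites A `residue_sites` data frame (>= 5 sites).
#' @return Named numeric vector of z-scores (names = residue ids).
#' @export
normalize_bfactors <- function(sites) {
  stopifnot(is.data.frame(sites), "b_factor" %in% names(sites))
  b <- sites$b_factor
  if (length(b) < 5L) stop("insufficient data: need >= 5 sites")
  s <- stats::sd(b)
  if (!is.finite(s) || s == 0)
    stop("zero variance: B-factors are constant, z-scores undefined")
  stats::setNames((b - mean(b)) / s, sites$residue_id)
}

#' Compare normalized B-factors between two structures
#'
#' Z-scores are computed per structure first (normalization precedes
#' subtraction), then differenced on the intersection of residue numbers.
#' The residue coverage must be identical after intersection.
#'
#' @param sites_a,sites_b `residue_sites` for the two structures.
#' @return Data frame `residue_id`, `z_a`, `z_b`, `delta_z`.
#' @export
compare_bfactors <- function(sites_a, sites_b) {
  za <- normalize_bfactors(sites_a)
  zb <- normalize_bfactors(sites_b)
  shared <- intersect(names(za), names(zb))
  if (length(shared) == 0L) stop("input error: no shared residues")
  data.frame(residue_id = as.integer(shared),
             z_a = unname(za[shared]), z_b = unname(zb[shared]),
             delta_z = unname(za[shared] - zb[shared]))
}

#' Cluster significant residues by spatial proximity
#'
#' Single-linkage clustering on Calpha-Calpha Euclidean distances: two
#' residues are connected if their distance is at most `cutoff`
#' (default 8 Angstrom, the standard coarse residue-contact definition),
#' and clusters are the connected components of that graph.  Implemented
#' through single-linkage hierarchical clustering cut at the cutoff
#' height, which is exactly the component structure of the thresholded
#' distance graph.
#'
#' @param significant Integer vector of significant residue ids.
#' @param sites A `residue_sites` data frame providing coordinates.
#' @param cutoff Connection distance (Angstrom), default 8.
#' @param observable Label recorded on each cluster.
#' @return List of clusters, each a list with `members` (sorted residue
#'   ids), `observable` and `diameter` (max within-cluster Calpha
#'   distance, Angstrom); ordered by decreasing size.  Residues without
#'   coordinates are dropped with a warning.
#' @export
cluster_residues <- function(significant, sites, cutoff = 8,
                             observable = NA_character_) {
  stopifnot(is.data.frame(sites), cutoff > 0)
  significant <- unique(as.integer(significant))
  if (length(significant) == 0L) return(list())
  idx <- match(significant, sites$residue_id)
  if (any(is.na(idx))) {
    warning("significant residues without coordinates excluded: ",
            paste(significant[is.na(idx)], collapse = ", "))
    significant <- significant[!is.na(idx)]
    idx <- idx[!is.na(idx)]
  }
  if (length(significant) == 0L) return(list())
  xyz <- as.matrix(sites[idx, c("x", "y", "z")])
  if (length(significant) == 1L) {
    membership <- stats::setNames(1L, significant)
  } else {
    d <- stats::dist(xyz)
    hc <- stats::hclust(d, method = "single")
    membership <- stats::setNames(stats::cutree(hc, h = cutoff), significant)
  }
  dm <- if (length(significant) > 1L) as.matrix(stats::dist(xyz)) else
    matrix(0, 1, 1)
  clusters <- lapply(split(seq_along(significant), membership), function(ii) {
    list(members = sort(significant[ii]), observable = observable,
         diameter = if (length(ii) > 1L) max(dm[ii, ii]) else 0)
  })
  clusters <- unname(clusters)
  clusters[order(-vapply(clusters, function(cl) length(cl$members),
                         integer(1)),
                 vapply(clusters, function(cl) cl$members[1], integer(1)))]
}

#' Cluster report as a data frame
#'
#' @param clusters List from [cluster_residues()].
#' @return Data frame `cluster_id`, `observable`, `n_members`, `members`
#'   (comma separated), `diameter`.
#' @export
cluster_table <- function(clusters) {
  if (length(clusters) == 0L)
    return(data.frame(cluster_id = integer(), observable = character(),
                      n_members = integer(), members = character(),
                      diameter = numeric()))
  data.frame(
    cluster_id = seq_along(clusters),
    observable = vapply(clusters, function(cl) as.character(cl$observable),
                        character(1)),
    n_members = vapply(clusters, function(cl) length(cl$members), integer(1)),
    members = vapply(clusters, function(cl)
      paste(cl$members, collapse = ","), character(1)),
    diameter = vapply(clusters, function(cl) cl$diameter, numeric(1)))
}

#' Write per-residue scores into the B-factor column of a PDB file
#'
#' Emits a PDB-format Calpha trace with each residue's score in the
#' temperature-factor column (fixed width, two decimals), the standard
#' trick for coloring structures by an arbitrary per-residue quantity.
#' Residues without a score receive the sentinel `-1.00`.  Scores
#' overflowing the 6-character column are linearly scaled into range and
#' a message is logged.
#'
#' @param sites A `residue_sites` data frame.
#' @param scores Named numeric vector (names = residue ids) or a data
#'   frame with `residue_id` and `value`.
#' @param path Output path.
#' @return The path, invisibly; attribute `scale` on the return value
#'   records any scaling factor applied (1 if none).
#' @export
write_score_structure <- function(sites, scores, path) {
  stopifnot(is.data.frame(sites))
  if (is.data.frame(scores))
    scores <- stats::setNames(scores$value, scores$residue_id)
  sc <- scores[as.character(sites$residue_id)]
  sc[!is.finite(sc)] <- NA_real_
  scale <- 1
  rng <- range(sc, na.rm = TRUE)
  if (any(is.finite(rng)) && (rng[2] > 999.99 || rng[1] < -99.99)) {
    scale <- min(999.99 / max(rng[2], 1e-9), 99.99 / max(-rng[1], 1e-9))
    sc <- sc * scale
    message(sprintf("scores scaled by %.4g to fit the B-factor column",
                    scale))
  }
  sc[is.na(sc)] <- -1  # sentinel for unscored residues
  rn <- sites$residue_name
  rn[is.na(rn) | !nzchar(rn)] <- "ALA"
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(sites)), substr(rn, 1, 3), sites$chain_id,
    sites$residue_id, sites$x, sites$y, sites$z, 1, sc)
  writeLines(c(lines, "END"), path)
  out <- invisible(path)
  attr(out, "scale") <- scale
  out
}

#' Write a residue_sites table as a plain PDB Calpha trace
#'
#' @param sites A `residue_sites` data frame (B-factors written as-is).
#' @param path Output path.
#' @export
write_structure <- function(sites, path) {
  b <- sites$b_factor
  b[is.na(b)] <- 0
  rn <- sites$residue_name
  rn[is.na(rn) | !nzchar(rn)] <- "ALA"
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(sites)), substr(rn, 1, 3), sites$chain_id,
    sites$residue_id, sites$x, sites$y, sites$z, 1, b)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
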