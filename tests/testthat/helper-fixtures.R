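# Shared fixtures: a scaled-down synthetic study and an independent
# brute-force clustering oracle.

# small 60-residue study used by unit tests (scaled from the 120-residue
# default to keep the suite fast); planted sets scaled accordingly
small_study <- function(dir, seed = 11L, noise = 0.015) {
  generate_study(dir, n_res = 60, seed = seed, noise = noise,
                 ligand_site = 40:46,
                 network_residues = c(8, 16, 24),
                 rex_above_bound = c(16, 41, 44, 52),
                 rex_below_bound = c(20, 50),
                 rex_above_apo = c(41, 52),
                 rex_below_apo = c(20),
                 disappeared = c(39, 47))
}

# independent oracle: connected components of the thresholded Calpha
# distance graph by breadth-first search (no hclust involved)
brute_components <- function(ids, sites, cutoff) {
  idx <- match(ids, sites$residue_id)
  xyz <- as.matrix(sites[idx, c("x", "y", "z"), drop = FALSE])
  n <- length(ids)
  adj <- as.matrix(stats::dist(xyz)) <= cutoff
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s
    comp <- integer()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      comp <- c(comp, v)
      queue <- c(queue, which(adj[v, ] & !seen))
    }
    comps[[length(comps) + 1L]] <- sort(ids[comp])
  }
  comps[order(vapply(comps, min, numeric(1)))]
}

# canonical ordering for comparing cluster membership lists
sort_clusters <- function(members_list) {
  members_list <- lapply(members_list, sort)
  members_list[order(vapply(members_list, min, numeric(1)))]
}
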