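# Synthetic two-state NMR dynamics study with planted allosteric ground
# truth: a toy helical structure, per-residue chemical shifts and
# relaxation parameters in an apo and a ligand-bound state, a pocket-
# proximal effect field decaying with distance plus a sparse long-range
# network, planted two-site exchange, and emission of every file type the
# analysis pipeline consumes.

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

#' Build an ideal alpha-helical Calpha trace
#'
#' Generates an idealized helix (rise 1.5 Angstrom per residue, 100 degree
#' rotation, radius 2.3 Angstrom), giving the canonical ~3.8 Angstrom
#' consecutive Calpha spacing, with B-factors drawn around a configured
#' base value.
#'
#' @param n_res Number of residues (>= 20).
#' @param seed Integer seed for residue names and B-factor draws.
#' @param b_base,b_sd Mean and SD of the Gaussian B-factor draw (Angstrom^2).
#' @param chain Chain identifier.
#' @return A `residue_sites` data frame (see [read_structure()]).
#' @export
build_toy_structure <- function(n_res, seed = 1L, b_base = 20, b_sd = 2,
                                chain = "A") {
  stopifnot(n_res >= 20)
  i <- seq_len(n_res)
  theta <- (i - 1) * 100 * pi / 180
  out <- with_seed(seed, {
    data.frame(residue_id = i, chain_id = chain,
               residue_name = sample(.AA3, n_res, replace = TRUE),
               x = 2.3 * cos(theta), y = 2.3 * sin(theta),
               z = 1.5 * (i - 1),
               b_factor = stats::rnorm(n_res, b_base, b_sd))
  })
  class(out) <- c("residue_sites", "data.frame")
  out
}

#' Default planted effect sizes
#'
#' Full-size (distance-zero) per-observable effects of ligand binding, on
#' the scale of the comparative study being emulated: amide shift changes
#' around 0.1-0.3 ppm, R1 drops of a few tenths 1/s, R2 increases of
#' several 1/s, modest NOE reduction, and a B-factor increment.
#'
#' @return Named list of effect magnitudes (`delta_h`, `delta_n` in ppm;
#'   `r1`, `r2` in 1/s; `noe` dimensionless; `b_factor` in Angstrom^2).
#' @export
study_effect_sizes <- function() {
  list(delta_h = 0.12, delta_n = 0.40, r1 = -0.40, r2 = 8, noe = -0.08,
       b_factor = 4)
}

# distance of every residue to the nearest ligand-site residue (Angstrom)
.pocket_distance <- function(sites, ligand_site) {
  idx <- match(ligand_site, sites$residue_id)
  if (any(is.na(idx)))
    stop("ligand-site residues outside structure: ",
         paste(ligand_site[is.na(idx)], collapse = ", "))
  xyz <- as.matrix(sites[, c("x", "y", "z")])
  pk <- xyz[idx, , drop = FALSE]
  apply(xyz, 1, function(p) sqrt(min(colSums((t(pk) - p)^2))))
}

# solve delta_omega so the propagated Rex between the schedule endpoints
# hits a target value
.solve_dw_for_rex <- function(target, p_b, k_ex, r2_0, schedule) {
  f <- function(ldw) {
    model_rex(exchange_params(p_b, k_ex, exp(ldw), r2_0, r2_0), schedule) -
      target
  }
  exp(stats::uniroot(f, c(log(10), log(8000)), tol = 1e-8)$root)
}

#' Baseline (apo) per-residue ground truth
#'
#' Draws apo-state chemical shifts and relaxation parameters for every
#' residue: amide 1H shifts around 8.3 ppm, 15N around 119 ppm, R1 around
#' 1.2 1/s, intrinsic R2 around 15 1/s, hetNOE around 0.82 -- a rigid
#' mid-size protein at high field.
#'
#' @param sites A `residue_sites` data frame.
#' @param seed Integer seed.
#' @return Data frame of apo values per residue.
#' @export
baseline_truth <- function(sites, seed = 1L) {
  n <- nrow(sites)
  with_seed(seed + 1000L, {
    data.frame(residue_id = sites$residue_id,
               dh_apo = stats::rnorm(n, 8.3, 0.45),
               dn_apo = stats::rnorm(n, 119, 3.5),
               r1_apo = stats::rnorm(n, 1.2, 0.10),
               r2_apo = stats::rnorm(n, 15, 1.5),
               noe_apo = stats::rnorm(n, 0.82, 0.04))
  })
}

#' Plant allosteric perturbations into a two-state ground truth
#'
#' Bound-state values are the apo values plus a full-size effect
#' attenuated by `exp(-d / decay_length)`, where `d` is the Calpha
#' distance to the nearest ligand-site residue -- plus full-size effects on
#' a sparse set of distal network residues regardless of distance,
#' emulating long-range dynamic allostery.  Per-residue effect multipliers
#' (pocket ~ U(0.8, 2), network ~ U(1.5, 2.5)) spread the planted
#' magnitudes as in real perturbation maps.  Configurable residue subsets
#' acquire two-site exchange parameters whose propagated Rex lies above or
#' below the 7.5 1/s strong-exchange rule, and a configurable subset
#' loses its bound-state peak ("disappeared", exchange broadening beyond
#' detection).
#'
#' @param truth Data frame from [baseline_truth()].
#' @param sites A `residue_sites` data frame.
#' @param ligand_site Residue ids forming the binding pocket.
#' @param network_residues Distal residues receiving full-size effects.
#' @param effect_sizes Named list as [study_effect_sizes()].
#' @param decay_length Spatial decay length of the effect field (Angstrom).
#' @param rex_above_bound,rex_below_bound Bound-state residues planted
#'   with exchange giving Rex above (11-18 1/s) or below (2.5-4.5 1/s)
#'   the rule.
#' @param rex_above_apo,rex_below_apo Same for the apo state (the bound
#'   state should carry more than twice as many strong-exchange residues).
#' @param disappeared Residues whose peak vanishes in the bound state.
#' @param schedule [cpmg_schedule()] defining the Rex endpoints.
#' @param seed Integer seed.
#' @return A `study_truth` data frame: per-residue two-state values,
#'   exchange parameters (`NA` where no exchange), true Rex per state,
#'   `csp_true`, and logical flags `pocket`, `network`, `disappeared`;
#'   attributes record the planted sets and generator settings.
#' @export
plant_allostery <- function(truth, sites,
                            ligand_site = 95:105,
                            network_residues = c(15, 22, 30, 38, 47, 55,
                                                 63, 70),
                            effect_sizes = study_effect_sizes(),
                            decay_length = 10,
                            rex_above_bound = c(30, 36, 47, 58, 68, 85, 96,
                                                98, 100, 102, 104, 110),
                            rex_below_bound = c(22, 40, 75, 88, 112, 118),
                            rex_above_apo = c(85, 96, 100, 102, 110),
                            rex_below_apo = c(40, 75, 88, 112),
                            disappeared = c(31, 93, 94, 106, 107),
                            schedule = cpmg_schedule(),
                            seed = 1L) {
  stopifnot(is.data.frame(truth), is.data.frame(sites))
  ids <- truth$residue_id
  for (set in list(network_residues, rex_above_bound, rex_below_bound,
                   rex_above_apo, rex_below_apo, disappeared))
    if (!all(set %in% ids))
      stop("planted residues outside structure: ",
           paste(setdiff(set, ids), collapse = ", "))
  stopifnot(all(vapply(effect_sizes, is.finite, logical(1))))
  d <- .pocket_distance(sites, ligand_site)
  w <- exp(-d / decay_length)
  gt <- truth
  gt$pocket <- ids %in% ligand_site
  gt$network <- ids %in% network_residues
  gt$d_pocket <- d
  gt <- with_seed(seed + 2000L, {
    mult <- stats::runif(length(ids), 0.8, 2.0)
    mult[gt$network] <- stats::runif(sum(gt$network), 1.5, 2.5)
    amp <- mult * pmax(w, as.numeric(gt$network))
    gt$effect_amp <- amp
    for (obs in c("r1", "r2", "noe")) {
      gt[[paste0(obs, "_bound")]] <-
        gt[[paste0(obs, "_apo")]] + effect_sizes[[obs]] * amp
    }
    sgn <- sample(c(-1, 1), length(ids), replace = TRUE)
    gt$dh_bound <- gt$dh_apo + sgn * effect_sizes$delta_h * amp
    gt$dn_bound <- gt$dn_apo - sgn * effect_sizes$delta_n * amp
    # plant two-site exchange with Rex solved onto the stated bands
    for (st in c("apo", "bound")) {
      above <- if (st == "apo") rex_above_apo else rex_above_bound
      below <- if (st == "apo") rex_below_apo else rex_below_bound
      pb <- kex <- dw <- rep(NA_real_, length(ids))
      rex <- rep(0, length(ids))
      for (set_rex in list(list(set = above, lo = 11, hi = 18),
                           list(set = below, lo = 2.5, hi = 4.5))) {
        for (rid in set_rex$set) {
          j <- match(rid, ids)
          pb[j] <- stats::runif(1, 0.02, 0.05)
          kex[j] <- stats::runif(1, 1200, 2500)
          target <- stats::runif(1, set_rex$lo, set_rex$hi)
          r20 <- gt[[paste0("r2_", st)]][j]
          dw[j] <- .solve_dw_for_rex(target, pb[j], kex[j], r20, schedule)
          rex[j] <- model_rex(exchange_params(pb[j], kex[j], dw[j],
                                              r20, r20), schedule)
        }
      }
      gt[[paste0("pb_", st)]] <- pb
      gt[[paste0("kex_", st)]] <- kex
      gt[[paste0("dw_", st)]] <- dw
      gt[[paste0("rex_", st)]] <- rex
    }
    gt
  })
  gt$csp_true <- compute_csp(gt$dh_apo, gt$dn_apo, gt$dh_bound, gt$dn_bound)
  gt$disappeared <- ids %in% disappeared
  structure(gt,
            class = c("study_truth", "data.frame"),
            ligand_site = ligand_site, network_residues = network_residues,
            effect_sizes = effect_sizes, decay_length = decay_length,
            rex_above_bound = sort(rex_above_bound),
            rex_below_bound = sort(rex_below_bound),
            rex_above_apo = sort(rex_above_apo),
            rex_below_apo = sort(rex_below_apo),
            disappeared = sort(disappeared), seed = seed)
}

# planted scoring reference sets -------------------------------------------

#' Ground-truth reference sets for scoring a pipeline run
#'
#' Derives, from a planted ground truth, the reference answers the
#' analysis pipeline should recover: the true 2-SD-significant CSP set
#' (computed over matched residues exactly as the pipeline computes it),
#' the CSP "positives" at `k_pos` SDs used for sensitivity scoring, the
#' strong-exchange sets per state, the disappeared set, and the true
#' single-linkage cluster memberships.
#'
#' @param truth A `study_truth` data frame.
#' @param sites The `residue_sites` used to build the study.
#' @param k Significance multiplier of the pipeline rule (default 2).
#' @param k_pos Multiplier defining scoring positives (default 3:
#'   "planted effects of at least 3 background SD").
#' @param rex_cutoff Strong-exchange cutoff (default 7.5 1/s).
#' @param cluster_cutoff Clustering distance cutoff (Angstrom).
#' @return List with elements `csp_significant`, `csp_positive`,
#'   `csp_negative`, `rex_above_apo`, `rex_above_bound`, `disappeared`,
#'   `csp_sd`, `clusters_csp` (list of sorted member vectors).
#' @export
truth_reference <- function(truth, sites, k = 2, k_pos = 3,
                            rex_cutoff = 7.5, cluster_cutoff = 8) {
  matched <- !truth$disappeared
  s <- stats::sd(truth$csp_true[matched])
  sig <- truth$residue_id[matched & truth$csp_true > k * s]
  pos <- truth$residue_id[matched & truth$csp_true >= k_pos * s]
  neg <- truth$residue_id[matched & truth$effect_amp < 1e-3]
  cl <- cluster_residues(sig, sites, cutoff = cluster_cutoff,
                         observable = "csp")
  list(csp_significant = sort(sig), csp_positive = sort(pos),
       csp_negative = sort(neg),
       rex_above_apo = truth$residue_id[truth$rex_apo > rex_cutoff],
       rex_above_bound = truth$residue_id[truth$rex_bound > rex_cutoff],
       disappeared = sort(truth$residue_id[truth$disappeared]),
       csp_sd = s,
       clusters_csp = lapply(cl, function(x) x$members))
}

# ---- emission -------------------------------------------------------------

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Emit a complete synthetic study to disk
#'
#' Writes, for each state (`apo`, `bound`): an assigned peak list, R1 and
#' R2 decay-series tables, a CPMG dispersion intensity table (reference
#' plane as `nu_cpmg_hz = 0`), and a hetNOE saturated/reference pair
#' table; plus the apo and bound structures (PDB Calpha traces, the bound
#' one with planted B-factor increments), the ground-truth table, and a
#' JSON manifest recording every artifact, seed and setting.  All
#' intensities receive Gaussian noise of SD `noise * I0` (per-residue
#' reference intensity `I0`); chemical shifts receive noise of SD
#' `noise * 0.25` ppm (1H) and `noise * 1.0` ppm (15N), so `noise = 0`
#' reproduces the ground truth exactly.  Regenerating with the same seed
#' is byte-identical.
#'
#' @param truth A `study_truth` from [plant_allostery()].
#' @param sites Apo `residue_sites`.
#' @param schedule A [cpmg_schedule()].
#' @param noise Noise fraction (default 0.015).
#' @param rng_seed Integer seed for all emission randomness.
#' @param out_dir Output directory (created if needed).
#' @return An object of class `synthetic_study`: list with `paths` (named
#'   list of files), `truth`, `sites`, `sites_bound`, `schedule`, `noise`,
#'   `rng_seed`.
#' @export
emit_study <- function(truth, sites, schedule = cpmg_schedule(),
                       noise = 0.015, rng_seed = 1L, out_dir) {
  stopifnot(inherits(truth, "study_truth"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create output directory ", out_dir)
  ids <- truth$residue_id
  n <- length(ids)
  sig_floor <- function(i0) pmax(noise, 1e-8) * i0
  r1_delays <- c(0.02, 0.06, 0.12, 0.20, 0.32, 0.50, 0.80, 1.20)
  r2_delays <- c(0.004, 0.008, 0.016, 0.024, 0.032, 0.048, 0.064, 0.080)

  paths <- list()
  with_seed(rng_seed + 3000L, {
    i0 <- exp(stats::rnorm(n, 0, 0.15))      # per-residue peak intensity
    nz <- function(nn) if (noise > 0) stats::rnorm(nn, 0, noise) else
      numeric(nn)
    for (st in c("apo", "bound")) {
      keep <- if (st == "bound") !truth$disappeared else rep(TRUE, n)
      dh <- truth[[paste0("dh_", st)]] + noise * 0.25 *
        (if (noise > 0) stats::rnorm(n) else numeric(n))
      dn <- truth[[paste0("dn_", st)]] + noise * 1.0 *
        (if (noise > 0) stats::rnorm(n) else numeric(n))
      pk <- data.frame(residue_id = ids, residue_name = sites$residue_name,
                       delta_h_ppm = dh, delta_n_ppm = dn,
                       intensity = i0 * (1 + nz(n)),
                       sigma = sig_floor(i0))[keep, ]
      paths[[paste0("peaks_", st)]] <-
        .write_tsv(pk, file.path(out_dir, paste0("peaks_", st, ".tsv")))

      for (obs in c("r1", "r2")) {
        delays <- if (obs == "r1") r1_delays else r2_delays
        rate <- truth[[paste0(obs, "_", st)]]
        rows <- do.call(rbind, lapply(seq_len(n), function(j) {
          ii <- i0[j] * exp(-rate[j] * delays) + i0[j] * nz(length(delays))
          data.frame(residue = ids[j], delay_s = delays, intensity = ii,
                     sigma = sig_floor(i0[j]))
        }))
        paths[[paste0(obs, "_", st)]] <-
          .write_tsv(rows, file.path(out_dir, paste0(obs, "_", st, ".tsv")))
      }

      noe <- truth[[paste0("noe_", st)]]
      noe_rows <- data.frame(
        residue = rep(ids, 2L),
        experiment = rep(c("ref", "sat"), each = n),
        intensity = c(i0 * (1 + nz(n)), noe * i0 + i0 * nz(n)),
        sigma = rep(sig_floor(i0), 2L))
      paths[[paste0("noe_", st)]] <-
        .write_tsv(noe_rows, file.path(out_dir, paste0("noe_", st, ".tsv")))

      disp_rows <- do.call(rbind, lapply(seq_len(n), function(j) {
        pb <- truth[[paste0("pb_", st)]][j]
        pars <- if (is.na(pb))
          exchange_params(0, 0, 0, truth[[paste0("r2_", st)]][j])
        else
          exchange_params(pb, truth[[paste0("kex_", st)]][j],
                          truth[[paste0("dw_", st)]][j],
                          truth[[paste0("r2_", st)]][j],
                          truth[[paste0("r2_", st)]][j])
        r2eff <- propagate_cpmg(pars, schedule$t_relax, schedule$nu_cpmg)
        itrue <- i0[j] * exp(-r2eff * schedule$t_relax)
        data.frame(residue = ids[j],
                   nu_cpmg_hz = c(0, schedule$nu_cpmg),
                   intensity = c(i0[j], itrue) +
                     i0[j] * nz(length(itrue) + 1L),
                   sigma = sig_floor(i0[j]))
      }))
      paths[[paste0("cpmg_", st)]] <-
        .write_tsv(disp_rows, file.path(out_dir,
                                        paste0("cpmg_", st, ".tsv")))
    }
  })

  sites_bound <- sites
  es <- attr(truth, "effect_sizes")
  sites_bound$b_factor <- sites$b_factor + es$b_factor * truth$effect_amp
  paths$structure_apo <- file.path(out_dir, "structure_apo.pdb")
  write_structure(sites, paths$structure_apo)
  paths$structure_bound <- file.path(out_dir, "structure_bound.pdb")
  write_structure(sites_bound, paths$structure_bound)
  paths$ground_truth <- .write_tsv(as.data.frame(truth),
                                   file.path(out_dir, "ground_truth.tsv"))

  manifest <- list(
    generator = "nmrdyn synthetic two-state study",
    rng_seed = rng_seed, noise = noise,
    t_relax = schedule$t_relax, nu_cpmg = schedule$nu_cpmg,
    ligand_site = attr(truth, "ligand_site"),
    network_residues = attr(truth, "network_residues"),
    decay_length = attr(truth, "decay_length"),
    effect_sizes = attr(truth, "effect_sizes"),
    disappeared = attr(truth, "disappeared"),
    rex_above_apo = attr(truth, "rex_above_apo"),
    rex_above_bound = attr(truth, "rex_above_bound"),
    files = lapply(paths, basename))
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  structure(list(paths = paths, truth = truth, sites = sites,
                 sites_bound = sites_bound, schedule = schedule,
                 noise = noise, rng_seed = rng_seed, out_dir = out_dir),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic two-state study: %d residues, noise %.3g, seed %d\n",
              nrow(x$truth), x$noise, x$rng_seed))
  cat(sprintf("  %d files under %s\n", length(x$paths), x$out_dir))
  invisible(x)
}

#' Generate the default synthetic two-state study
#'
#' One-call wrapper building the toy structure, drawing the apo baseline,
#' planting the allosteric perturbation field (ligand site at residues
#' 95-105 in the C-terminal third, 8 distal network residues, 10 Angstrom
#' decay length), and emitting all files at the default 1.5% intensity
#' noise.
#'
#' @param out_dir Output directory.
#' @param n_res Number of residues (default 120).
#' @param seed Integer master seed; all stage seeds derive from it.
#' @param noise Intensity noise fraction (default 0.015; use 0 for the
#'   noiseless study).
#' @param schedule A [cpmg_schedule()].
#' @param ... Passed through to [plant_allostery()] (planted sets,
#'   effect sizes, decay length).
#' @return A `synthetic_study` object.
#' @examples
#' \donttest{
#' st <- generate_study(file.path(tempdir(), "study"), n_res = 60,
#'                      seed = 7, ligand_site = 40:46,
#'                      network_residues = c(8, 16, 24),
#'                      rex_above_bound = c(16, 41, 44),
#'                      rex_below_bound = c(20, 50),
#'                      rex_above_apo = c(41), rex_below_apo = c(20),
#'                      disappeared = c(39, 47))
#' }
#' @export
generate_study <- function(out_dir, n_res = 120, seed = 1L, noise = 0.015,
                           schedule = cpmg_schedule(), ...) {
  sites <- build_toy_structure(n_res, seed = seed)
  base <- baseline_truth(sites, seed = seed)
  truth <- plant_allostery(base, sites, schedule = schedule, seed = seed,
                           ...)
  emit_study(truth, sites, schedule = schedule, noise = noise,
             rng_seed = seed, out_dir = out_dir)
}
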