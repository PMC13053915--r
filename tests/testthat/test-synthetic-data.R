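# Synthetic study generator: geometry, planted effects, determinism and
# the declared noise model.

test_that("toy helix has canonical Calpha geometry", {
  sites <- build_toy_structure(50, seed = 1)
  expect_equal(nrow(sites), 50)
  d <- sqrt(diff(sites$x)^2 + diff(sites$y)^2 + diff(sites$z)^2)
  expect_true(all(abs(d - 3.8) < 0.1))
  # determinism
  expect_identical(build_toy_structure(50, seed = 1),
                   build_toy_structure(50, seed = 1))
  expect_error(build_toy_structure(10), "n_res")
})

test_that("planted effects decay with pocket distance; network is full-size", {
  sites <- build_toy_structure(60, seed = 4)
  base <- baseline_truth(sites, seed = 4)
  zero_fx <- list(delta_h = 0, delta_n = 0, r1 = 0, r2 = 0, noe = 0,
                  b_factor = 0)
  gt0 <- plant_allostery(base, sites, ligand_site = 40:46,
                         network_residues = c(8, 16),
                         effect_sizes = zero_fx,
                         rex_above_bound = integer(),
                         rex_below_bound = integer(),
                         rex_above_apo = integer(),
                         rex_below_apo = integer(),
                         disappeared = integer(), seed = 4)
  expect_equal(gt0$dh_bound, gt0$dh_apo)
  expect_equal(gt0$r2_bound, gt0$r2_apo)
  expect_true(all(gt0$csp_true == 0))
  gt <- plant_allostery(base, sites, ligand_site = 40:46,
                        network_residues = c(8, 16),
                        rex_above_bound = c(16, 41),
                        rex_below_bound = c(20),
                        rex_above_apo = c(41), rex_below_apo = integer(),
                        disappeared = c(39), seed = 4)
  fx <- study_effect_sizes()
  # the shift change factors through one amplitude: |dH|/eH == |dN|/eN
  expect_equal(abs(gt$dh_bound - gt$dh_apo) / fx$delta_h,
               abs(gt$dn_bound - gt$dn_apo) / fx$delta_n,
               tolerance = 1e-9)
  amp <- abs(gt$dh_bound - gt$dh_apo) / fx$delta_h
  w <- exp(-gt$d_pocket / 10)
  non_net <- !gt$network
  # amplitude bounded by the multiplier range times the distance decay
  expect_true(all(amp[non_net] <= 2.0 * w[non_net] + 1e-9))
  expect_true(all(amp[non_net] >= 0.8 * w[non_net] - 1e-9))
  # pocket residues at d = 0; a residue 3 decay lengths out keeps ~5%
  expect_true(all(gt$d_pocket[gt$pocket] == 0))
  far <- which(!gt$network & abs(gt$d_pocket - 30) < 2)
  expect_true(all(amp[far] < 2.0 * exp(-28 / 10)))
  # network residues get full-size (distance-independent) effects
  expect_true(all(amp[gt$network] >= 1.5 - 1e-9))
  # planted exchange lands on the stated Rex bands
  expect_true(all(gt$rex_bound[gt$residue_id %in% c(16, 41)] > 11 - 0.5))
  expect_true(gt$rex_bound[gt$residue_id == 20] < 4.5 + 0.5)
  expect_true(all(gt$rex_bound[is.na(gt$pb_bound)] == 0))
  expect_error(plant_allostery(base, sites, ligand_site = 40:46,
                               network_residues = c(999), seed = 1),
               "outside structure")
})

test_that("emission is byte-identical under the same seed", {
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  st1 <- small_study(d1, seed = 33)
  st2 <- small_study(d2, seed = 33)
  for (nm in names(st1$paths)) {
    expect_identical(readLines(st1$paths[[nm]]),
                     readLines(st2$paths[[nm]]),
                     label = paste("file", nm))
  }
})

test_that("default study emits every consumed format, under 5 MB", {
  dir <- file.path(tempdir(), "full_default")
  st <- generate_study(dir, n_res = 120, seed = 2, noise = 0.015)
  expect_setequal(
    setdiff(names(st$paths), "manifest"),
    c(paste0(rep(c("peaks_", "r1_", "r2_", "noe_", "cpmg_"), 2),
             rep(c("apo", "bound"), each = 5)),
      "structure_apo", "structure_bound", "ground_truth"))
  sizes <- file.size(unlist(st$paths))
  expect_lt(sum(sizes), 5e6)
  # disappeared residues are absent from the bound peak list only
  pa <- read_peaklist(st$paths$peaks_apo)
  pb <- read_peaklist(st$paths$peaks_bound)
  gone <- attr(st$truth, "disappeared")
  expect_true(all(gone %in% pa$residue_id))
  expect_false(any(gone %in% pb$residue_id))
  # manifest records seed and settings
  man <- jsonlite::read_json(st$paths$manifest, simplifyVector = TRUE)
  expect_equal(man$rng_seed, 2)
  expect_equal(man$noise, 0.015)
})

test_that("emitted intensity noise is Gaussian with the declared SD", {
  sch <- cpmg_schedule(nu_cpmg = c(100, 500, 1000, 2000))
  p <- exchange_params(0, 0, 0, 12)
  draws <- unlist(lapply(seq_len(2000), function(i) {
    cu <- simulate_dispersion(p, sch, 0.015, rng_seed = 5000 + i)
    attr(cu, "intensities")$intensity
  }))
  true_i <- c(1, exp(-12 * sch$t_relax) * rep(1, 4))
  resid <- (draws - rep(true_i, 2000)) / 0.015
  expect_gte(length(resid), 1e4)
  ks <- stats::ks.test(resid, "pnorm")
  expect_gt(ks$p.value, 0.01)
  expect_equal(stats::sd(resid), 1, tolerance = 0.05)
})
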