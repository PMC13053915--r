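# PDB site reading/writing, B-factor normalization and spatial clustering.

test_that("structure writing and reading round-trip", {
  sites <- build_toy_structure(30, seed = 5)
  tmp <- tempfile(fileext = ".pdb")
  write_structure(sites, tmp)
  rt <- read_structure(tmp)
  expect_equal(nrow(rt), 30)
  expect_equal(rt$residue_id, sites$residue_id)
  expect_equal(rt$x, sites$x, tolerance = 1e-3)
  expect_equal(rt$y, sites$y, tolerance = 1e-3)
  expect_equal(rt$z, sites$z, tolerance = 1e-3)
  expect_equal(rt$b_factor, sites$b_factor, tolerance = 0.01)
  expect_equal(rt$residue_name, sites$residue_name)
})

test_that("altloc resolution keeps the highest occupancy; icodes rejected", {
  mk <- function(serial, alt, res, occ, icode = " ")
    sprintf("ATOM  %5d  CA %sALA A%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            serial, alt, res, icode, 1.0, 2.0, 3.0 + res, occ, 20.0)
  f <- tempfile(fileext = ".pdb")
  writeLines(c(mk(1, "A", 1, 0.60), mk(2, "B", 1, 0.40),
               mk(3, " ", 2, 1.00), "END"), f)
  sites <- read_structure(f)
  expect_equal(nrow(sites), 2)
  expect_equal(sites$residue_id, c(1, 2))
  f2 <- tempfile(fileext = ".pdb")
  writeLines(c(mk(1, " ", 1, 1), mk(2, " ", 1, 1, "A"), "END"), f2)
  expect_error(read_structure(f2), "insertion codes")
  f3 <- tempfile(fileext = ".pdb")
  writeLines("REMARK nothing", f3)
  expect_error(read_structure(f3), "no ATOM")
  expect_error(read_structure(f, chain = "Z"), "chain")
})

test_that("B-factor z-scores normalize per chain and detect perturbation", {
  sites <- build_toy_structure(40, seed = 2)
  z <- normalize_bfactors(sites)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(stats::sd(z), 1, tolerance = 1e-10)
  # same structure twice: zero difference everywhere
  cmp <- compare_bfactors(sites, sites)
  expect_true(all(abs(cmp$delta_z) < 1e-12))
  # a single epsilon perturbation on flat B carries all the signal
  flat <- sites
  flat$b_factor <- rep(20, 40)
  flat$b_factor[7] <- 20.001
  zf <- normalize_bfactors(flat)
  expect_equal(which.max(zf), 7, ignore_attr = TRUE)
  flat$b_factor <- rep(20, 40)
  expect_error(normalize_bfactors(flat), "zero variance")
})

test_that("single-linkage clusters equal thresholded-graph components", {
  line_sites <- function(xs) {
    df <- data.frame(residue_id = seq_along(xs), chain_id = "A",
                     residue_name = "ALA", x = xs, y = 0, z = 0,
                     b_factor = 20)
    class(df) <- c("residue_sites", "data.frame")
    df
  }
  s <- line_sites(c(0, 5, 100))
  cl <- cluster_residues(c(1, 2), s, cutoff = 8)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$members, c(1, 2))
  expect_equal(cl[[1]]$diameter, 5)
  s2 <- line_sites(c(0, 12))
  expect_length(cluster_residues(c(1, 2), s2, cutoff = 8), 2)
  # chain 0-6-12: endpoints 12 apart but single linkage joins all three
  s3 <- line_sites(c(0, 6, 12))
  cl3 <- cluster_residues(1:3, s3, cutoff = 8)
  expect_length(cl3, 1)
  expect_equal(cl3[[1]]$members, 1:3)
  expect_equal(sort_clusters(lapply(cl3, `[[`, "members")),
               brute_components(1:3, s3, 8))
  # singleton
  cl1 <- cluster_residues(5, build_toy_structure(20), cutoff = 8)
  expect_length(cl1, 1)
  expect_equal(cl1[[1]]$diameter, 0)
  # unknown residues are excluded with a warning
  expect_warning(cluster_residues(c(1, 999), build_toy_structure(20)),
                 "excluded")
})

test_that("clustering is invariant under rigid motion and monotone in cutoff", {
  sites <- build_toy_structure(50, seed = 8)
  ids <- c(3, 4, 5, 12, 13, 30, 44, 45, 46, 47)
  base <- sort_clusters(lapply(cluster_residues(ids, sites, 8),
                               `[[`, "members"))
  set.seed(31)
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  xyz <- as.matrix(sites[, c("x", "y", "z")]) %*% Q
  rot <- sites
  rot$x <- xyz[, 1] + 100; rot$y <- xyz[, 2] - 50; rot$z <- xyz[, 3] + 7
  expect_equal(sort_clusters(lapply(cluster_residues(ids, rot, 8),
                                    `[[`, "members")), base)
  ns <- vapply(c(4, 6, 8, 12, 20, 1000), function(ct)
    length(cluster_residues(ids, sites, ct)), integer(1))
  expect_true(all(diff(ns) <= 0))
  # brute-force oracle agreement on random subsets
  set.seed(77)
  for (i in 1:20) {
    sub <- sort(sample(sites$residue_id, sample(2:20, 1)))
    expect_equal(
      sort_clusters(lapply(cluster_residues(sub, sites, 8),
                           `[[`, "members")),
      brute_components(sub, sites, 8))
  }
})

test_that("score-annotated structures carry scores in the B column", {
  sites <- build_toy_structure(25, seed = 3)
  scores <- stats::setNames(seq(0, 4.8, by = 0.2), sites$residue_id)
  scores <- scores[-5]   # residue 5 unscored -> sentinel
  out <- tempfile(fileext = ".pdb")
  write_score_structure(sites, scores, out)
  rt <- read_structure(out)
  expect_equal(rt$b_factor[rt$residue_id == 5], -1)
  keep <- rt$residue_id != 5
  expect_equal(rt$b_factor[keep],
               unname(scores[as.character(rt$residue_id[keep])]),
               tolerance = 0.006)
  # fixed-width layout per the PDB spec: record name, coordinate and
  # B-factor columns at their exact positions
  lines <- readLines(out)
  atom <- lines[startsWith(lines, "ATOM")]
  expect_true(all(nchar(atom) == 78))
  expect_true(all(substr(atom, 13, 16) == " CA "))
  expect_true(all(grepl("^[ 0-9-]*\\.[0-9]{3}$", substr(atom, 31, 38))))
  expect_true(all(grepl("^[ 0-9-]*\\.[0-9]{2}$", substr(atom, 61, 66))))
  expect_true(all(substr(atom, 22, 22) == "A"))
  # overflowing scores are scaled into the column, with a message
  expect_message(
    write_score_structure(sites, stats::setNames(rep(1e5, 25),
                                                 sites$residue_id),
                          tempfile(fileext = ".pdb")),
    "scaled")
})
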