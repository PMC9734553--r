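test_that("bead chemistry decorates charges and aromatics", {
  expect_equal(assign_bead_chemistry("DEKR")$charges, c(-1, -1, 1, 1))
  expect_false(any(assign_bead_chemistry("DEKR")$aromatic))
  chem <- assign_bead_chemistry("FYW")
  expect_equal(chem$charges, c(0, 0, 0))
  expect_true(all(chem$aromatic))
  expect_equal(assign_bead_chemistry("PRPR")$charges, c(0, 1, 0, 1))
  ## histidine is neutral by convention
  expect_equal(assign_bead_chemistry("H")$charges, 0L)
  expect_error(assign_bead_chemistry("AXB"), "position 2")
})

test_that("NCPR is exact integer arithmetic", {
  for (n in c(1, 7, 25, 50))
    expect_identical(
      compute_ncpr(assign_bead_chemistry(strrep("PR", n))$charges), 0.5)
  expect_identical(compute_ncpr(assign_bead_chemistry("DE")$charges), -1)
  expect_identical(compute_ncpr(assign_bead_chemistry("DKDKAA")$charges), 0)
  expect_error(compute_ncpr(numeric(0)), "empty")
})

test_that("poly-PR models have the stated composition and geometry", {
  m7 <- build_polypr(7)
  expect_equal(nchar(m7$sequence), 14)
  expect_equal(sum(m7$charges), 7)
  expect_false(any(m7$structured))
  expect_equal(nrow(m7$elastic), 0)
  expect_identical(compute_ncpr(build_polypr(25)), 0.5)
  expect_equal(build_polypr(50)$charges, rep(c(0L, 1L), 50))
  ## consecutive bead spacing is exactly the backbone bond length
  d <- sqrt(rowSums((m7$positions[-1, ] - m7$positions[-14, ])^2))
  expect_equal(d, rep(0.38, 13), tolerance = 1e-12)
  expect_error(build_polypr(0), ">= 1")
})

test_that("elastic network matches a brute-force all-pairs scan", {
  pos <- rbind(c(0, 0, 0), c(0.38, 0, 0), c(0.76, 0, 0))
  en <- build_elastic_network(pos, rep(TRUE, 3), cutoff = 0.8)
  expect_equal(en$i, 1L)
  expect_equal(en$j, 3L)
  expect_equal(en$r0, 0.76)
  expect_equal(nrow(build_elastic_network(pos, rep(TRUE, 3), cutoff = 0.5)),
               0)
  expect_error(build_elastic_network(pos, rep(TRUE, 3), cutoff = 0.3),
               "degenerate")
  ## random 50-bead globule vs O(N^2) oracle
  set.seed(99)
  gp <- matrix(rnorm(150, sd = 1.2), 50, 3)
  struct <- runif(50) > 0.2
  en <- build_elastic_network(gp, struct, cutoff = 1.4)
  oracle <- NULL
  for (i in 1:48) for (j in (i + 2):50) {
    if (!struct[i] || !struct[j]) next
    r <- sqrt(sum((gp[i, ] - gp[j, ])^2))
    if (r <= 1.4) oracle <- rbind(oracle, c(i, j, r))
  }
  expect_equal(nrow(en), nrow(oracle))
  expect_equal(en$i, oracle[, 1])
  expect_equal(en$j, oracle[, 2])
  expect_equal(en$r0, oracle[, 3])
})

test_that("Calpha traces parse with missing residues and unit conversion", {
  ## expected values frozen from an independent parser (Biopython) on the
  ## same fixture: residues 1,2,4,5,6 observed, residue 3 unresolved
  tr <- parse_calpha_trace(pdb_fixture_lines())
  expect_equal(paste(tr$sequence, collapse = ""), "AGDFKE")
  expect_equal(tr$resolved, c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(tr$positions[1, ], c(0, 0, 0))
  expect_equal(tr$positions[2, ], c(0.38, 0, 0))
  expect_true(all(is.na(tr$positions[3, ])))
  expect_equal(tr$positions[4, ], c(1.10, 0, 0))
  expect_equal(tr$positions[5, ], c(1.48, 0, 0.2))
  expect_equal(tr$positions[6, ], c(1.86, 0, 0))
})

test_that("altloc duplicates keep highest occupancy, with a warning", {
  expect_warning(tr <- parse_calpha_trace(pdb_fixture_altloc()), "altloc")
  expect_equal(tr$positions[2, 1], 0.39)   # occupancy 0.60 wins
})

test_that("parser errors are explicit", {
  expect_error(parse_calpha_trace("REMARK nothing here"), "no protein CA")
  expect_error(parse_calpha_trace(pdb_fixture_two_chains()),
               "select one explicitly")
  trB <- parse_calpha_trace(pdb_fixture_two_chains(), chain = "B")
  expect_equal(paste(trB$sequence, collapse = ""), "KE")
})

test_that("missing regions are grown without moving resolved beads", {
  tr <- parse_calpha_trace(pdb_fixture_lines())
  m <- model_missing_regions(tr, seed = 5)
  expect_s3_class(m, "cg_model")
  expect_equal(m$structured, tr$resolved)
  expect_equal(m$positions[tr$resolved, ],
               tr$positions[tr$resolved, ])
  ## the bridged bead keeps backbone-like spacing to both anchors
  d23 <- sqrt(sum((m$positions[3, ] - m$positions[2, ])^2))
  d34 <- sqrt(sum((m$positions[4, ] - m$positions[3, ])^2))
  expect_true(all(c(d23, d34) > 0.3 & c(d23, d34) < 0.46))
  ## no elastic pair touches the disordered bead
  expect_false(any(m$elastic$i == 3 | m$elastic$j == 3))
})

test_that("fully resolved traces pass through unchanged", {
  tr <- parse_calpha_trace(pdb_fixture_two_chains(), chain = "A")
  m <- model_missing_regions(tr)
  expect_equal(m$positions, tr$positions)
  expect_true(all(m$structured))
})

test_that("interior loops and terminal tails are built to spec", {
  ## 5-residue unresolved loop between anchors 1.5 nm apart
  n <- 12
  pos <- matrix(NA_real_, n, 3)
  resolved <- rep(TRUE, n)
  resolved[5:9] <- FALSE
  for (i in 1:4) pos[i, ] <- c(0.38 * (i - 1), 0, 0)
  pos[10, ] <- pos[4, ] + c(1.5, 0, 0)
  for (i in 11:12) pos[i, ] <- pos[10, ] + c(0.38 * (i - 10), 0, 0)
  tr <- list(sequence = strsplit("AAAAGGGGGAAA", "")[[1]],
             positions = pos, resolved = resolved)
  for (seed in 1:5) {
    m <- model_missing_regions(tr, seed = seed)
    expect_equal(m$positions[resolved, ], pos[resolved, ])
    d <- sqrt(rowSums((m$positions[5:10, ] - m$positions[4:9, ])^2))
    expect_true(all(d > 0.30 & d < 0.46))
  }
  ## unbridgeable gap errors
  pos2 <- pos; pos2[10, ] <- pos2[4, ] + c(4, 0, 0)
  tr2 <- tr; tr2$positions <- pos2
  expect_error(model_missing_regions(tr2), "not bridgeable")
  ## terminal tail of 10 residues: appended, untouched by the network
  n3 <- 16
  pos3 <- matrix(NA_real_, n3, 3)
  res3 <- c(rep(TRUE, 6), rep(FALSE, 10))
  for (i in 1:6) pos3[i, ] <- c(0.38 * (i - 1), 0.1 * (i %% 2), 0)
  tr3 <- list(sequence = rep("A", n3), positions = pos3, resolved = res3)
  m3 <- model_missing_regions(tr3, seed = 2)
  expect_false(any(m3$structured[7:16]))
  expect_false(any(m3$elastic$i > 6 | m3$elastic$j > 6))
})

test_that("model serialization round-trips bit-for-bit", {
  toy <- small_toy()
  path <- tempfile(fileext = ".json")
  write_cg_model(toy$model, path)
  back <- read_cg_model(path)
  expect_identical(back, toy$model)
  expect_error(read_cg_model({
    p <- tempfile(); writeLines('{"format":"other"}', p); p
  }), "not a kapcg model")
})

test_that("annotations and binding sites validate and round-trip", {
  ann <- region_annotation(c(1, 5, 9), c(4, 8, 12), c(1, 1, 1),
                           c("A", "B", "linker"))
  p <- tempfile(fileext = ".tsv")
  write_region_annotation(ann, p)
  expect_equal(read_region_annotation(p), ann)
  expect_error(region_annotation(c(1, 3), c(4, 8), c(1, 1), c("A", "B")),
               "overlapping")
  expect_error(region_annotation(1, 4, 1, "C"), "labels")

  bs <- binding_site_set(cargo = c(3, 5), rangtp = 9, n_residues = 12)
  p2 <- tempfile(fileext = ".tsv")
  write_binding_sites(bs, p2)
  expect_equal(read_binding_sites(p2), bs)
  expect_length(bs$ibb, 0)
  expect_error(binding_site_set(cargo = 99, n_residues = 12), "outside")
})

test_that("cg_model invariants are enforced", {
  expect_error(cg_model("AAA", matrix(0, 2, 3)), "3 x 3")
  m <- build_polypr(3)
  m$charges[1] <- 2L
  expect_error(validate_cg_model(m), "-1, 0")
})
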