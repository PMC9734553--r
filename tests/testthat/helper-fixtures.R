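# shared fixtures: tiny PDB texts and model builders (all generated in code)

# 6-residue chain A with SEQRES; residue 3 (ASP) missing from ATOM records.
# Gap anchors are 0.72 nm apart, bridgeable by one bead at 0.38 nm bonds.
pdb_fixture_lines <- function() c(
  "HEADER    TEST FIXTURE",
  "SEQRES   1 A    6  ALA GLY ASP PHE LYS GLU",
  "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
  "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
  "ATOM      4  CA  PHE A   4      11.000   0.000   0.000  1.00  0.00           C",
  "ATOM      5  CA  LYS A   5      14.800   0.000   2.000  1.00  0.00           C",
  "ATOM      6  CA  GLU A   6      18.600   0.000   0.000  1.00  0.00           C",
  "END")

# duplicate altloc CA records for residue 2 (occupancies 0.40 / 0.60)
pdb_fixture_altloc <- function() c(
  "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
  "ATOM      2  CA AGLY A   2       3.800   0.000   0.000  0.40  0.00           C",
  "ATOM      3  CA BGLY A   2       3.900   0.000   0.000  0.60  0.00           C",
  "ATOM      4  CA  ASP A   3       7.600   0.000   0.000  1.00  0.00           C",
  "END")

pdb_fixture_two_chains <- function() c(
  "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
  "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
  "ATOM      3  CA  LYS B   1      10.000   0.000   0.000  1.00  0.00           C",
  "ATOM      4  CA  GLU B   2      13.800   0.000   0.000  1.00  0.00           C",
  "END")

no_elastic <- function()
  data.frame(i = integer(0), j = integer(0), r0 = numeric(0))

# small single-bead / few-bead models at explicit positions
bead_model <- function(seq, pos, structured = FALSE, ...) {
  pos <- matrix(pos, ncol = 3, byrow = TRUE)
  cg_model(seq, pos, structured = rep(structured, nchar(seq)),
           elastic = no_elastic(), ...)
}

# random mixed-role configuration exercising every force-field term
random_mixed_system <- function(params, seed, box = 0) {
  set.seed(seed)
  pr <- build_polypr(4, seed = seed + 500)
  kseq <- paste(sample(c("D", "E", "R", "K", "F", "S", "A", "G", "P"),
                       8, replace = TRUE), collapse = "")
  ## compact chain at near-backbone spacing so bonded energies stay at
  ## physical magnitudes (finite differences drown in roundoff otherwise)
  repeat {
    kpos <- matrix(0, 8, 3)
    for (t in 2:8) {
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      kpos[t, ] <- kpos[t - 1, ] + (0.38 + rnorm(1, 0, 0.02)) * dir
    }
    dmat <- as.matrix(dist(kpos))
    sep <- abs(row(dmat) - col(dmat))
    if (min(dmat[sep > 1]) > 0.45) break
  }
  struct <- c(rep(TRUE, 5), rep(FALSE, 3))
  kap <- cg_model(kseq, kpos, structured = struct, chain_id = "K")
  sys <- build_system(list(kap, pr), c("kap", "pr"), params, box = box)
  ## pull the PR chain near the receptor so nonbonded terms engage, but
  ## keep a physical separation: finite differences are meaningless on
  ## the near-singular excluded-volume wall
  prbeads <- which(sys$chain_map$role == "pr")
  prpos <- sweep(sys$positions[prbeads, ], 2,
                 colMeans(sys$positions[prbeads, ]))
  repeat {
    shift <- c(1.0, 0.3, 0.2) + runif(3, -0.4, 0.4)
    cand <- sweep(prpos, 2, shift, "+")
    dmin <- min(as.matrix(dist(rbind(cand, kpos)))[
      seq_len(nrow(cand)), nrow(cand) + seq_len(nrow(kpos))])
    if (dmin > 0.40) break
  }
  sys$positions[prbeads, ] <- cand
  sys
}

# Kabsch-aligned RMSD between two coordinate sets
kabsch_rmsd <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P)); Q <- sweep(Q, 2, colMeans(Q))
  S <- svd(t(P) %*% Q)
  d <- sign(det(S$v %*% t(S$u)))
  R <- S$v %*% diag(c(1, 1, d)) %*% t(S$u)
  sqrt(mean(rowSums((Q - P %*% t(R))^2)))
}

# brute-force min-image contact count (independent R oracle)
brute_contacts <- function(posA, posB, box, cutoff = 1.0) {
  count <- 0L
  fA <- logical(nrow(posA)); fB <- logical(nrow(posB))
  for (i in seq_len(nrow(posA)))
    for (j in seq_len(nrow(posB))) {
      d <- posA[i, ] - posB[j, ]
      if (box > 0) d <- d - box * round(d / box)
      if (sum(d * d) <= cutoff^2) {
        count <- count + 1L; fA[i] <- TRUE; fB[j] <- TRUE
      }
    }
  list(count = count, flagsA = fA, flagsB = fB)
}

# small, quick toy receptor shared across analysis tests
small_toy <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_toy_solenoid(
        solenoid_spec(n_repeats = 4, helix_len = 6, seed = 7))
    cache
  }
})
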