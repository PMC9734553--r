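test_that("Debye length matches the closed form and scaling law", {
  ## independent evaluation of the closed form with CODATA constants
  lam_ref <- function(salt, T, er) {
    eps0 <- 8.8541878128e-12; e <- 1.602176634e-19
    NA_ <- 6.02214076e23; kB <- 1.380649e-23
    sqrt(eps0 * er * kB * T / (2 * NA_ * e^2 * salt)) * 1e9
  }
  l100 <- debye_length(100, 300, 80)
  expect_equal(l100, lam_ref(100, 300, 80), tolerance = 1e-12)
  expect_equal(l100, 0.975, tolerance = 2e-3)
  expect_equal(debye_length(200, 300, 80), l100 / sqrt(2),
               tolerance = 1e-12)
  ## monotone vanishing at high salt
  salts <- 10^seq(2, 6, by = 0.5)
  lams <- debye_length(salts, 300, 80)
  expect_true(all(diff(lams) < 0))
  expect_lt(lams[length(lams)], 0.01)
  expect_error(debye_length(0), "> 0")
})

test_that("screened Coulomb pair energy behaves as specified", {
  p <- ff_params(salt_mM = 100)
  r <- seq(0.3, 1.9, by = 0.1)
  expect_equal(electrostatic_pair_energy(0, 1, r, p), rep(0, length(r)))
  expect_true(all(electrostatic_pair_energy(1, -1, r, p) < 0))
  expect_true(all(electrostatic_pair_energy(1, 1, r, p) > 0))
  ## at r = lambda_D the unshifted screened value is e^-1 of unscreened
  lam <- p$lambda_d
  u <- electrostatic_pair_energy(1, -1, lam, p, shifted = FALSE)
  u0 <- p$coulomb * 1 * -1 / (p$epsilon_r * lam)
  expect_equal(u / u0, exp(-1), tolerance = 1e-12)
  expect_error(electrostatic_pair_energy(1, 1, 0, p), "> 0")
  ## screening monotonicity: magnitude falls with salt
  us <- sapply(c(50, 100, 200, 400), function(s)
    abs(electrostatic_pair_energy(1, -1, 0.8, ff_params(salt_mM = s))))
  expect_true(all(diff(us) < 0))
})

test_that("cation-pi well has exact depth, range and cutoff", {
  p <- ff_params()
  expect_equal(cation_pi_pair_energy(p$catpi_sigma, p), -p$catpi_depth)
  expect_identical(cation_pi_pair_energy(p$cutoff, p), 0)
  expect_identical(cation_pi_pair_energy(3.0, p), 0)
  ## dense scan recovers the configured minimum location
  r <- seq(0.30, 1.50, by = 1e-4)
  u <- cation_pi_pair_energy(r, p)
  expect_equal(r[which.min(u)], p$catpi_sigma, tolerance = 1e-3)
  ## continuity at the cutoff
  expect_lt(abs(cation_pi_pair_energy(p$cutoff - 1e-9, p)), 1e-6)
})

test_that("excluded volume is repulsive, monotone, and compactly supported", {
  p <- ff_params()
  s <- p$ev_sigma
  expect_identical(excluded_volume_pair_energy(s, p), 0)
  expect_identical(excluded_volume_pair_energy(s * 1.5, p), 0)
  u_half <- excluded_volume_pair_energy(s / 2, p)
  u_close <- excluded_volume_pair_energy(0.9 * s, p)
  expect_gt(u_half, u_close)
  expect_gt(u_close, 0)
  r <- seq(0.2, s - 1e-9, length.out = 200)
  expect_true(all(diff(excluded_volume_pair_energy(r, p)) < 0))
  ## force continuity at the diameter (WCA form: zero slope at sigma)
  h <- 1e-7
  expect_lt(abs(excluded_volume_pair_energy(s - h, p)) / h, 1e-4)
})

test_that("engine nonbonded energies equal the R reference potentials", {
  ## dual route: independent R-side accumulation with the pair-class
  ## rules vs the C++ engine with its Verlet list
  for (seed in c(3, 17, 42)) {
    for (mode in c("constant", "distance")) {
      params <- ff_params(salt_mM = 150, eps_mode = mode)
      sys <- random_mixed_system(params, seed)
      en <- total_forces(sys, params)$energy
      ref <- list(elec = 0, catpi = 0, ev = 0, hp = 0)
      n <- sys$n
      excl <- paste(sys$exclusions[, 1], sys$exclusions[, 2])
      hyd <- sys$hyd
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        if (paste(i, j) %in% excl || paste(j, i) %in% excl) next
        r <- sqrt(sum((sys$positions[i, ] - sys$positions[j, ])^2))
        if (r >= params$cutoff) next
        same <- sys$chain[i] == sys$chain[j]
        pri <- sys$is_pr[i]; prj <- sys$is_pr[j]
        ref$ev <- ref$ev + excluded_volume_pair_energy(r, params)
        qq <- sys$charge[i] * sys$charge[j]
        if (qq != 0 && !(same && !pri && !prj))
          ref$elec <- ref$elec +
            electrostatic_pair_energy(sys$charge[i], sys$charge[j], r,
                                      params)
        if (pri != prj &&
            ((sys$charge[i] > 0 && sys$aromatic[j]) ||
             (sys$charge[j] > 0 && sys$aromatic[i])))
          ref$catpi <- ref$catpi + cation_pi_pair_energy(r, params)
        if (pri && prj)
          ref$hp <- ref$hp +
            hydrophobic_pair_energy(r, hyd[i], hyd[j], params)
      }
      expect_equal(en$elec, ref$elec, tolerance = 1e-10)
      expect_equal(en$catpi, ref$catpi, tolerance = 1e-10)
      expect_equal(en$ev, ref$ev, tolerance = 1e-10)
      expect_equal(en$hydrophobic, ref$hp, tolerance = 1e-10)
    }
  }
})

test_that("bonded energies match closed forms and an independent oracle", {
  params <- ff_params()
  ## crystal geometry: elastic term is exactly zero
  toy <- small_toy()
  be <- bonded_energy(toy$model, params = params)
  expect_equal(be$elastic, 0, tolerance = 1e-20)
  ## single stretched backbone bond: (k/2) delta^2
  delta <- 0.013
  m2 <- bead_model("AS", c(0, 0, 0, 0.38 + delta, 0, 0))
  be2 <- bonded_energy(m2, params = params)
  expect_equal(be2$backbone, 0.5 * params$backbone_k * delta^2,
               tolerance = 1e-10)
  expect_equal(be2$angle, 0)
  ## disordered 4-bead chain vs independent R evaluation of the formulas
  set.seed(8)
  pos <- build_polypr(2, seed = 3)$positions + matrix(rnorm(12, sd = 0.05),
                                                      4, 3)
  m4 <- cg_model("PRPR", pos, structured = rep(FALSE, 4),
                 elastic = no_elastic())
  be4 <- bonded_energy(m4, params = params)
  bb <- 0
  for (i in 1:3) {
    r <- sqrt(sum((pos[i + 1, ] - pos[i, ])^2))
    bb <- bb + 0.5 * params$backbone_k * (r - params$backbone_r0)^2
  }
  ang <- 0
  for (j in 2:3) {
    cls <- if (substr("PRPR", j, j) == "P") "P" else "other"
    u <- pos[j - 1, ] - pos[j, ]; v <- pos[j + 1, ] - pos[j, ]
    th <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
    ang <- ang + 0.5 * params$angle_k[[cls]] *
      (th - params$angle_theta0[[cls]])^2
  }
  b1 <- pos[2, ] - pos[1, ]; b2 <- pos[3, ] - pos[2, ]
  b3 <- pos[4, ] - pos[3, ]
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  phi <- atan2(sum(cr(n1, n2) * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
  dih <- params$dihedral_k[["other"]] * (1 + cos(phi))  # R is class "other"
  expect_equal(be4$backbone, bb, tolerance = 1e-10)
  expect_equal(be4$angle, ang, tolerance = 1e-10)
  expect_equal(be4$dihedral, dih, tolerance = 1e-10)
  expect_error(bonded_energy(m4, positions = NULL), "positions")
})

test_that("forces obey Newton's third law and translation invariance", {
  params <- ff_params(salt_mM = 100)
  sys <- random_mixed_system(params, 11, box = 8)
  out <- total_forces(sys, params)
  expect_lt(max(abs(colSums(out$forces))), 1e-9)
  shifted <- total_forces(sys, params,
                          positions = sys$positions + c(1.3))
  expect_equal(shifted$energy$total, out$energy$total, tolerance = 1e-9)
  expect_equal(shifted$forces, out$forces, tolerance = 1e-7)
})

test_that("PR near a negative surface binds tighter at lower salt", {
  ## fixed geometry: a PR chain 0.7 nm above a row of aspartates
  kap <- bead_model(strrep("D", 10),
                    as.vector(t(cbind(0.38 * (0:9), 0, 0))),
                    structured = TRUE, chain_id = "D10")
  pr <- build_polypr(5, seed = 2)
  pr$positions <- cbind(0.38 * (0:9), 0.7, 0)
  for (salt in list(c(100, 200))) {
    e <- sapply(salt, function(s) {
      sys <- build_system(list(kap, pr), c("kap", "pr"),
                          ff_params(salt_mM = s), box = 0)
      total_forces(sys, ff_params(salt_mM = s))$energy$elec
    })
    expect_lt(e[1], e[2])   # more attractive at 100 mM
    expect_true(all(e < 0))
  }
})

test_that("overlapping beads raise an error naming the pair", {
  params <- ff_params()
  a <- bead_model("D", c(0, 0, 0))
  b <- bead_model("R", c(1e-6, 0, 0))
  sys <- build_system(list(a, b), c("kap", "pr"), params, box = 0)
  expect_error(total_forces(sys, params), "overlapping beads 1 and 2")
})

test_that("parameter validation and the shipped defaults file work", {
  expect_error(ff_params(cutoff = 0.3), "smaller than an interaction")
  expect_error(ff_params(nonsense = 1), "unknown ff parameter")
  expect_error(ff_params(salt_mM = -5), "> 0")
  f <- system.file("extdata", "ff_defaults.cfg", package = "kapcg")
  p <- ff_params(file = f)
  expect_equal(p$cutoff, 2.0)
  expect_equal(p$salt_mM, 200)
  ## energy report TSV
  path <- tempfile(fileext = ".tsv")
  write_energy_report(list(elec = -1.5, ev = 0.2), path)
  d <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(d$energy_kJ_mol, c(-1.5, 0.2))
})
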