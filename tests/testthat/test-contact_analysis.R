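test_that("frame contacts match the brute-force double loop", {
  ## single contact pair
  traj <- generate_fixture_trajectory(list(cbind(1, 1)), n_pr = 3,
                                      n_kap = 4)
  fc <- frame_contacts(traj$frames[, , 1], traj$chain_map, box = 0)
  expect_equal(fc$count, 1)
  expect_equal(sum(fc$pr_flags), 1)
  expect_equal(sum(fc$kap_flags), 1)
  ## nothing within 1 nm
  traj0 <- generate_fixture_trajectory(list(NULL), n_pr = 3, n_kap = 4)
  fc0 <- frame_contacts(traj0$frames[, , 1], traj0$chain_map, box = 0)
  expect_equal(fc0$count, 0)
  ## 200 random frames, with and without periodic wrapping
  set.seed(21)
  cm <- data.frame(chain = rep(c(1L, 2L), c(30, 40)),
                   role = rep(c("pr", "kap"), c(30, 40)))
  for (f in 1:200) {
    box <- if (f %% 2 == 0) 5 else 0
    pos <- matrix(runif(210, -6, 6), 70, 3)
    got <- frame_contacts(pos, cm, box = box, cutoff = 1.0)
    want <- brute_contacts(pos[1:30, ], pos[31:70, ], box, 1.0)
    expect_identical(got$count, want$count)
    expect_identical(got$pr_flags, want$flagsA)
    expect_identical(got$kap_flags, want$flagsB)
  }
  expect_error(frame_contacts(pos, data.frame(chain = 1, role = "pr"),
                              0), "both")
})

test_that("Ct averaging and normalization follow the scripted fixture", {
  ## constant 5 contacts per frame
  sc5 <- lapply(1:8, function(f) cbind(1:5, 1:5))
  traj <- generate_fixture_trajectory(sc5, n_pr = 14, n_kap = 100)
  ct <- time_averaged_contacts(traj, equilibration_fraction = 0)
  expect_equal(ct$Ct, 5)
  expect_equal(ct$Ct_normalized, 5 / (100 * 14))
  ## frames with 0 and 10 contacts average to 5
  sc <- list(NULL, cbind(1:10, 1:10))
  traj2 <- generate_fixture_trajectory(sc, n_pr = 14, n_kap = 100)
  expect_equal(time_averaged_contacts(traj2,
                                      equilibration_fraction = 0)$Ct, 5)
  ## random scripts against their own closed form
  set.seed(4)
  for (rep in 1:5) {
    script <- lapply(1:20, function(f) {
      k <- sample(0:10, 1)
      if (k == 0) NULL else cbind(sample(14, k), sample(100, k,
                                                        replace = TRUE))
    })
    trajr <- generate_fixture_trajectory(script, n_pr = 14, n_kap = 100)
    want <- mean(vapply(script, function(s)
      if (is.null(s)) 0L else nrow(s), integer(1)))
    got <- time_averaged_contacts(trajr, equilibration_fraction = 0)
    expect_equal(got$Ct, want)
    expect_equal(got$Ct_normalized, want / 1400)
    expect_gte(got$Ct, 0)
  }
  ## equilibration discard: with fraction 0.5, only the second half counts
  expect_equal(time_averaged_contacts(traj2,
                                      equilibration_fraction = 0.5)$Ct, 10)
})

test_that("binding probability uses a strict >10% residue criterion", {
  bound_all <- lapply(1:6, function(f) cbind(1:14, rep(1, 14)))
  traj <- generate_fixture_trajectory(bound_all, n_pr = 14, n_kap = 20)
  expect_equal(binding_probability(traj)$Pb, 1.0)
  never <- generate_fixture_trajectory(lapply(1:6, function(f) NULL),
                                       n_pr = 14, n_kap = 20)
  expect_equal(binding_probability(never)$Pb, 0.0)
  ## PR7: 1 residue in contact (1 <= 1.4) unbound; 2 residues (> 1.4) bound
  one <- generate_fixture_trajectory(list(cbind(1, 1)), 14, 20)
  two <- generate_fixture_trajectory(list(cbind(1:2, c(1, 2))), 14, 20)
  expect_equal(binding_probability(one)$Pb, 0)
  expect_equal(binding_probability(two)$Pb, 1)
})

test_that("residue contact probabilities match per-residue recomputation", {
  ## a receptor residue in contact every frame scores 1.0
  always <- lapply(1:10, function(f) cbind(1, 7))
  traj <- generate_fixture_trajectory(always, n_pr = 4, n_kap = 12)
  prof <- residue_contact_probability(traj, equilibration_fraction = 0)
  expect_equal(prof[7], 1.0)
  expect_equal(sum(prof), 1.0)
  ## alternating frames score 0.5
  alt <- lapply(1:10, function(f) if (f %% 2) cbind(1, 7) else NULL)
  traj2 <- generate_fixture_trajectory(alt, n_pr = 4, n_kap = 12)
  expect_equal(residue_contact_probability(traj2,
                                           equilibration_fraction = 0)[7],
               0.5)
  ## random scripts vs direct per-residue oracle
  set.seed(12)
  script <- lapply(1:30, function(f) {
    k <- sample(0:6, 1)
    if (k == 0) NULL else cbind(sample(8, k), sample(12, k, replace = TRUE))
  })
  traj3 <- generate_fixture_trajectory(script, n_pr = 8, n_kap = 12)
  prof3 <- residue_contact_probability(traj3, equilibration_fraction = 0)
  oracle <- vapply(1:12, function(res)
    mean(vapply(script, function(s)
      !is.null(s) && res %in% s[, 2], logical(1))), numeric(1))
  expect_equal(prof3, oracle)
  expect_true(all(prof3 >= 0 & prof3 <= 1))
})

test_that("contact sites use a strict probability threshold", {
  expect_equal(contact_sites(c(0.05, 0.10, 0.11)), 3L)
  expect_length(contact_sites(rep(0, 10)), 0)
  set.seed(3)
  prof <- runif(1000)
  expect_identical(contact_sites(prof, 0.25), which(prof > 0.25))
})

test_that("region-resolved counts follow the interval annotation", {
  ann <- region_annotation(c(1, 5, 9), c(4, 8, 12), c(1, 1, 1),
                           c("A", "B", "linker"))
  rc <- region_contact_counts(c(3, 5, 9), ann)
  expect_equal(rc$Ncontact, c(A = 1L, B = 1L, linker = 1L))
  expect_equal(rc$unannotated, 0)
  rc0 <- region_contact_counts(integer(0), ann)
  expect_equal(sum(rc0$Ncontact), 0)
  ## random sites/spans vs membership oracle, plus unannotated residues
  set.seed(9)
  ann2 <- region_annotation(c(1, 11, 21), c(10, 20, 30), c(1, 1, 2),
                            c("A", "linker", "B"))
  sites <- sample(40, 15)
  rc2 <- region_contact_counts(sites, ann2)
  expect_equal(rc2$Ncontact[["A"]], sum(sites <= 10))
  expect_equal(rc2$Ncontact[["linker"]], sum(sites >= 11 & sites <= 20))
  expect_equal(rc2$Ncontact[["B"]], sum(sites >= 21 & sites <= 30))
  expect_equal(rc2$unannotated, sum(sites > 30))
  expect_equal(sum(unlist(rc2$Ncontact)) + rc2$unannotated, 15)
  bad <- data.frame(start = c(1, 3), end = c(5, 8), heat_index = 1,
                    label = c("A", "B"))
  expect_error(region_contact_counts(1:3, bad), "overlapping")
})

test_that("shared binding sites are set intersections with absent classes", {
  bs <- binding_site_set(rangtp = c(5, 9, 12))
  ns <- shared_binding_sites(c(3, 5, 9), bs)
  expect_equal(ns[["rangtp"]], 2L)
  expect_true(is.na(ns[["cargo"]]))   # absent class, not zero
  set.seed(14)
  bs2 <- binding_site_set(cargo = sample(50, 12), ibb = sample(50, 8),
                          rangtp = sample(50, 10), fg_nup = sample(50, 5))
  sites <- sample(50, 20)
  ns2 <- shared_binding_sites(sites, bs2)
  for (cl in names(bs2)) {
    expect_equal(ns2[[cl]], length(intersect(sites, bs2[[cl]])))
    expect_lte(ns2[[cl]], min(length(sites), length(bs2[[cl]])))
  }
})

test_that("uncertainty is half the block standard deviation", {
  expect_equal(scalar_uncertainty(c(2, 2, 2, 2)), 0)
  expect_equal(scalar_uncertainty(c(0, 2)), 0.5 * sqrt(2))
  set.seed(6)
  b <- rnorm(10)
  expect_equal(scalar_uncertainty(b), 0.5 * sd(b))
  expect_error(scalar_uncertainty(1), ">= 2")
})

test_that("NCPR regression reproduces closed-form least squares", {
  fit <- ncpr_contact_regression(c(-0.1, -0.05, 0), c(0.3, 0.2, 0.1))
  expect_equal(fit$slope, -2)
  expect_equal(abs(fit$correlation), 1)
  ## two symmetric clusters: zero slope
  fit0 <- ncpr_contact_regression(c(-1, -1, 1, 1), c(0, 1, 1, 0))
  expect_equal(fit0$slope, 0)
  set.seed(30)
  x <- rnorm(10); y <- rnorm(10)
  fit2 <- ncpr_contact_regression(x, y)
  lm_ref <- lm(y ~ x)
  expect_equal(fit2$slope, unname(coef(lm_ref)[2]))
  expect_equal(fit2$intercept, unname(coef(lm_ref)[1]))
  expect_equal(fit2$correlation, cor(x, y))
  expect_error(ncpr_contact_regression(c(1, 1, 1), c(1, 2, 3)),
               "degenerate")
  expect_error(ncpr_contact_regression(1:2, 1:2), ">= 3")
})

test_that("full analysis assembles consistent results", {
  set.seed(18)
  script <- lapply(1:25, function(f) {
    k <- sample(0:8, 1)
    if (k == 0) NULL else cbind(sample(10, k), sample(24, k,
                                                      replace = TRUE))
  })
  traj <- generate_fixture_trajectory(script, n_pr = 10, n_kap = 24)
  ann <- region_annotation(c(1, 9, 17), c(8, 16, 24), c(1, 1, 2),
                           c("A", "B", "linker"))
  bs <- binding_site_set(cargo = 1:5, rangtp = 20:24)
  res <- analyze_trajectory(traj, ann, bs)
  expect_s3_class(res, "contact_results")
  expect_true(res$Pb >= 0 && res$Pb <= 1)
  expect_true(all(res$residue_profile >= 0 & res$residue_profile <= 1))
  expect_equal(sum(unlist(res$Ncontact_by_region)) +
                 res$Ncontact_unannotated, length(res$contact_sites))
  expect_true(is.na(res$Nshared_by_class[["ibb"]]))
  ## TSV/JSON emission
  dir <- tempfile()
  write_contact_results(res, dir)
  expect_true(file.exists(file.path(dir, "contacts_summary.json")))
  summ <- jsonlite::fromJSON(file.path(dir, "contacts_summary.json"))
  expect_equal(summ$Ct, res$Ct)
})

test_that("fixture trajectories reject unrealizable scripts", {
  expect_error(generate_fixture_trajectory(
    list(rbind(c(1, 1), c(1, 3))), 4, 6), "unrealizable")
  expect_error(generate_fixture_trajectory(list(cbind(9, 1)), 4, 6),
               "outside")
  expect_error(generate_fixture_trajectory(list(), 4, 6), "empty")
})
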