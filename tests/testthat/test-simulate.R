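test_that("marker simulation honours missing rate, seed and sampling law", {
  cfg <- small_sim_config(n_lines = 50, n_markers = 200)
  m <- simulate_markers(cfg, "G2")
  expect_equal(dim(m), c(50, 200))
  expect_equal(sum(is.na(m$dosages)), 0)  # missing_rate 0

  # determinism: identical config + seed -> bit-identical matrices
  m2 <- simulate_markers(small_sim_config(n_lines = 50, n_markers = 200), "G2")
  expect_identical(m$dosages, m2$dosages)

  # masking applies at the configured rate
  cfg_miss <- sim_config(
    n_lines = 100, n_markers = c(G1 = 500), missing_rate = c(G1 = 0.3),
    seed = 3
  )
  mm <- simulate_markers(cfg_miss, "G1")
  expect_gt(mean(is.na(mm$dosages)), 0.25)
  expect_lt(mean(is.na(mm$dosages)), 0.35)
})

test_that("empirical allele frequency matches the binomial draw within 3 SE", {
  n <- 1000
  p <- 0.3
  cfg <- sim_config(n_lines = n, n_markers = c(G1 = 5L),
                    maf_range = c(p, p), missing_rate = c(G1 = 0), seed = 5)
  m <- simulate_markers(cfg, "G1")
  # pooled over 5 markers: 2 * n * 5 allele draws at frequency p
  se <- sqrt(p * (1 - p) / (2 * n * 5))
  freq <- mean(m$dosages) / 2
  expect_lt(abs(freq - p), 3 * se)
})

test_that("degenerate phenotype draw returns the overall mean exactly", {
  cfg <- small_sim_config(
    n_lines = 6, n_env = 3,
    var_E = 0, var_L = 0, var_g = 0, var_EL = 0, var_Eg = 0, var_e = 0,
    mu = 10
  )
  grm <- identity_grm(sprintf("L%03d", 1:6))
  ph <- simulate_phenotypes(cfg, grm)
  expect_equal(ph$value, rep(10, nrow(ph)))
  expect_equal(nrow(ph), 18)
})

test_that("phenotype simulation is deterministic and errors on non-PSD G", {
  cfg <- small_sim_config(n_lines = 10, n_env = 3)
  grm <- identity_grm(sprintf("L%03d", 1:10))
  ph1 <- simulate_phenotypes(cfg, grm)
  ph2 <- simulate_phenotypes(cfg, grm)
  expect_identical(ph1$value, ph2$value)

  bad <- grm
  bad$G[1, 2] <- bad$G[2, 1] <- 2  # eigenvalues -1 and 3
  expect_error(simulate_phenotypes(cfg, bad), "positive semidefinite")
})

test_that("pure-residual simulation has unit empirical variance", {
  # 10^4 cells of pure N(0, 1) noise; sample variance has SE ~ sqrt(2/n)
  design <- tidyr::expand_grid(year = 2012L:2013L, location = c("A1", "B1"))
  design$management <- "Normal"
  design$location <- paste0("Loc", seq_len(nrow(design)))
  cfg <- sim_config(
    n_lines = 2500, n_markers = c(G1 = 5L), missing_rate = c(G1 = 0),
    trial_design = design, traits = "PH", mu = 0,
    var_E = 0, var_L = 0, var_g = 0, var_EL = 0, var_Eg = 0, var_e = 1,
    seed = 9
  )
  grm <- identity_grm(sprintf("L%03d", 1:2500))
  ph <- simulate_phenotypes(cfg, grm)
  n <- nrow(ph)
  expect_equal(n, 10000)
  expect_lt(abs(var(ph$value) - 1), 3 * sqrt(2 / n))
})

test_that("cross-environment genetic correlation matches its closed form", {
  # with G = I, cor(g + Eg_1, g + Eg_2) = var_g / (var_g + var_Eg)
  n <- 3000
  design <- tibble::tibble(year = c(2012L, 2013L),
                           location = "IARI", management = "Normal")
  cfg <- sim_config(
    n_lines = n, n_markers = c(G1 = 5L), missing_rate = c(G1 = 0),
    trial_design = design, traits = "PH",
    var_E = 0, var_L = 0, var_g = 0.4, var_EL = 0, var_Eg = 0.2, var_e = 0,
    seed = 21
  )
  grm <- identity_grm(sprintf("L%03d", seq_len(n)))
  truth <- sim_truth(simulate_phenotypes(cfg, grm))
  envs <- unique(truth$env)
  tv <- tidyr::pivot_wider(
    dplyr::select(
      dplyr::mutate(truth, total_g = g + Eg),
      env, line, total_g
    ),
    names_from = "env", values_from = "total_g"
  )
  r <- cor(tv[[envs[1]]], tv[[envs[2]]])
  expect_equal(r, 0.4 / (0.4 + 0.2), tolerance = 0.05)
})

test_that("empirical variance decomposition matches the configured components", {
  cfg <- small_sim_config(n_lines = 500, n_env = 5, seed = 31)
  grm <- identity_grm(sprintf("L%03d", 1:500))
  truth <- sim_truth(simulate_phenotypes(cfg, grm))
  v <- cfg$variances
  n_cells <- nrow(truth)
  expect_equal(n_cells, 2500)
  # sample variance of N(0, s2) over n draws has SE ~ s2 * sqrt(2/n)
  se <- function(s2, n) s2 * sqrt(2 / n)
  expect_lt(abs(var(truth$EL) - v[["EL"]]), 3 * se(v[["EL"]], n_cells))
  expect_lt(abs(var(truth$e) - v[["e"]]), 3 * se(v[["e"]], n_cells))
  expect_lt(abs(var(truth$Eg) - v[["Eg"]]), 3 * se(v[["Eg"]], n_cells))
  line_L <- dplyr::distinct(truth, line, L)
  expect_lt(abs(var(line_L$L) - v[["L"]]), 3 * se(v[["L"]], 500))
})

test_that("a full synthetic dataset is internally consistent and writable", {
  cfg <- sim_config(
    n_lines = 25, n_markers = c(G1 = 120L, G2 = 60L),
    missing_rate = c(G1 = 0.2, G2 = 0.02), seed = 13,
    traits = c("PH", "SY")
  )
  ds <- simulate_dataset(cfg)
  expect_named(ds$grm, c("G1", "G2", "G3"))
  expect_equal(nrow(ds$phenotypes), 25 * 9 * 2)
  expect_setequal(unique(ds$phenotypes$trait), c("PH", "SY"))
  # truth decomposition reconstructs the phenotype
  joined <- dplyr::left_join(
    ds$phenotypes, ds$truth, by = c("env", "line", "trait")
  )
  recon <- cfg$mu + joined$E + joined$L + joined$g +
    joined$EL + joined$Eg + joined$e
  expect_equal(joined$value, recon, tolerance = 1e-12)

  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(
    dir, c("phenotypes.csv", "truth.csv", "design.csv",
           "genotypes_G1.tsv", "genotypes_G2.tsv")
  ))))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_lines = 1), "at least 2")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(var_e = -1), "non-negative")
  expect_error(sim_config(missing_rate = c(G1 = 1.2, G2 = 0)), "Missing rates")
  expect_error(
    sim_config(trial_design = default_trial_design()[1, ], var_E = 0.2),
    "2 environments"
  )
  expect_error(simulate_markers(small_sim_config(), "G9"), "Unknown platform")
})
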