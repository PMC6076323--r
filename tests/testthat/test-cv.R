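check_partition_invariants <- function(parts, pheno) {
  n <- nrow(pheno)
  for (i in seq_len(nrow(parts))) {
    test <- parts$test[[i]]
    expect_true(length(test) >= 1)
    expect_true(all(test %in% seq_len(n)))
    expect_equal(anyDuplicated(test), 0)
  }
}

test_that("CV0 leaves out one environment at a time with full coverage", {
  ds <- small_dataset(n_lines = 6, n_env = 4)
  ph <- ds$phenotypes
  parts <- make_cv0(ph)
  expect_equal(nrow(parts), 4)
  check_partition_invariants(parts, ph)
  # each test set is exactly one environment; train covers the rest
  for (i in seq_len(nrow(parts))) {
    expect_setequal(unique(ph$env[parts$test[[i]]]), parts$env[i])
    train_envs <- unique(ph$env[-parts$test[[i]]])
    expect_setequal(train_envs, setdiff(unique(ph$env), parts$env[i]))
  }
  # every record is held out exactly once over the scheme
  all_test <- sort(unlist(parts$test))
  expect_equal(all_test, seq_len(nrow(ph)))

  # nine environments in the default design
  ph9 <- tidyr::expand_grid(
    env = derive_environments(default_trial_design())$env,
    line = paste0("L", 1:3)
  )
  ph9$value <- rnorm(nrow(ph9))
  expect_equal(nrow(make_cv0(ph9)), 9)

  # two-environment toy: two complementary partitions
  ph2 <- toy_pheno(n_lines = 3, n_env = 2)
  p2 <- make_cv0(ph2)
  expect_equal(nrow(p2), 2)
  expect_setequal(c(p2$test[[1]], p2$test[[2]]), seq_len(nrow(ph2)))

  expect_error(make_cv0(toy_pheno(n_env = 1)), "2 environments")
})

test_that("CV1 folds group all records of a line and balance fold sizes", {
  lines <- sprintf("L%03d", 1:320)
  ph <- tidyr::expand_grid(env = paste0("E", 1:9), line = lines)
  ph$value <- rnorm(nrow(ph))
  parts <- make_cv1(ph, k = 5, repeats = 20, seed = 1)
  expect_equal(nrow(parts), 100)
  check_partition_invariants(parts, ph)
  for (i in sample(nrow(parts), 10)) {
    test_lines <- unique(ph$line[parts$test[[i]]])
    # 320 lines over 5 folds: 64 lines each
    expect_equal(length(test_lines), 64)
    # all 9 records of every test line are held out together
    expect_equal(length(parts$test[[i]]), 64 * 9)
    train_lines <- unique(ph$line[-parts$test[[i]]])
    expect_equal(length(intersect(test_lines, train_lines)), 0)
  }
  # within one repeat the folds cover every line exactly once
  rep1 <- parts[parts$rep == 1, ]
  expect_equal(sort(unlist(rep1$test)), seq_len(nrow(ph)))

  # remainder lines are distributed one per leading fold
  ph7 <- tidyr::expand_grid(env = paste0("E", 1:2),
                            line = paste0("L", 1:7))
  ph7$value <- rnorm(14)
  p7 <- make_cv1(ph7, k = 3, repeats = 1, seed = 2)
  sizes <- vapply(p7$test, function(i) {
    length(unique(ph7$line[i]))
  }, integer(1))
  expect_equal(sort(sizes, decreasing = TRUE), c(3, 2, 2))

  expect_error(make_cv1(ph7, k = 10), "More folds than lines")
})

test_that("CV2 is record-level, environment-stratified sparse testing", {
  ds <- small_dataset(n_lines = 45, n_env = 5)
  ph <- ds$phenotypes   # 225 records
  parts <- make_cv2(ph, k = 5, repeats = 20, seed = 1)
  expect_equal(nrow(parts), 100)
  check_partition_invariants(parts, ph)
  expect_true(all(lengths(parts$test) == 45))
  # stratification: every environment contributes 1/5 of its records
  for (i in sample(nrow(parts), 5)) {
    contrib <- table(ph$env[parts$test[[i]]])
    expect_true(all(contrib == 9))
  }
  # folds of a repeat tile the records
  rep1 <- parts[parts$rep == 3, ]
  expect_equal(sort(unlist(rep1$test)), seq_len(nrow(ph)))
  # sparse-testing property: a line is typically split across train and test
  i <- 1
  test_lines <- unique(ph$line[parts$test[[i]]])
  train_lines <- unique(ph$line[-parts$test[[i]]])
  expect_gt(length(intersect(test_lines, train_lines)), 0)

  # tiny environments fall back to unstratified splitting with a warning
  ph_small <- toy_pheno(n_lines = 3, n_env = 2)
  expect_warning(make_cv2(ph_small, k = 5, repeats = 1, seed = 1),
                 "stratification")
})

test_that("partition generation is seed-deterministic and model-agnostic", {
  ph <- toy_pheno(n_lines = 20, n_env = 4)
  a <- make_cv1(ph, k = 4, repeats = 3, seed = 42)
  b <- make_cv1(ph, k = 4, repeats = 3, seed = 42)
  expect_identical(a$test, b$test)
  c2 <- make_cv2(ph, k = 4, repeats = 3, seed = 42)
  d2 <- make_cv2(ph, k = 4, repeats = 3, seed = 42)
  expect_identical(c2$test, d2$test)
  expect_false(identical(
    make_cv2(ph, k = 4, repeats = 3, seed = 43)$test, c2$test
  ))
})

test_that("partitions round-trip through their CSV export", {
  ph <- toy_pheno(n_lines = 10, n_env = 3)
  parts <- make_cv1(ph, k = 5, repeats = 2, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_partitions(parts, ph, path)
  back <- read_partitions(path, ph)
  expect_equal(nrow(back), nrow(parts))
  key <- function(p) p[order(p$rep, p$fold), ]$test
  expect_equal(lapply(key(back), sort), lapply(key(parts), sort))
})

test_that("run_cv predicts every held-out record with the expected multiplicity", {
  ds <- small_dataset(n_lines = 12, n_env = 3)
  ph <- ds$phenotypes
  parts <- make_cv0(ph)
  preds <- run_cv("E+L+G2", ph, ds$grm$G2, parts,
                  niter = 400, burnin = 100, thin = 2, seed = 5)
  # CV0: every record predicted exactly once
  expect_equal(nrow(preds), nrow(ph))
  expect_equal(
    sort(paste(preds$env, preds$line)),
    sort(paste(ph$env, ph$line))
  )
  # CV1 with r repeats: every record predicted exactly r times
  parts1 <- make_cv1(ph, k = 3, repeats = 2, seed = 5)
  preds1 <- run_cv("E+L", ph, NULL, parts1,
                   niter = 400, burnin = 100, thin = 2, seed = 5)
  counts <- dplyr::count(preds1, env, line)
  expect_true(all(counts$n == 2))
})
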