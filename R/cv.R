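#' Cross-validation partitions for multi-environment prediction
#'
#' Three schemes mirror the prediction problems a breeding program faces:
#' `CV0` predicts a whole untested environment (leave-one-environment-out,
#' deterministic), `CV1` predicts never-tested lines (line-level folds, all
#' records of a line held out together), and `CV2` predicts lines tested in
#' some environments but not others (record-level folds, stratified by
#' environment — sparse testing).
#'
#' Partitions are returned as a tibble with one row per partition: columns
#' `scheme`, `rep`, `fold`, `env` (CV0 only) and a list-column `test` of
#' record indices into `pheno`. Training records are the complement.
#'
#' @param pheno Phenotype tibble with columns `env` and `line` (one trait).
#' @param k Number of folds.
#' @param repeats Number of random repetitions of the k-fold split.
#' @param seed Integer master seed; per-repeat seeds are derived from it so
#'   the same partitions can be reused across all model specifications.
#' @return A partition tibble (class `cv_partitions`).
#' @name cross_validation
NULL

.new_partitions <- function(df, n_records) {
  attr(df, "n_records") <- n_records
  class(df) <- c("cv_partitions", class(df))
  df
}

#' @rdname cross_validation
#' @export
make_cv0 <- function(pheno) {
  envs <- unique(as.character(pheno$env))
  if (length(envs) < 2) abort("CV0 needs at least 2 environments.")
  out <- tibble(
    scheme = "CV0", rep = 1L, fold = seq_along(envs), env = envs,
    test = lapply(envs, function(ev) which(pheno$env == ev))
  )
  .new_partitions(out, nrow(pheno))
}

#' @rdname cross_validation
#' @export
make_cv1 <- function(pheno, k = 5, repeats = 20, seed = 1L) {
  lines <- unique(as.character(pheno$line))
  n_lines <- length(lines)
  if (k > n_lines) abort("More folds than lines.")
  line_of <- as.character(pheno$line)
  out <- purrr::map_dfr(seq_len(repeats), function(r) {
    shuffled <- withr::with_seed(
      (as.integer(seed) + r * 7919L) %% .Machine$integer.max,
      sample(lines)
    )
    # base fold size, remainder lines one per leading fold
    sizes <- rep(n_lines %/% k, k)
    rem <- n_lines %% k
    if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
    fold_of <- rep(seq_len(k), times = sizes)
    tibble(
      scheme = "CV1", rep = r, fold = seq_len(k), env = NA_character_,
      test = lapply(seq_len(k), function(f) {
        which(line_of %in% shuffled[fold_of == f])
      })
    )
  })
  .new_partitions(out, nrow(pheno))
}

#' @rdname cross_validation
#' @export
make_cv2 <- function(pheno, k = 5, repeats = 20, seed = 1L) {
  n <- nrow(pheno)
  if (k > n) abort("More folds than records.")
  env_of <- as.character(pheno$env)
  env_counts <- table(env_of)
  stratified <- all(env_counts >= k)
  if (!stratified) {
    warn("Some environment has fewer records than folds; splitting without stratification.")
  }
  out <- purrr::map_dfr(seq_len(repeats), function(r) {
    folds <- withr::with_seed(
      (as.integer(seed) + r * 104729L) %% .Machine$integer.max, {
        fold_of <- integer(n)
        if (stratified) {
          for (ev in names(env_counts)) {
            idx <- sample(which(env_of == ev))
            fold_of[idx] <- rep_len(sample(k), length(idx))
          }
        } else {
          fold_of[sample.int(n)] <- rep_len(seq_len(k), n)
        }
        fold_of
      }
    )
    tibble(
      scheme = "CV2", rep = r, fold = seq_len(k), env = NA_character_,
      test = lapply(seq_len(k), function(f) which(folds == f))
    )
  })
  .new_partitions(out, nrow(pheno))
}

#' Export / import partitions for exact replay
#'
#' @param partitions A `cv_partitions` tibble.
#' @param pheno The phenotype tibble the partitions index into.
#' @param path CSV path.
#' @return `path` (write); a `cv_partitions` tibble (read).
#' @export
write_partitions <- function(partitions, pheno, path) {
  long <- partitions %>%
    mutate(.row = row_number()) %>%
    tidyr::unnest_longer(test, values_to = "record") %>%
    mutate(env_rec = as.character(pheno$env[.data$record]),
           line = as.character(pheno$line[.data$record])) %>%
    select("scheme", "rep", "fold", env = "env_rec", "line", "record")
  readr::write_csv(long, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_partitions
#' @export
read_partitions <- function(path, pheno) {
  long <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  out <- long %>%
    group_by(.data$scheme, .data$rep, .data$fold) %>%
    summarise(test = list(.data$record), .groups = "drop")
  if (all(out$scheme == "CV0")) {
    out$env <- vapply(out$test, function(i) {
      as.character(pheno$env[i[1]])
    }, character(1))
  } else {
    out$env <- NA_character_
  }
  .new_partitions(
    out[, c("scheme", "rep", "fold", "env", "test")], nrow(pheno)
  )
}

#' Run one model over a set of cross-validation partitions
#'
#' For each partition the model is fitted on the training records and the
#' held-out records are predicted; the same partition tibble can (and
#' should) be reused across model specifications so every model sees
#' identical splits. Kernel eigendecompositions are computed once and shared
#' across partitions.
#'
#' @param spec Model spec (one-row tibble or canonical name).
#' @param pheno Single-trait phenotype tibble with columns `env`, `line`,
#'   `value`.
#' @param grm `genomic_relationship` (required for genomic models). For
#'   registry specs with a `platform` column, a named list of GRMs may be
#'   supplied and the platform's GRM is picked automatically.
#' @param partitions A `cv_partitions` tibble.
#' @param niter,burnin,thin,df0,R2 Passed to [fit_gibbs()].
#' @param seed Master seed; each partition's sampler seed derives from it.
#' @return Tibble of test-set predictions with columns `scheme`, `rep`,
#'   `fold`, `env`, `line`, `obs`, `pred`.
#' @export
run_cv <- function(spec, pheno, grm = NULL, partitions,
                   niter = 4000, burnin = 1000, thin = 5,
                   df0 = 5, R2 = 0.5, seed = 1L) {
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(all(c("env", "line", "value") %in% names(pheno)))
  if ("trait" %in% names(pheno) && length(unique(pheno$trait)) > 1) {
    abort("`pheno` must contain a single trait; filter first.")
  }
  if (is.list(grm) && !inherits(grm, "genomic_relationship")) {
    pf <- spec$platform
    grm <- if (pf %in% names(grm)) grm[[pf]] else NULL
  }
  kernels <- build_kernels(spec, pheno, grm)
  eigens <- lapply(kernels, function(k) kernel_eigen(k$K))
  y <- pheno$value
  n <- length(y)
  res <- purrr::map_dfr(seq_len(nrow(partitions)), function(i) {
    test_idx <- partitions$test[[i]]
    train <- rep(TRUE, n)
    train[test_idx] <- FALSE
    fit <- tryCatch(
      fit_gibbs(y, kernels, train = train, niter = niter, burnin = burnin,
                thin = thin, df0 = df0, R2 = R2,
                seed = (as.integer(seed) + i * 13L) %% .Machine$integer.max,
                eigens = eigens),
      error = function(e) {
        abort(sprintf("Partition %d (%s rep %d fold %d): %s",
                      i, partitions$scheme[i], partitions$rep[i],
                      partitions$fold[i], conditionMessage(e)))
      }
    )
    tibble(
      scheme = partitions$scheme[i], rep = partitions$rep[i],
      fold = partitions$fold[i],
      env = as.character(pheno$env[test_idx]),
      line = as.character(pheno$line[test_idx]),
      obs = y[test_idx], pred = fit$yhat[test_idx]
    )
  })
  res
}
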