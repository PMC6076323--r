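#' Configuration for the synthetic multi-environment dataset
#'
#' Defines the generative conditions for a synthetic genomic-prediction
#' study: marker panels of contrasting density with platform-specific
#' missingness, a multi-environment trial design, and phenotypes drawn from
#' the full reaction-norm model
#' \deqn{y_{ij} = \mu + E_i + L_j + g_j + EL_{ij} + Eg_{ij} + e_{ij}}
#' with known variance components. Defaults mirror a 320-line chickpea-style
#' study: 9 year-by-location-by-management environments, 8 traits, a dense
#' GBS-like panel (~89 K SNPs, high missingness) and a sparse DArTseq-like
#' panel (~1.6 K SNPs, low missingness).
#'
#' @param n_lines Number of lines (>= 2).
#' @param n_markers Named integer vector of marker counts per platform.
#' @param maf_range Length-2 numeric in (0, 0.5]: allele-frequency range from
#'   which each marker's frequency is drawn uniformly.
#' @param missing_rate Named numeric vector (same names as `n_markers`) of
#'   per-platform missing-call rates in \[0, 1).
#' @param trial_design Tibble of (year, location, management) rows; see
#'   [default_trial_design()].
#' @param traits Character vector of trait names.
#' @param mu Overall trait mean (trait units).
#' @param var_E,var_L,var_g,var_EL,var_Eg,var_e Variance components (trait
#'   units squared) of the environment, line, genomic, line-by-environment,
#'   genomic-by-environment and residual terms.
#' @param seed Integer seed driving all draws.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 320L,
                       n_markers = c(G1 = 88845L, G2 = 1568L),
                       maf_range = c(0.05, 0.5),
                       missing_rate = c(G1 = 0.3, G2 = 0.05),
                       trial_design = default_trial_design(),
                       traits = c("PH", "BM", "DF", "DM",
                                  "HI", "PS", "SDW", "SY"),
                       mu = 10,
                       var_E = 0.15, var_L = 0.10, var_g = 0.25,
                       var_EL = 0.10, var_Eg = 0.15, var_e = 0.25,
                       seed = 1L) {
  vars <- c(E = var_E, L = var_L, g = var_g,
            EL = var_EL, Eg = var_Eg, e = var_e)
  if (any(vars < 0)) abort("All variance components must be non-negative.")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must lie within (0, 0.5] and be non-decreasing.")
  }
  if (n_lines < 2) abort("`n_lines` must be at least 2.")
  if (is.null(names(n_markers)) || any(n_markers < 1)) {
    abort("`n_markers` must be a named vector of positive counts.")
  }
  if (!setequal(names(missing_rate), names(n_markers))) {
    abort("`missing_rate` must be named like `n_markers`.")
  }
  if (any(missing_rate < 0 | missing_rate >= 1)) {
    abort("Missing rates must lie in [0, 1).")
  }
  n_env <- nrow(trial_design)
  if (n_env < 2 && (var_E > 0 || var_EL > 0 || var_Eg > 0)) {
    abort("At least 2 environments required when environment terms have variance.")
  }
  structure(
    list(
      n_lines = as.integer(n_lines), n_markers = n_markers,
      maf_range = maf_range, missing_rate = missing_rate,
      trial_design = trial_design, traits = traits, mu = mu,
      variances = vars, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d lines, %d environments, %d traits; platforms: %s\n",
    x$n_lines, nrow(x$trial_design), length(x$traits),
    paste(sprintf("%s (%d SNPs)", names(x$n_markers), x$n_markers),
          collapse = ", ")
  ))
  cat("  variances:",
      paste(sprintf("%s=%.3g", names(x$variances), x$variances),
            collapse = " "), "\n")
  invisible(x)
}

.platform_seed <- function(config, platform) {
  idx <- match(platform, names(config$n_markers))
  (config$seed + idx * 1000003L) %% .Machine$integer.max
}

#' Simulate a marker dosage panel
#'
#' Marker allele frequencies are drawn uniformly from `maf_range`; dosages
#' are binomial(2, p_m) per line and marker (Hardy-Weinberg, no linkage
#' disequilibrium); calls are masked at the platform's missing rate.
#' Reproducible for a fixed (config, platform).
#'
#' @param config A [sim_config()].
#' @param platform Platform label, one of `names(config$n_markers)`.
#' @return A [marker_matrix()].
#' @export
simulate_markers <- function(config, platform = names(config$n_markers)[1]) {
  stopifnot(inherits(config, "sim_config"))
  if (!platform %in% names(config$n_markers)) {
    abort(paste0("Unknown platform: ", platform))
  }
  n <- config$n_lines
  p <- config$n_markers[[platform]]
  miss <- config$missing_rate[[platform]]
  withr::with_seed(.platform_seed(config, platform), {
    freq <- runif(p, config$maf_range[1], config$maf_range[2])
    x <- matrix(
      rbinom(n * p, size = 2L, prob = rep(freq, each = n)),
      nrow = n, ncol = p
    )
    if (miss > 0) {
      x[runif(n * p) < miss] <- NA_integer_
    }
    storage.mode(x) <- "double"
    rownames(x) <- sprintf("L%03d", seq_len(n))
    colnames(x) <- sprintf("%s_M%05d", platform, seq_len(p))
    marker_matrix(x, platform = platform)
  })
}

# draw one N(0, sigma2 * G) vector given the eigendecomposition of G
.rmvn_eig <- function(eig, sigma2) {
  d <- pmax(eig$values, 0)
  as.vector(eig$vectors %*% (sqrt(d * sigma2) * rnorm(length(d))))
}

#' Simulate multi-environment phenotypes from the reaction-norm model
#'
#' For each trait, phenotypes over the complete environment-by-line layout
#' are drawn as `y_ij = mu + E_i + L_j + g_j + EL_ij + Eg_ij + e_ij` with
#' `E ~ N(0, var_E I)`, `L ~ N(0, var_L I)`, `g ~ N(0, var_g G)`, `EL` iid
#' `N(0, var_EL)` per cell, `Eg` realizing the Hadamard covariance
#' `var_Eg (Z_g G Z_g') o (Z_E Z_E')` (drawn as one independent
#' `N(0, var_Eg G)` vector per environment, exact for complete layouts), and
#' iid residuals. All drawn effects are returned as a truth sidecar for
#' parameter-recovery work.
#'
#' @param config A [sim_config()].
#' @param grm A `genomic_relationship` whose line set is used as the design's
#'   line set; must be positive semidefinite.
#' @return A tibble with columns `env`, `line`, `trait`, `value`, carrying
#'   the per-cell effect draws as the `"truth"` attribute (see [sim_truth()]).
#' @export
simulate_phenotypes <- function(config, grm) {
  stopifnot(inherits(config, "sim_config"),
            inherits(grm, "genomic_relationship"))
  g_mat <- grm$G
  n <- nrow(g_mat)
  eig <- eigen(g_mat, symmetric = TRUE)
  if (min(eig$values) < -1e-8 * n) {
    abort("G is not positive semidefinite.")
  }
  envs <- derive_environments(config$trial_design)$env
  n_env <- length(envs)
  lines <- grm$lines
  v <- config$variances
  grid <- tidyr::expand_grid(env = envs, line = lines)

  one_trait <- function(trait) {
    E_i <- rnorm(n_env, 0, sqrt(v[["E"]]))
    L_j <- rnorm(n, 0, sqrt(v[["L"]]))
    g_j <- .rmvn_eig(eig, v[["g"]])
    # per-environment independent N(0, var_Eg * G) draws realize the
    # Hadamard covariance (Z_g G Z_g') o (Z_E Z_E') on a complete layout
    Eg <- lapply(seq_len(n_env), function(i) .rmvn_eig(eig, v[["Eg"]]))
    ei <- rep(seq_len(n_env), each = n)
    li <- rep(seq_len(n), times = n_env)
    truth <- tibble(
      env = grid$env, line = grid$line, trait = trait,
      E = E_i[ei], L = L_j[li], g = g_j[li],
      EL = rnorm(n_env * n, 0, sqrt(v[["EL"]])),
      Eg = unlist(Eg, use.names = FALSE),  # records are env-major
      e = rnorm(n_env * n, 0, sqrt(v[["e"]]))
    )
    truth$value <- config$mu + truth$E + truth$L + truth$g +
      truth$EL + truth$Eg + truth$e
    truth
  }

  truth_all <- withr::with_seed(
    (config$seed + 101L) %% .Machine$integer.max,
    dplyr::bind_rows(lapply(config$traits, one_trait))
  )
  pheno <- truth_all %>% select("env", "line", "trait", "value")
  attr(pheno, "truth") <- truth_all %>%
    select("env", "line", "trait", "E", "L", "g", "EL", "Eg", "e")
  attr(pheno, "mu") <- config$mu
  pheno
}

#' Extract the truth sidecar from simulated phenotypes
#' @param pheno Output of [simulate_phenotypes()].
#' @return Tibble of per-cell effect draws keyed by (env, line, trait).
#' @export
sim_truth <- function(pheno) {
  truth <- attr(pheno, "truth")
  if (is.null(truth)) abort("No truth sidecar attached to `pheno`.")
  truth
}

#' Simulate a complete synthetic study
#'
#' Generates the marker panels, runs QC, builds per-platform and combined
#' genomic relationship matrices, and simulates phenotypes using the GRM of
#' `truth_platform` as the true genomic covariance.
#'
#' @param config A [sim_config()].
#' @param truth_platform Platform whose GRM drives the generative model
#'   (defaults to the combined panel when two platforms are configured).
#' @param max_missing,min_maf QC thresholds passed to [filter_and_impute()].
#' @return A list with elements `markers` (named list of raw panels), `grm`
#'   (named list of `genomic_relationship`, including `G3` when two platforms
#'   are present), `phenotypes` (tibble), `truth` (tibble) and `config`.
#' @export
simulate_dataset <- function(config = sim_config(), truth_platform = NULL,
                             max_missing = 0.2, min_maf = 0.01) {
  stopifnot(inherits(config, "sim_config"))
  platforms <- names(config$n_markers)
  markers <- lapply(platforms, function(pl) simulate_markers(config, pl))
  names(markers) <- platforms
  filtered <- lapply(markers, filter_and_impute,
                     max_missing = max_missing, min_maf = min_maf)
  grm <- lapply(filtered, build_grm)
  if (length(platforms) >= 2) {
    combined <- combine_platforms(filtered[[1]], filtered[[2]])
    grm$G3 <- build_grm(combined)
  }
  if (is.null(truth_platform)) {
    truth_platform <- if ("G3" %in% names(grm)) "G3" else platforms[1]
  }
  pheno <- simulate_phenotypes(config, grm[[truth_platform]])
  list(
    markers = markers, grm = grm,
    phenotypes = pheno, truth = sim_truth(pheno),
    config = config
  )
}

#' Write a synthetic study to disk
#'
#' Writes phenotypes and the truth sidecar as CSV, marker panels as
#' tab-delimited dosage matrices, and the trial design as CSV.
#'
#' @param dataset Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(dataset$phenotypes, file.path(dir, "phenotypes.csv"),
                   progress = FALSE)
  readr::write_csv(dataset$truth, file.path(dir, "truth.csv"),
                   progress = FALSE)
  readr::write_csv(dataset$config$trial_design, file.path(dir, "design.csv"),
                   progress = FALSE)
  for (pl in names(dataset$markers)) {
    write_dosage_matrix(dataset$markers[[pl]],
                        file.path(dir, paste0("genotypes_", pl, ".tsv")))
  }
  invisible(dir)
}
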