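#' Enumerate the reaction-norm model registry
#'
#' With all three platforms the registry holds thirteen models: the baseline
#' `E+L`; genomic main-effect models `E+L+Gk`; naive-interaction models
#' `E+L+Gk+LE`; marker-informed interaction models `E+L+Gk+GkE`; and the
#' full models `E+L+Gk+GkE+LE`, for each platform k. Four models carry main
#' effects only, three carry the naive line-by-environment interaction and
#' six carry marker information in the interaction.
#'
#' @param platforms Character subset of `c("G1", "G2", "G3")`.
#' @return A tibble with columns `name`, `platform` (`"none"` for `E+L`),
#'   `terms` (list of character vectors over `{E, L, G, GE, LE}`) and
#'   `class` (`main_effects`, `naive_interaction`, `informed_interaction`),
#'   in deterministic registry order.
#' @export
#' @examples
#' enumerate_models()            # 13 models
#' enumerate_models("G2")$name   # baseline + four G2 variants
enumerate_models <- function(platforms = c("G1", "G2", "G3")) {
  bad <- setdiff(platforms, c("G1", "G2", "G3"))
  if (length(bad) > 0) {
    abort(paste0("Unknown platform label(s): ", paste(bad, collapse = ", ")))
  }
  platforms <- unique(platforms)
  base <- tibble(
    name = "E+L", platform = "none",
    terms = list(c("E", "L")), class = "main_effects"
  )
  main <- tibble(
    name = paste0("E+L+", platforms), platform = platforms,
    terms = rep(list(c("E", "L", "G")), length(platforms)),
    class = "main_effects"
  )
  naive <- tibble(
    name = paste0("E+L+", platforms, "+LE"), platform = platforms,
    terms = rep(list(c("E", "L", "G", "LE")), length(platforms)),
    class = "naive_interaction"
  )
  informed <- tibble(
    name = paste0("E+L+", platforms, "+", platforms, "E"),
    platform = platforms,
    terms = rep(list(c("E", "L", "G", "GE")), length(platforms)),
    class = "informed_interaction"
  )
  full <- tibble(
    name = paste0("E+L+", platforms, "+", platforms, "E+LE"),
    platform = platforms,
    terms = rep(list(c("E", "L", "G", "GE", "LE")), length(platforms)),
    class = "informed_interaction"
  )
  bind_rows(base, main, naive, informed, full)
}

#' Look up one model specification by canonical name
#'
#' @param name Canonical model name, e.g. `"E+L+G2+G2E+LE"`.
#' @param platforms Platforms available to the registry.
#' @return A one-row model-spec tibble.
#' @export
model_spec <- function(name, platforms = c("G1", "G2", "G3")) {
  reg <- enumerate_models(platforms)
  hit <- reg[reg$name == name, ]
  if (nrow(hit) == 0) {
    abort(paste0(
      "Unknown model '", name, "'. Canonical names: ",
      paste(reg$name, collapse = ", ")
    ))
  }
  hit
}

#' Build covariance kernels for one model over a phenotype table
#'
#' Materializes the model's record-level covariance structures:
#' `K_E = Z_E Z_E'`, `K_L = Z_L Z_L'`, `K_G = Z_g G Z_g'`, and the Hadamard
#' interaction kernels `K_LE = K_L o K_E` (naive) and `K_GE = K_G o K_E`
#' (marker-informed). By the Schur product theorem every kernel is symmetric
#' positive semidefinite.
#'
#' @param spec A one-row model spec from [enumerate_models()] or
#'   [model_spec()], or a canonical model name.
#' @param pheno Phenotype tibble with columns `env`, `line` (single trait;
#'   one record per (env, line)).
#' @param grm A `genomic_relationship` covering every line in `pheno`
#'   (required when the model includes `G`).
#' @return A named list of `kernel_term` objects, each a list with `name`,
#'   `K` (records-by-records matrix) and `vc` (variance symbol, e.g.
#'   `"sigma2_Eg"`), in the model's term order.
#' @export
build_kernels <- function(spec, pheno, grm = NULL) {
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(is.data.frame(spec), nrow(spec) == 1)
  terms <- spec$terms[[1]]
  stopifnot(all(c("env", "line") %in% names(pheno)))
  env <- as.character(pheno$env)
  line <- as.character(pheno$line)
  n <- length(env)

  k_env <- outer(env, env, "==") * 1
  k_line <- outer(line, line, "==") * 1
  kernels <- list()
  vc_map <- c(E = "sigma2_E", L = "sigma2_L", G = "sigma2_g",
              GE = "sigma2_Eg", LE = "sigma2_EL")
  for (tm in terms) {
    K <- switch(
      tm,
      E = k_env,
      L = k_line,
      G = ,
      GE = {
        if (is.null(grm)) {
          abort(paste0("Model ", spec$name, " needs a genomic relationship."))
        }
        idx <- match(line, grm$lines)
        if (anyNA(idx)) {
          missing_lines <- unique(line[is.na(idx)])
          abort(paste0(
            "Line(s) absent from the genomic relationship: ",
            paste(head(missing_lines, 5), collapse = ", ")
          ))
        }
        kg <- grm$G[idx, idx, drop = FALSE]
        if (tm == "G") kg else kg * k_env
      },
      LE = k_line * k_env,
      abort(paste0("Unknown model term: ", tm))
    )
    dimnames(K) <- NULL
    kernels[[tm]] <- structure(
      list(name = tm, K = K, vc = vc_map[[tm]]),
      class = "kernel_term"
    )
  }
  kernels
}
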