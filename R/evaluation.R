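#' Pearson prediction accuracy
#'
#' Standard Pearson correlation between observed phenotypes and predicted
#' genomic breeding values. The correlation is undefined (returned as `NA`)
#' when either vector is constant or fewer than three pairs are available;
#' undefined values are excluded (never zero-filled) from downstream
#' aggregation.
#'
#' @param obs,pred Numeric vectors of equal length.
#' @return A single correlation, or `NA` when undefined.
#' @export
pearson_r <- function(obs, pred) {
  if (length(obs) != length(pred)) abort("`obs` and `pred` differ in length.")
  ok <- is.finite(obs) & is.finite(pred)
  obs <- obs[ok]; pred <- pred[ok]
  if (length(obs) < 3) return(NA_real_)
  if (sd(obs) == 0 || sd(pred) == 0) return(NA_real_)
  cor(obs, pred)
}

#' Within-environment (trial-basis) accuracies for one run
#'
#' @param predictions Prediction tibble (columns `env`, `obs`, `pred`) for a
#'   single run (one partition's test set).
#' @return Tibble with columns `env` and `r` (possibly `NA`).
#' @export
accuracy_by_environment <- function(predictions) {
  predictions %>%
    group_by(.data$env) %>%
    summarise(r = pearson_r(.data$obs, .data$pred), .groups = "drop")
}

# run identifier: CV0 is a single deterministic run; CV1/CV2 one run per
# (repeat, fold) partition
.run_id <- function(df) {
  ifelse(df$scheme == "CV0", "run1",
         paste0("r", df$rep, "f", df$fold))
}

#' Aggregate per-run accuracies into a summary cell
#'
#' For each run, correlations are computed within each environment's test
#' records; the run-level summary is the mean over environments with a
#' defined correlation; the cell's `mean_r` and `sd_r` are the mean and
#' sample SD (n - 1) of the run-level summaries over runs. CV0 comprises a
#' single deterministic run, so its SD is reported as `NA`.
#'
#' @param predictions Prediction tibble from [run_cv()].
#' @param trait,model Labels recorded on the cell.
#' @return A one-row tibble: `trait`, `model`, `scheme`, `mean_r`, `sd_r`,
#'   `n_runs`, `n_undefined` (count of excluded undefined correlations) and
#'   a nested `per_env` tibble of per-environment means over runs.
#' @export
aggregate_accuracy <- function(predictions, trait = NA_character_,
                               model = NA_character_) {
  if (nrow(predictions) == 0) abort("No predictions to aggregate.")
  scheme <- unique(predictions$scheme)
  if (length(scheme) != 1) abort("Aggregate one scheme at a time.")
  per_run_env <- predictions %>%
    mutate(run = .run_id(predictions)) %>%
    group_by(.data$run, .data$env) %>%
    summarise(r = pearson_r(.data$obs, .data$pred), .groups = "drop")
  n_undef <- sum(is.na(per_run_env$r))
  run_means <- per_run_env %>%
    filter(!is.na(.data$r)) %>%
    group_by(.data$run) %>%
    summarise(r_run = mean(.data$r), .groups = "drop")
  if (nrow(run_means) == 0) {
    return(tibble(
      trait = trait, model = model, scheme = scheme,
      mean_r = NA_real_, sd_r = NA_real_, n_runs = 0L,
      n_undefined = n_undef, per_env = list(tibble())
    ))
  }
  per_env <- per_run_env %>%
    filter(!is.na(.data$r)) %>%
    group_by(.data$env) %>%
    summarise(mean_r = mean(.data$r), .groups = "drop")
  tibble(
    trait = trait, model = model, scheme = scheme,
    mean_r = mean(run_means$r_run),
    sd_r = if (scheme == "CV0") NA_real_ else sd(run_means$r_run),
    n_runs = nrow(run_means),
    n_undefined = n_undef,
    per_env = list(per_env)
  )
}

#' Render accuracy cells as a wide, report-style table
#'
#' One row per (scheme, trait); per model a paired Mean/SD column, models in
#' registry order. CV0 SD entries are blank by construction (a single
#' deterministic run).
#'
#' @param cells Tibble of accuracy cells from [aggregate_accuracy()].
#' @param digits Rounding for the report.
#' @return A wide tibble; write with [readr::write_csv()] for a CSV report.
#' @export
render_table <- function(cells, digits = 3) {
  stopifnot(all(c("trait", "model", "scheme", "mean_r", "sd_r")
                %in% names(cells)))
  model_order <- intersect(enumerate_models()$name, unique(cells$model))
  model_order <- c(model_order, setdiff(unique(cells$model), model_order))
  long <- cells %>%
    mutate(
      model = factor(.data$model, levels = model_order),
      Mean = round(.data$mean_r, digits),
      SD = round(.data$sd_r, digits)
    ) %>%
    select("scheme", "trait", "model", "Mean", "SD") %>%
    arrange(.data$model)
  wide <- long %>%
    tidyr::pivot_wider(
      names_from = "model", values_from = c("Mean", "SD"),
      names_glue = "{model}_{.value}", names_vary = "slowest"
    ) %>%
    arrange(.data$scheme, .data$trait)
  wide
}

#' Plot an accuracy table
#'
#' Dot plot of mean within-environment accuracy by model, faceted by trait,
#' colored by cross-validation scheme, with +-1 SD bars where defined.
#'
#' @param cells Accuracy-cell tibble from [aggregate_accuracy()] (rows may
#'   be bound over traits, models and schemes).
#' @return A ggplot object.
#' @export
plot_accuracy <- function(cells) {
  model_order <- intersect(enumerate_models()$name, unique(cells$model))
  model_order <- c(model_order, setdiff(unique(cells$model), model_order))
  cells <- cells %>%
    mutate(model = factor(.data$model, levels = model_order))
  ggplot2::ggplot(
    cells,
    ggplot2::aes(x = .data$model, y = .data$mean_r, color = .data$scheme)
  ) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_r - .data$sd_r,
                   ymax = .data$mean_r + .data$sd_r),
      width = 0.2, na.rm = TRUE,
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::facet_wrap(~trait) +
    ggplot2::labs(
      x = NULL, y = "Mean within-environment accuracy (Pearson r)",
      color = "Scheme"
    ) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
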