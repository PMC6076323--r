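#' Trial design of the multi-environment chickpea-style study
#'
#' The default layout mirrors a nine-environment multi-environment trial:
#' two locations (IARI, ICRISAT) evaluated over three seasons (2012--2014)
#' under up to four water/sowing managements. Environments are the
#' year-by-location-by-management combinations on which all environment
#' kernels and the leave-one-environment-out scheme operate.
#'
#' @return A tibble with columns `year` (integer), `location` (character)
#'   and `management` (character, one of `"Normal"`, `"Irrigated"`,
#'   `"Rainfed"`, `"Latesown"`).
#' @export
#' @examples
#' default_trial_design()
default_trial_design <- function() {
  tibble::tribble(
    ~year, ~location, ~management,
    2012L, "IARI",    "Normal",
    2012L, "ICRISAT", "Normal",
    2013L, "IARI",    "Irrigated",
    2013L, "ICRISAT", "Irrigated",
    2013L, "ICRISAT", "Rainfed",
    2014L, "IARI",    "Latesown",
    2014L, "IARI",    "Normal",
    2014L, "ICRISAT", "Irrigated",
    2014L, "ICRISAT", "Rainfed"
  )
}

# management abbreviations used in environment labels
.mgmt_abbrev <- c(
  Normal = "Norm", Irrigated = "Irrig", Rainfed = "Rain", Latesown = "Late"
)

#' Derive environment labels from a trial design
#'
#' Each (year, location, management) row becomes one environment. Labels
#' follow the `{location}-{management}{yy}` convention with the management
#' abbreviated (Norm, Irrig, Rain, Late); first-season (2012) trials were all
#' conducted under normal management and carry no management suffix, giving
#' labels such as `IARI12`.
#'
#' @param design A data frame with columns `year`, `location`, `management`.
#' @return The design tibble ordered by (year, location, management) with an
#'   added character column `env` holding the unique environment label.
#' @export
#' @examples
#' derive_environments(default_trial_design())$env
derive_environments <- function(design) {
  stopifnot(is.data.frame(design))
  req <- c("year", "location", "management")
  missing_cols <- setdiff(req, names(design))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "`design` lacks column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(design) == 0) abort("`design` has no rows.")
  bad <- setdiff(unique(design$management), names(.mgmt_abbrev))
  if (length(bad) > 0) {
    abort(paste0("Unknown management level(s): ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(design[req]) > 0) {
    abort("Duplicate (year, location, management) combination in design.")
  }
  design %>%
    as_tibble() %>%
    arrange(.data$year, .data$location, .data$management) %>%
    mutate(
      env = ifelse(
        .data$management == "Normal" & .data$year == 2012L,
        sprintf("%s%02d", .data$location, .data$year %% 100L),
        sprintf(
          "%s-%s%02d", .data$location,
          .mgmt_abbrev[.data$management], .data$year %% 100L
        )
      )
    )
}
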