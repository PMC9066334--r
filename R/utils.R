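# internal helpers

DAYS_PER_MONTH <- 30.4375  # 365.25 / 12

MORTALITY_BAND_NAMES <- c("65-69", "70-74", "75-79", "80-84", "85-89",
                          "90-94", ">95")
MORTALITY_PARAM_IDS <- c("mortality_65_69", "mortality_70_74",
                         "mortality_75_79", "mortality_80_84",
                         "mortality_85_89", "mortality_90_94",
                         "mortality_95plus")

# lower edges of the mortality bands; ages below the first band fall into
# band 1, ages at or above 95 stay in the terminal band forever
mortality_band_index <- function(age_years) {
  edges <- c(70, 75, 80, 85, 90, 95)
  findInterval(age_years, edges) + 1L
}

days_to_cycles <- function(days) {
  stopifnot(is.numeric(days), days > 0)
  as.integer(round(days / DAYS_PER_MONTH))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

stop_field <- function(field, msg) {
  stop(sprintf("parameter '%s': %s", field, msg), call. = FALSE)
}
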