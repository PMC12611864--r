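# Internal constants and helpers shared across modules.

DAYS_PER_YEAR <- 365.25
DAYS_PER_MONTH <- 30.44

# Cohort age window: 6 weeks (42 days) to 2 years (730 days), in decimal years.
AGE_MIN_YEARS <- 42 / DAYS_PER_YEAR
AGE_MAX_YEARS <- 730 / DAYS_PER_YEAR

# Age-group boundaries (half-open on the right except the last):
#   G1 = [6 weeks, 4 months), G2 = [4, 8 months), G3 = [8 months, 2 years]
AGE_G2_LO <- 4 * DAYS_PER_MONTH / DAYS_PER_YEAR
AGE_G3_LO <- 8 * DAYS_PER_MONTH / DAYS_PER_YEAR

# AGE_YRS is stored rounded to 2 decimals (the VAERS convention), so boundary
# comparisons tolerate half a rounding step: an infant aged exactly 42 days
# is stored as 0.11 and must still fall inside the window.
AGE_TOL <- 0.005

VACCINE_CLASSES <- c("penta", "hexa")
AGE_GROUPS <- c("G1", "G2", "G3")
SEX_LEVELS <- c("male", "female", "unknown")
RECOVERED_LEVELS <- c("yes", "no", "unknown", "missing")

#' Assign the infant age group
#'
#' Maps decimal age in years to the three analysis age groups: `G1` (6 weeks
#' to under 4 months), `G2` (4 to under 8 months) and `G3` (8 months to
#' 2 years), using 30.44-day months. Values marginally outside the cohort
#' window (possible after 2-decimal rounding of `AGE_YRS`) are clamped into
#' the nearest group.
#'
#' @param age_years numeric vector of ages in decimal years.
#' @return factor with levels `G1`, `G2`, `G3` (`NA` for missing ages).
#' @export
assign_age_group <- function(age_years) {
  grp <- ifelse(is.na(age_years), NA_character_,
    ifelse(age_years < AGE_G2_LO, "G1",
      ifelse(age_years < AGE_G3_LO, "G2", "G3")
    )
  )
  factor(grp, levels = AGE_GROUPS)
}

# Round half away from zero, as printed summary tables conventionally do
# (base round() rounds half to even).
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Per-stage seed derivation: keeps all derived seeds valid 32-bit integers.
derive_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) + 7919 * stage_index) %% (2^31 - 1))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

sort_pts <- function(pts) sort(unique(pts), method = "radix")
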