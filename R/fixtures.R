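#' Joint injury-severity contingency table of the reference crash sample
#'
#' The published 4 x 4 joint distribution of regrouped KABCO injury levels
#' (L1 no injury ... L4 incapacitating or fatal) for the drivers of the
#' front and rear vehicles across 15,159 car-car rear-end crashes, with
#' margins.
#'
#' @return A list: `counts` (4 x 4 matrix, front level in rows, rear level in
#'   columns), `front_totals`, `rear_totals`, `n`.
#' @export
table1_fixture <- function() {
  counts <- matrix(c(8723, 576, 585, 209,
                     1683, 548, 220, 80,
                     1374, 188, 264, 47,
                     437,  60,  59, 106),
                   nrow = 4, byrow = TRUE,
                   dimnames = list(front = paste0("L", 1:4),
                                   rear = paste0("L", 1:4)))
  list(counts = counts,
       front_totals = rowSums(counts),
       rear_totals = colSums(counts),
       n = sum(counts))
}

#' Expand a joint count table into one row per crash
#'
#' Turns a front-by-rear contingency table into a crash-level data frame of
#' outcome pairs (deterministic order: cells in column-major order), e.g. for
#' refitting intercept-only models to printed tables.
#'
#' @param counts a matrix of nonnegative integer cell counts (front level in
#'   rows, rear level in columns).
#' @return A data frame with columns `crash_id`, `outcome_rear`,
#'   `outcome_front`.
#' @export
expand_count_table <- function(counts) {
  counts <- as.matrix(counts)
  kk <- rep(rep(seq_len(ncol(counts)), each = nrow(counts)), c(counts))
  ll <- rep(rep(seq_len(nrow(counts)), times = ncol(counts)), c(counts))
  data.frame(crash_id = seq_along(kk), outcome_rear = kk, outcome_front = ll)
}

#' Model specification matching the published final model
#'
#' The covariate lists and random-coefficient flags of the reported final
#' random-parameters bivariate ordered probit model: 17 front-equation and
#' 23 rear-equation coefficients (including the rear constant, which is
#' random), four outcome levels per equation.
#'
#' @return A [bivop_spec()].
#' @export
table3_spec <- function() {
  front <- bivop_equation(
    covariates = c("age_le24", "male", "airbag_not_deployed",
                   "belt_not_used", "speed_related", "mdlyr_2001_2005",
                   "mdlyr_2006_2010", "mdlyr_2011_2015", "four_doors",
                   "monday", "day_hour", "trafway_divided_no_median",
                   "trafway_ramp", "region_midwest", "light_daylight",
                   "light_dark"),
    random = c("age_le24", "male", "airbag_not_deployed", "mdlyr_2001_2005",
               "mdlyr_2006_2010", "mdlyr_2011_2015", "four_doors",
               "day_hour", "trafway_divided_no_median", "trafway_ramp",
               "region_midwest", "light_daylight"))
  rear <- bivop_equation(
    covariates = c("age_le24", "age_25_63", "male", "alcohol", "drugs",
                   "airbag_not_deployed", "belt_not_used",
                   "mdlyr_1995_2000", "mdlyr_2001_2005", "mdlyr_2006_2010",
                   "mdlyr_2011_2015", "summer", "day_hour", "surface_snow",
                   "trafway_divided_no_median", "trafway_divided_median",
                   "trafway_oneway", "align_straight", "region_midwest",
                   "region_south", "light_daylight"),
    random = c("(Intercept)", "age_le24", "age_25_63", "male", "drugs",
               "belt_not_used", "mdlyr_1995_2000", "mdlyr_2001_2005",
               "mdlyr_2006_2010", "summer", "surface_snow",
               "trafway_divided_no_median"))
  bivop_spec(rear = rear, front = front, n_categories = c(4L, 4L))
}

#' Published final-model estimates as a ground-truth parameter set
#'
#' The reported coefficient means, random-coefficient standard deviations,
#' free thresholds (0.6191 and 1.4814 for the front equation, 0.5090 and
#' 1.3173 for the rear, above the identification cutoff at 0) and error
#' correlation 0.2440, assembled as a [bivop_params()] for realistic
#' simulation studies.
#'
#' @param spec the matching specification, [table3_spec()].
#' @return A [bivop_params()].
#' @export
table3_truth_fixture <- function(spec = table3_spec()) {
  beta_front <- c("(Intercept)" = -0.2028,
                  age_le24 = -0.3182, male = -0.4426,
                  airbag_not_deployed = 0.8767, belt_not_used = 0.5594,
                  speed_related = -0.3872, mdlyr_2001_2005 = -0.1392,
                  mdlyr_2006_2010 = -0.3648, mdlyr_2011_2015 = -0.3569,
                  four_doors = 0.0839, monday = 0.0592, day_hour = -0.1753,
                  trafway_divided_no_median = 0.1414, trafway_ramp = 0.0971,
                  region_midwest = 0.0876, light_daylight = 0.1237,
                  light_dark = 0.1215)
  sigma_front <- c(age_le24 = 0.1657, male = 0.5292,
                   airbag_not_deployed = 0.2692, mdlyr_2001_2005 = 0.0945,
                   mdlyr_2006_2010 = 0.1559, mdlyr_2011_2015 = 0.1255,
                   four_doors = 0.1164, day_hour = 0.0713,
                   trafway_divided_no_median = 0.2967,
                   trafway_ramp = 0.4995, region_midwest = 0.5032,
                   light_daylight = 0.0306)
  beta_rear <- c("(Intercept)" = -0.7899,
                 age_le24 = -0.4894, age_25_63 = -0.2780, male = -0.3822,
                 alcohol = 0.2452, drugs = 0.5898,
                 airbag_not_deployed = 1.0486, belt_not_used = 1.1682,
                 mdlyr_1995_2000 = -0.1192, mdlyr_2001_2005 = -0.1669,
                 mdlyr_2006_2010 = -0.2833, mdlyr_2011_2015 = -0.2049,
                 summer = 0.0933, day_hour = -0.2304, surface_snow = -0.6991,
                 trafway_divided_no_median = 0.1426,
                 trafway_divided_median = 0.2466, trafway_oneway = 0.2140,
                 align_straight = 0.1703, region_midwest = -0.1221,
                 region_south = -0.0916, light_daylight = 0.1929)
  sigma_rear <- c("(Intercept)" = 0.2067, age_le24 = 0.3615,
                  age_25_63 = 0.0754, male = 0.3554, drugs = 0.6645,
                  belt_not_used = 0.8390, mdlyr_1995_2000 = 0.0774,
                  mdlyr_2001_2005 = 0.1782, mdlyr_2006_2010 = 0.4353,
                  summer = 0.0575, surface_snow = 0.5531,
                  trafway_divided_no_median = 0.0613)
  bivop_params(spec,
               beta_rear = beta_rear[spec$rear$coef_names],
               beta_front = beta_front[spec$front$coef_names],
               sigma_rear = sigma_rear, sigma_front = sigma_front,
               cut_rear = c(0, 0.5090, 1.3173),
               cut_front = c(0, 0.6191, 1.4814),
               rho = 0.2440)
}

#' Default covariate scheme mimicking the reference crash sample
#'
#' Prevalences follow the marginal rates of the published summary of the
#' 2011-2015 national rear-end crash sample (driver counts over 30,318
#' drivers for driver-scoped variables, crash-shared rates for environment
#' variables).  Roadway/traffic-way layout and season, which the published
#' summary reports only graphically, use plausible rates fixed here.
#'
#' @return A [covariate_scheme()].
#' @export
table2_scheme <- function() {
  covariate_scheme(
    name = c("age_le24", "age_25_63",
             "male", "alcohol", "drugs", "airbag_not_deployed",
             "belt_not_used",
             "mdlyr_1995_2000", "mdlyr_2001_2005", "mdlyr_2006_2010",
             "mdlyr_2011_2015",
             "four_doors", "speed_related",
             "day_hour", "monday", "summer",
             "light_daylight", "light_dark",
             "region_northeast", "region_midwest", "region_south",
             "align_straight", "surface_snow",
             "trafway_divided_no_median", "trafway_divided_median",
             "trafway_oneway", "trafway_ramp"),
    prevalence = c(8700 / 30318, 18867 / 30318,
                   14211 / 30318, 452 / 30318, 153 / 30318, 3891 / 30318,
                   375 / 30318,
                   4778 / 30318, 8298 / 30318, 9723 / 30318, 5765 / 30318,
                   21636 / 30318, 3369 / 30318,
                   25080 / 30318, 1 / 7, 0.25,
                   23232 / 30318, 6072 / 30318,
                   6076 / 30318, 5522 / 30318, 15174 / 30318,
                   28772 / 30318, 402 / 30318,
                   0.15, 0.25, 0.05, 0.03),
    scope = c("driver", "driver",
              "driver", "driver", "driver", "driver", "driver",
              "driver", "driver", "driver", "driver",
              "driver", "driver",
              "shared", "shared", "shared",
              "shared", "shared",
              "shared", "shared", "shared",
              "shared", "shared",
              "shared", "shared", "shared", "shared"),
    group = c("age", "age",
              NA, NA, NA, NA, NA,
              "mdlyr", "mdlyr", "mdlyr", "mdlyr",
              NA, NA,
              NA, NA, NA,
              "light", "light",
              "region", "region", "region",
              NA, NA,
              "trafway", "trafway", "trafway", "trafway"))
}
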