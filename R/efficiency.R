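# Conversion and partitioning efficiencies, and the cross-crop comparison of
# relative efficiencies against theoretical maxima.
#
# epsilon_c (%) = 100 * RUE / 57.14, where 57.14 g MJ^-1 follows from an
# assumed biomass energy content of 17.5 MJ kg^-1; epsilon_p (%) = 100 * HI.
# Relative efficiencies divide an observed efficiency by the theoretical
# maximum appropriate to the plant and crop type (epsilon_i 90% for all crops;
# epsilon_c 9.4% for C3 and 12.3% for C4 plants; epsilon_p 65% for grain/seed
# crops and 90% for storage-organ crops).

#' Efficiency constants and theoretical maxima
#'
#' @param biomass_energy energy content of vegetative biomass, MJ kg^-1.
#' @return a list with `biomass_energy` (17.5 MJ kg^-1), its reciprocal
#'   `biomass_conversion` (57.14 g MJ^-1), `seed_energy` (23 MJ kg^-1, carried
#'   as metadata for seed crops), and the theoretical maxima `max_ei` (90),
#'   `max_ec_c3` (9.4), `max_ec_c4` (12.3), `max_ep_grain` (65) and
#'   `max_ep_tuber` (90), all in percent.
#' @export
efficiency_constants <- function(biomass_energy = 17.5) {
  conv <- round_half_up(1000 / biomass_energy, 2)
  list(biomass_energy = biomass_energy,
       biomass_conversion = conv,
       seed_energy = 23,
       max_ei = 90, max_ec_c3 = 9.4, max_ec_c4 = 12.3,
       max_ep_grain = 65, max_ep_tuber = 90)
}

#' Radiation use efficiency from biomass and intercepted PAR
#'
#' `RUE = TB / PARint` on a per-square-metre basis: per-plant biomass is
#' divided by the plant ground area before the ratio.
#'
#' @param tb total dry biomass, g per plant.
#' @param par_int cumulative intercepted PAR, MJ m^-2, `> 0`.
#' @param plant_area ground area per plant, m^2.
#' @return RUE, g MJ^-1.
#' @export
rue_from_biomass <- function(tb, par_int, plant_area = 0.78) {
  assert_that(all(par_int > 0), "PARint must be positive")
  assert_that(is_number(plant_area) && plant_area > 0,
              "plant_area must be positive")
  (tb / plant_area) / par_int
}

#' Conversion efficiency
#'
#' `epsilon_c (%) = 100 * RUE / 57.14`.
#'
#' @param rue radiation use efficiency, g MJ^-1, `>= 0`.
#' @param constants see [efficiency_constants()].
#' @return epsilon_c, percent. Vectorized.
#' @export
epsilon_c <- function(rue, constants = efficiency_constants()) {
  assert_that(all(rue >= 0), "rue must be non-negative")
  100 * rue / constants$biomass_conversion
}

#' Partitioning efficiency
#'
#' `epsilon_p (%) = 100 * HI`.
#'
#' @param hi harvest index, fraction in `[0, 1]`.
#' @return epsilon_p, percent. Vectorized.
#' @export
epsilon_p <- function(hi) {
  assert_that(all(hi >= 0 & hi <= 1), "harvest index must lie in [0, 1]")
  100 * hi
}

#' Relative efficiency
#'
#' Ratio of an observed efficiency to its theoretical maximum.
#'
#' @param value observed efficiency, percent.
#' @param theoretical_max theoretical maximum, percent, `> 0`.
#' @return the fraction `value / theoretical_max`. Vectorized.
#' @export
relative_efficiency <- function(value, theoretical_max) {
  assert_that(all(theoretical_max > 0), "theoretical maximum must be positive")
  value / theoretical_max
}

#' Literature cross-crop efficiency table
#'
#' Maximum efficiencies (percent) reported in the literature for major crops,
#' shipped as a plain-text fixture.
#'
#' @return a `data.frame` with columns `plant_type` (C3/C4), `crop_type`,
#'   `crop`, `ei`, `ec`, `ep`.
#' @export
crop_efficiency_table <- function() {
  path <- system.file("extdata", "crop_efficiencies.csv",
                      package = "potatoRUE", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

ep_max_for <- function(crop_type, constants) {
  grain <- c("grain", "leguminous", "seed")
  storage <- c("tuber", "tuber root", "perennial grass")
  out <- ifelse(tolower(crop_type) %in% grain, constants$max_ep_grain,
                ifelse(tolower(crop_type) %in% storage,
                       constants$max_ep_tuber, NA_real_))
  assert_that(!anyNA(out), "unknown crop type: %s",
              paste(unique(crop_type[is.na(out)]), collapse = ", "))
  out
}

ec_max_for <- function(plant_type, constants) {
  out <- ifelse(toupper(plant_type) == "C3", constants$max_ec_c3,
                ifelse(toupper(plant_type) == "C4", constants$max_ec_c4,
                       NA_real_))
  assert_that(!anyNA(out), "unknown plant type: %s",
              paste(unique(plant_type[is.na(out)]), collapse = ", "))
  out
}

#' Cross-crop comparison of relative efficiencies
#'
#' Injects the study's potato maxima into the literature table, computes each
#' crop's relative efficiencies against the type-appropriate theoretical
#' maxima (reported half-up to two decimals), and ranks crops by each.
#'
#' @param potato named numeric vector with the potato maxima `ei`, `ec`, `ep`
#'   (percent).
#' @param table literature table, see [crop_efficiency_table()].
#' @param constants see [efficiency_constants()].
#' @return the table with added columns `rel_ei`, `rel_ec`, `rel_ep` and ranks
#'   `rank_ei`, `rank_ec`, `rank_ep` (1 = highest relative efficiency).
#' @export
crop_comparison <- function(potato, table = crop_efficiency_table(),
                            constants = efficiency_constants()) {
  assert_that(all(c("ei", "ec", "ep") %in% names(potato)),
              "potato must name ei, ec and ep")
  tab <- rbind(table,
               data.frame(plant_type = "C3", crop_type = "tuber",
                          crop = "Potato", ei = potato[["ei"]],
                          ec = potato[["ec"]], ep = potato[["ep"]]))
  tab$rel_ei <- round_half_up(relative_efficiency(tab$ei, constants$max_ei), 2)
  tab$rel_ec <- round_half_up(
    relative_efficiency(tab$ec, ec_max_for(tab$plant_type, constants)), 2)
  tab$rel_ep <- round_half_up(
    relative_efficiency(tab$ep, ep_max_for(tab$crop_type, constants)), 2)
  tab$rank_ei <- rank(-tab$rel_ei, ties.method = "min")
  tab$rank_ec <- rank(-tab$rel_ec, ties.method = "min")
  tab$rank_ep <- rank(-tab$rel_ep, ties.method = "min")
  tab
}

#' Assemble an accession's efficiency set
#'
#' Bundles interception, conversion and partitioning efficiencies with their
#' inputs, enforcing the range invariants.
#'
#' @param accession accession identifier.
#' @param radiation a [radiation_summary()].
#' @param growth a [simulate_growth()] result.
#' @param ty observed dry tuber yield, g per plant (defaults to the simulated
#'   value).
#' @param plant_area ground area per plant, m^2.
#' @param constants see [efficiency_constants()].
#' @return one-row `data.frame` with `accession`, `epsilon_i`, `epsilon_c`,
#'   `epsilon_p` (percent), `rue` (g MJ^-1), `par_int` (MJ m^-2) and `ty`
#'   (g per plant).
#' @export
efficiency_set <- function(accession, radiation, growth, ty = growth$ty_sim,
                           plant_area = 0.78,
                           constants = efficiency_constants()) {
  rue <- rue_from_biomass(growth$tb, radiation$par_int_cum, plant_area)
  out <- data.frame(accession = accession,
                    epsilon_i = radiation$epsilon_i,
                    epsilon_c = epsilon_c(rue, constants),
                    epsilon_p = epsilon_p(growth$hi),
                    rue = rue,
                    par_int = radiation$par_int_cum,
                    ty = ty)
  assert_that(all(out$epsilon_i >= 0 & out$epsilon_i <= 100) &&
                all(out$epsilon_p >= 0 & out$epsilon_p <= 100),
              "efficiencies must lie in [0, 100]")
  out
}
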