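#' Nutrition composition and unit-conversion constants
#'
#' Conversion constants linking caloric rates to glucose appearance in the
#' model. Defaults describe a low-carbohydrate enteral formula
#' (74.6 g/L carbohydrate, 50 g/L protein, 1.0 kcal/mL), so roughly 30% of
#' enteral calories are carbohydrate; parenteral nutrition is assumed
#' dextrose-dominated.
#'
#' @param en_cho_frac fraction of enteral calories that are carbohydrate.
#' @param pn_cho_frac fraction of parenteral calories that are carbohydrate.
#' @param kcal_per_g_cho Atwater factor for carbohydrate (kcal/g).
#' @param g_per_mmol_glucose grams of glucose per mmol (0.18).
#' @return Named list of class \code{feed_composition}.
#' @examples feed_composition()
#' @export
feed_composition <- function(en_cho_frac = 74.6 * 4 / 1000,
                             pn_cho_frac = 0.6,
                             kcal_per_g_cho = 4,
                             g_per_mmol_glucose = 0.18) {
  stopifnot(en_cho_frac > 0, en_cho_frac <= 1, pn_cho_frac > 0,
            pn_cho_frac <= 1)
  structure(list(en_cho_frac = en_cho_frac, pn_cho_frac = pn_cho_frac,
                 kcal_per_g_cho = kcal_per_g_cho,
                 g_per_mmol_glucose = g_per_mmol_glucose),
            class = "feed_composition")
}

#' Convert a caloric rate to a model glucose appearance rate
#' @param kcal_h caloric delivery rate (kcal/h).
#' @param cho_frac carbohydrate fraction of those calories.
#' @param feed \code{\link{feed_composition}} (for the Atwater and molar
#'   constants).
#' @return glucose rate (mmol/min).
#' @examples kcal_h_to_glucose_mmol_min(75, cho_frac = 0.3)
#' @export
kcal_h_to_glucose_mmol_min <- function(kcal_h, cho_frac,
                                       feed = feed_composition()) {
  kcal_h / 60 * cho_frac / feed$kcal_per_g_cho / feed$g_per_mmol_glucose
}

#' Enteral rate as percent of caloric goal to glucose appearance
#' @param en_pct enteral rate (% of daily caloric goal).
#' @param goal_kcal daily caloric goal (kcal/day).
#' @param feed \code{\link{feed_composition}}.
#' @return glucose rate (mmol/min).
#' @examples en_pct_to_glucose_mmol_min(100, 2000)
#' @export
en_pct_to_glucose_mmol_min <- function(en_pct, goal_kcal,
                                       feed = feed_composition()) {
  kcal_h_to_glucose_mmol_min(en_pct / 100 * goal_kcal / 24,
                             feed$en_cho_frac, feed)
}
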