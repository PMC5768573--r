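#' Patient demographics for caloric-goal estimation
#' @param frame subjective frame size: "small", "medium" or "large".
#' @param age age in years (>= 16, adult ICU).
#' @param sex "male" or "female".
#' @return An object of class \code{demographics}.
#' @examples demographics("medium", 50, "male")
#' @export
demographics <- function(frame, age, sex) {
  frame <- match.arg(frame, c("small", "medium", "large"))
  sex <- match.arg(sex, c("male", "female"))
  if (!is.finite(age) || age < 16) stop("age must be >= 16 years")
  structure(list(frame = frame, age = age, sex = sex), class = "demographics")
}

#' Weight-surrogate coefficients for the daily caloric goal
#'
#' Patients are not routinely weighed on ICU admission, so the caloric goal
#' is anchored to an 80 kg reference adult, modified by frame size (F), age
#' band (A) and sex (G):
#' F = 0.9 / 1.0 / 1.1 for small / medium / large frame;
#' A = 1.1 / 1.0 / 0.9 / 0.8 for ages <= 39 / 40-59 / 60-79 / >= 80;
#' G = 1.0 / 0.8 for male / female.
#'
#' @param d \code{\link{demographics}}.
#' @return Named numeric vector \code{c(A, F, G)}.
#' @examples caloric_coefficients(demographics("small", 85, "female"))
#' @export
caloric_coefficients <- function(d) {
  stopifnot(inherits(d, "demographics"))
  F <- c(small = 0.9, medium = 1.0, large = 1.1)[[d$frame]]
  A <- if (d$age <= 39) 1.1 else if (d$age <= 59) 1.0 else
       if (d$age <= 79) 0.9 else 0.8
  G <- c(male = 1.0, female = 0.8)[[d$sex]]
  c(A = A, F = F, G = G)
}

#' Daily caloric goal (kcal/day)
#'
#' Computes the ACCP-style patient-specific caloric goal
#' \eqn{A \cdot F \cdot G \cdot 80\,\mathrm{kg} \cdot 25\,\mathrm{kcal/kg/day}},
#' spanning 1152-2420 kcal/day over all coefficient combinations. If a
#' measured weight is supplied it overrides the demographic surrogate
#' (goal = weight x kcal_per_kg).
#'
#' @param d \code{\link{demographics}}.
#' @param weight_kg optional measured body weight (kg).
#' @param ref_weight_kg reference weight of the surrogate (kg).
#' @param kcal_per_kg guideline energy target (kcal/kg/day).
#' @return kcal/day.
#' @examples
#' daily_goal_kcal(demographics("medium", 50, "male"))   # 2000
#' daily_goal_kcal(demographics("large", 30, "male"))    # 2420
#' @export
daily_goal_kcal <- function(d, weight_kg = NULL, ref_weight_kg = 80,
                            kcal_per_kg = 25) {
  if (!is.null(weight_kg)) {
    if (weight_kg <= 0) stop("weight must be positive")
    return(weight_kg * kcal_per_kg)
  }
  cf <- caloric_coefficients(d)
  # one-decimal coefficients: round away binary representation dust
  round(unname(cf["A"] * cf["F"] * cf["G"] * ref_weight_kg * kcal_per_kg), 6)
}

#' Enumerate all caloric-goal coefficient combinations
#'
#' Exhaustively evaluates the goal over the 3 frame x 4 age-band x 2 sex
#' grid; the range of the resulting 24 goals is 1152-2420 kcal/day.
#'
#' @inheritParams daily_goal_kcal
#' @return Data frame with columns frame, age_band, sex, A, F, G, goal_kcal.
#' @examples range(enumerate_caloric_goals()$goal_kcal)
#' @export
enumerate_caloric_goals <- function(ref_weight_kg = 80, kcal_per_kg = 25) {
  ages <- c("<=39" = 30, "40-59" = 50, "60-79" = 70, ">=80" = 85)
  grid <- expand.grid(frame = c("small", "medium", "large"),
                      age_band = names(ages),
                      sex = c("male", "female"),
                      stringsAsFactors = FALSE)
  cf <- t(vapply(seq_len(nrow(grid)), function(i) {
    caloric_coefficients(demographics(grid$frame[i], ages[[grid$age_band[i]]],
                                      grid$sex[i]))
  }, numeric(3)))
  grid$A <- cf[, "A"]; grid$F <- cf[, "F"]; grid$G <- cf[, "G"]
  grid$goal_kcal <- round(grid$A * grid$F * grid$G * ref_weight_kg *
                            kcal_per_kg, 6)
  grid
}
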