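#' Admissible experimental conditions for a simulated attempt
#'
#' The condition grid the simulator draws from: pass source, movement and
#' positioning of the receiver, pass style, catch style, athlete level and
#' environment.
#'
#' @return Named list of character vectors, one per condition.
#' @export
scenario_levels <- function() {
  list(
    outcome       = c("catch", "drop"),
    pass_source   = c("human_quarterback", "passing_machine"),
    movement      = c("standing", "running_left", "running_right",
                      "running_towards", "running_away", "jumping"),
    positioning   = c("facing_towards", "sideways", "facing_away"),
    pass_style    = c("high", "low", "off_target", "over_shoulder"),
    catch_style   = c("one_handed", "two_handed", "body_catch"),
    athlete_level = c("novice", "advanced", "expert"),
    environment   = c("indoor", "outdoor")
  )
}

#' Describe one attempt scenario
#'
#' @param outcome "catch" or "drop".
#' @param pass_source,movement,positioning,pass_style,catch_style,athlete_level,environment
#'   categorical condition labels; see [scenario_levels()] for admissible
#'   values.
#' @return An object of class `attempt_scenario`.
#' @export
#' @examples
#' attempt_scenario("catch", catch_style = "two_handed")
attempt_scenario <- function(outcome = "catch",
                             pass_source = "human_quarterback",
                             movement = "standing",
                             positioning = "facing_towards",
                             pass_style = "high",
                             catch_style = "two_handed",
                             athlete_level = "advanced",
                             environment = "indoor") {
  sc <- list(outcome = outcome, pass_source = pass_source, movement = movement,
             positioning = positioning, pass_style = pass_style,
             catch_style = catch_style, athlete_level = athlete_level,
             environment = environment)
  lv <- scenario_levels()
  for (f in names(sc)) {
    if (!is.character(sc[[f]]) || length(sc[[f]]) != 1L || !(sc[[f]] %in% lv[[f]]))
      stop("invalid value for scenario field '", f, "': ",
           deparse(sc[[f]]), " (allowed: ", paste(lv[[f]], collapse = ", "), ")")
  }
  structure(sc, class = "attempt_scenario")
}

#' @export
print.attempt_scenario <- function(x, ...) {
  cat("<attempt_scenario> ", x$outcome, "\n", sep = "")
  for (f in setdiff(names(x), "outcome"))
    cat("  ", format(f, width = 13), x[[f]], "\n", sep = "")
  invisible(x)
}

random_scenario <- function(outcome) {
  lv <- scenario_levels()
  draw <- lapply(lv[setdiff(names(lv), "outcome")], sample, size = 1L)
  do.call(attempt_scenario, c(list(outcome = outcome), draw))
}
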