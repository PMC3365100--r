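# Applying a fitted model to an unlabeled deployment and turning the
# classified fixes into diurnal/nocturnal per-habitat time-activity
# budgets. Each fix carries equal weight; the proportion for a
# (phase, habitat, behaviour) cell is its count divided by the total
# number of fixes in that diel phase, so proportions within a phase sum
# to 1 across habitat x behaviour.

#' Classify every fix of a deployment
#'
#' Pairs each acceleration segment with its GPS fix, extracts the
#' predictor set and predicts a behaviour with the fitted model.
#'
#' @param model A `behaviour_model` or a bare `cart_tree`.
#' @param fixes,segments Deployment tables as returned by [read_study()]
#'   or [simulate_study()].
#' @return The paired records with a `behaviour` column of predicted
#'   labels.
#' @export
classify_deployment <- function(model, fixes, segments) {
  recs <- dplyr::inner_join(
    segments, fixes,
    by = dplyr::join_by("bird_id", "start_time" == "time"))
  if (nrow(recs) < nrow(segments))
    stop(nrow(segments) - nrow(recs),
         " segment(s) could not be paired to a fix", call. = FALSE)
  if (nrow(recs) == 0) {
    return(dplyr::mutate(recs, behaviour = character(0)))
  }
  feats <- extract_features(recs)
  feats$behaviour <- predict(model, feats)
  feats
}

#' Compute a diurnal/nocturnal per-habitat time-activity budget
#'
#' Counts classified fixes per (bird, diel phase, habitat, behaviour) and
#' divides by the total count of that bird's fixes in the phase.
#'
#' @param classified Tibble with `bird_id`, `phase`, `habitat`,
#'   `behaviour` (e.g. [classify_deployment()] output after
#'   [assign_habitat()] and [diel_phase()]).
#' @return A `time_budget` tibble: `bird_id`, `phase`, `habitat`,
#'   `behaviour`, `count`, `proportion`, plus per-phase totals in
#'   `attr(, "phase_totals")`. Within each bird and phase the proportions
#'   sum to 1.
#' @export
compute_budget <- function(classified) {
  need <- c("bird_id", "phase", "habitat", "behaviour")
  stopifnot(all(need %in% names(classified)))
  totals <- dplyr::count(classified, .data$bird_id, .data$phase,
                         name = "total")
  out <- dplyr::count(classified, .data$bird_id, .data$phase,
                      .data$habitat, .data$behaviour, name = "count")
  out <- dplyr::left_join(out, totals, by = c("bird_id", "phase"))
  out <- dplyr::mutate(out, proportion = .data$count / .data$total)
  out <- dplyr::select(out, -"total")
  class(out) <- c("time_budget", class(out))
  attr(out, "phase_totals") <- totals
  out
}

#' Summarize a time budget as whole-percent shares per behaviour
#'
#' Marginal over habitats: the percentage of a bird's fixes in each diel
#' phase spent on each behaviour, rounded to whole percents.
#'
#' @param budget A `time_budget`.
#' @return Tibble `bird_id`, `phase`, `behaviour`, `percent`.
#' @export
budget_summary <- function(budget) {
  out <- dplyr::summarise(
    dplyr::group_by(budget, .data$bird_id, .data$phase, .data$behaviour),
    proportion = sum(.data$proportion), .groups = "drop")
  dplyr::mutate(out, percent = round(100 * .data$proportion))[
    c("bird_id", "phase", "behaviour", "percent")]
}

#' Run a full deployment analysis
#'
#' Convenience pipeline: classify all fixes with a fitted model, assign
#' habitat (territory / salt marsh / mudflats) and diel phase, and
#' compute the time budget.
#'
#' @param model A `behaviour_model` or `cart_tree`.
#' @param study A list with `fixes`, `segments`, `nests`, `habitat`
#'   (from [read_study()] or [simulate_study()]).
#' @param territory_radius_m Territory radius around the nest (m).
#' @param lat,lon Reference coordinates for the day/night split.
#' @return A list with `classified` (per-fix tibble) and `budget`
#'   (`time_budget`).
#' @export
deployment_budget <- function(model, study, territory_radius_m = 150,
                              lat = 53.47, lon = 6.23) {
  cls <- classify_deployment(model, study$fixes, study$segments)
  cls <- assign_habitat(cls, study$nests, study$habitat,
                        territory_radius_m = territory_radius_m)
  cls$phase <- diel_phase(cls$start_time, lat = lat, lon = lon)
  list(classified = cls, budget = compute_budget(cls))
}
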