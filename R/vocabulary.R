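# Ethogram used throughout: 8 main behaviours, 16 sub-behaviours, and the
# a-priori 3-class grouping (fly / terrestrial locomotion / no locomotion)
# used to calibrate the coarse models.

.vocab <- function() {
  tibble::tribble(
    ~behaviour,   ~sub_behaviour,          ~class3,
    "Aggression", "Bobbing",               "No locomotion",
    "Aggression", "Chasing",               "Terrestrial locomotion",
    "Aggression", "Stand Solitary piping", "No locomotion",
    "Aggression", "Piping ceremony",       "Terrestrial locomotion",
    "Aggression", "Walk Solitary piping",  "Terrestrial locomotion",
    "Body care",  "Preen",                 "No locomotion",
    "Body care",  "Wash",                  "No locomotion",
    "Fly",        "normal flight",         "Fly",
    "Forage",     "By sight",              "Terrestrial locomotion",
    "Forage",     "By touch",              "Terrestrial locomotion",
    "Handle",     "Handling at surface",   "No locomotion",
    "Handle",     "Handling in situ",      "No locomotion",
    "Handle",     "Walking with prey",     "Terrestrial locomotion",
    "Sit",        "Sit",                   "No locomotion",
    "Stand",      "Stand",                 "No locomotion",
    "Walk",       "Walk",                  "Terrestrial locomotion"
  )
}

#' Behaviour vocabulary of the field protocol
#'
#' The ethogram linking visually observed behaviours to sensor records:
#' 8 exhaustive and mutually exclusive main behaviours, their 16
#' sub-behaviours, and the a-priori 3-class grouping (`Fly`,
#' `Terrestrial locomotion`, `No locomotion`) used for the coarse
#' classification models. Main behaviours with no finer subdivision
#' (`Sit`, `Stand`, `Walk`) carry a sub-behaviour equal to the behaviour.
#'
#' @return A tibble with columns `behaviour`, `sub_behaviour`, `class3`.
#' @export
#' @examples
#' behaviour_vocabulary()
behaviour_vocabulary <- function() .vocab()

#' Main behaviour labels
#' @return Character vector of the 8 main behaviour labels.
#' @export
main_behaviours <- function() unique(.vocab()$behaviour)

assert_behaviour <- function(labels) {
  bad <- setdiff(unique(labels), main_behaviours())
  if (length(bad) > 0) {
    stop("unknown behaviour label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(labels)
}

#' Reclassify sub-behaviours into a model class scheme
#'
#' Maps sub-behaviour labels to the classes a model is trained on. The
#' 3-class scheme follows the a-priori grouping of the ethogram and operates
#' at sub-behaviour level, because some main behaviours (Aggression, Handle)
#' contain both locomotory and stationary sub-behaviours. The 8-class scheme
#' maps each sub-behaviour to its main behaviour.
#'
#' @param labels Character vector of sub-behaviour labels (for main
#'   behaviours without subdivision, the main-behaviour label itself).
#' @param scheme `"3-class"` or `"8-class"`.
#' @return Character vector of class labels, same length as `labels`.
#' @export
#' @examples
#' reclassify_behaviour(c("Preen", "By sight"), "3-class")
#' reclassify_behaviour("Walking with prey", "8-class")
reclassify_behaviour <- function(labels, scheme = c("3-class", "8-class")) {
  scheme <- match.arg(scheme)
  v <- .vocab()
  idx <- match(labels, v$sub_behaviour)
  if (anyNA(idx[!is.na(labels)])) {
    bad <- unique(labels[is.na(idx) & !is.na(labels)])
    stop("unknown sub-behaviour label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (scheme == "3-class") v$class3[idx] else v$behaviour[idx]
}
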