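# Joining sensor records to visual observations. An observation log is a
# sequence of behaviour-change times per bird; each change opens an
# interval that lasts until the next change, or until the session ends
# (last logged change + the 30 min session cap). A 3 s acceleration
# segment gets the behaviour whose interval fully contains it. Because the
# observer's handheld computer could log a change up to `max_delay_s`
# late, every interval is also widened by that margin; when more than one
# widened interval could cover a segment, the true behaviour during the
# segment is uncertain and the record is flagged ambiguous.

SESSION_CAP_S <- 30 * 60

#' Label sensor records with observed behaviours
#'
#' Joins each acceleration segment (and its GPS fix) to the visual
#' observation log of the same bird. A segment is labeled when exactly one
#' observation interval `[start_i, start_{i+1})` contains the whole 3 s
#' segment; it is flagged `ambiguous` when, after widening interval
#' boundaries by `max_delay_s` (the maximum recording delay of the
#' handheld logger), more than one behaviour could cover it. Segments
#' outside any observation session stay unlabeled (`NA`).
#'
#' @param fixes Tibble of GPS fixes (`bird_id`, `time`, `lat`, `lon`,
#'   `alt_m`, `speed_ms`).
#' @param segments Tibble of acceleration segments (`bird_id`,
#'   `start_time`, `rate`, `duration`, list-columns `x`, `y`, `z`).
#' @param observations Tibble of observation records (`bird_id`,
#'   `start_time`, `behaviour`, `sub_behaviour`).
#' @param max_delay_s Maximum recording delay (s) of the observation log.
#' @param session_cap_s An observation session is taken to end this many
#'   seconds after its last logged record.
#' @return The segments joined to their fixes, with columns `behaviour`,
#'   `sub_behaviour` (NA when unlabeled) and logical `ambiguous`.
#' @export
label_records <- function(fixes, segments, observations, max_delay_s = 10,
                          session_cap_s = SESSION_CAP_S) {
  stopifnot(max_delay_s >= 0)
  recs <- dplyr::inner_join(
    segments, fixes,
    by = dplyr::join_by("bird_id", "start_time" == "time"))
  if (nrow(segments) > 0 && nrow(recs) == 0 && nrow(fixes) > 0)
    stop("no segment could be paired to a fix; check bird_id and times",
         call. = FALSE)
  recs <- dplyr::arrange(recs, .data$bird_id, .data$start_time)
  recs$behaviour <- NA_character_
  recs$sub_behaviour <- NA_character_
  recs$ambiguous <- FALSE
  if (nrow(recs) == 0 || nrow(observations) == 0) return(recs)

  obs_split <- split(observations, observations$bird_id)
  for (bird in names(obs_split)) {
    ob <- dplyr::arrange(obs_split[[bird]], .data$start_time)
    # session boundaries: a gap longer than the session cap starts a new
    # session; each interval ends at the next record or the session end
    t0 <- as.numeric(ob$start_time)
    gap_next <- c(diff(t0), Inf)
    int_end <- ifelse(gap_next > session_cap_s, t0 + session_cap_s,
                      t0 + gap_next)
    idx <- which(recs$bird_id == bird)
    if (length(idx) == 0) next
    s0 <- as.numeric(recs$start_time[idx])
    s1 <- s0 + recs$duration[idx]
    for (j in seq_along(idx)) {
      contains <- t0 <= s0[j] & s1[j] <= int_end
      widened <- (t0 - max_delay_s) <= s0[j] &
        s1[j] <= (int_end + max_delay_s)
      k <- idx[j]
      if (sum(contains) == 1) {
        recs$behaviour[k] <- ob$behaviour[contains]
        recs$sub_behaviour[k] <- ob$sub_behaviour[contains]
      }
      recs$ambiguous[k] <- sum(widened) > 1
    }
  }
  recs
}

#' Filter labeled records for model fitting
#'
#' Removes records that cannot be used to calibrate a classifier: records
#' with no behaviour label, records flagged ambiguous (a behaviour change
#' may have fallen inside the segment's delay-uncertainty window),
#' duplicate `(bird_id, time)` keys, and malformed segments that do not
#' carry `rate * duration` finite samples on every axis. Filtering is
#' idempotent.
#'
#' @param records Output of [label_records()].
#' @return The retained records; the counts removed per reason are
#'   attached as `attr(, "filter_report")` (a tibble `reason`, `n`).
#' @export
filter_records <- function(records) {
  n_samp <- records$rate * records$duration
  ok_seg <- vapply(seq_len(nrow(records)), function(i) {
    length(records$x[[i]]) == n_samp[i] && all(is.finite(records$x[[i]])) &&
      length(records$y[[i]]) == n_samp[i] && all(is.finite(records$y[[i]])) &&
      length(records$z[[i]]) == n_samp[i] && all(is.finite(records$z[[i]]))
  }, logical(1))
  dup <- duplicated(paste(records$bird_id, records$start_time))
  unlabeled <- is.na(records$behaviour)
  ambiguous <- !unlabeled & records$ambiguous

  drop_malformed <- !ok_seg
  drop_dup <- ok_seg & dup
  drop_unlab <- ok_seg & !dup & unlabeled
  drop_ambig <- ok_seg & !dup & !unlabeled & ambiguous
  keep <- !(drop_malformed | drop_dup | drop_unlab | drop_ambig)

  report <- tibble::tibble(
    reason = c("malformed segment", "duplicate key", "unlabeled",
               "ambiguous"),
    n = c(sum(drop_malformed), sum(drop_dup), sum(drop_unlab),
          sum(drop_ambig)))
  out <- records[keep, , drop = FALSE]
  attr(out, "filter_report") <- report
  out
}
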