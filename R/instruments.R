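#' SNOT-20 sum score and subscores
#'
#' The 20 items of the Sino-Nasal Outcome Test are rated 0 ("no problem") to
#' 5 ("it can't get any worse"). Three subscores are expressed as percent of
#' the respective item-block maximum: primary nasal symptoms (items 1, 2, 3,
#' 5, 10; maximum 25), secondary nasal symptoms (items 4, 6, 7, 8, 9, 12;
#' maximum 30) and general quality of life (items 11, 13-20; maximum 45).
#'
#' @param ratings integer vector of length 20, each element in 0..5
#'   (1-based item order).
#' @return A list with elements `primary_nasal`, `secondary_nasal`,
#'   `general_qol` (each a percentage in \[0, 100\]) and `sum_score`
#'   (0..100, the plain sum of all 20 ratings).
#' @export
snot20_scores <- function(ratings) {
  if (length(ratings) != 20) stop("exactly 20 SNOT-20 item ratings are required")
  if (anyNA(ratings)) stop("missing item ratings are not allowed")
  if (any(ratings != round(ratings)) || any(ratings < 0) || any(ratings > 5))
    stop("SNOT-20 item ratings must be integers in 0..5")
  list(
    primary_nasal   = sum(ratings[c(1, 2, 3, 5, 10)]) / 25 * 100,
    secondary_nasal = sum(ratings[c(4, 6, 7, 8, 9, 12)]) / 30 * 100,
    general_qol     = sum(ratings[c(11, 13:20)]) / 45 * 100,
    sum_score       = sum(ratings)
  )
}

#' Symptom-freedom flags from SNOT-20 scores
#'
#' No-to-minor symptoms are inferred from a total sum score < 12, general
#' quality of life < 14, primary nasal symptoms < 12 or secondary nasal
#' symptoms < 10.5 (all comparisons strict).
#'
#' @param scores a list as returned by [snot20_scores()].
#' @return Named logical vector with elements `total`, `general`,
#'   `primary`, `secondary`.
#' @export
snot20_symptom_free <- function(scores) {
  c(total     = scores$sum_score < 12,
    general   = scores$general_qol < 14,
    primary   = scores$primary_nasal < 12,
    secondary = scores$secondary_nasal < 10.5)
}

#' Olfactory diagnosis from the TDI sum score
#'
#' The Sniffin' Sticks TDI sum (threshold + discrimination + identification)
#' maps to functional anosmia (< 16.5), hyposmia (16.5 to 30.5, boundaries
#' included) or normosmia (> 30.5).
#'
#' @param tdi numeric vector of TDI sum scores (>= 0).
#' @return factor with levels `anosmia`, `hyposmia`, `normosmia`.
#' @export
olfactory_diagnosis <- function(tdi) {
  if (any(tdi < 0, na.rm = TRUE)) stop("TDI scores must be non-negative")
  out <- ifelse(tdi < 16.5, "anosmia", ifelse(tdi <= 30.5, "hyposmia", "normosmia"))
  factor(out, levels = c("anosmia", "hyposmia", "normosmia"))
}

#' Subjectively perceptible olfactory improvement
#'
#' An increase in the TDI score of at least 5.5 points is the conventional
#' threshold for a subjectively perceptible change.
#'
#' @param tdi_pre,tdi_post TDI sum scores before and after surgery.
#' @return logical; `TRUE` iff `tdi_post - tdi_pre >= 5.5`.
#' @export
perceptible_improvement <- function(tdi_pre, tdi_post) {
  (tdi_post - tdi_pre) >= 5.5
}

#' Endoscopic score totals
#'
#' The Lildholdt score sums the per-side polyp size grade (0..3 per nostril,
#' total 0..6; 0 = no polyps). The Lund-Kennedy score sums five endoscopic
#' findings (polyps, edema, discharge, scarring, crusting), each graded 0..2
#' per side (total 0..20); a total below 2 is read as no significant
#' endoscopic findings.
#'
#' @param per_side_polyp_grades integer vector of length 2, each 0..3.
#' @param per_side_lk_items numeric matrix or vector of 10 grades
#'   (5 findings x 2 sides), each 0..2.
#' @return list with `lildholdt` (0..6), `lund_kennedy` (0..20) and
#'   `lk_no_findings` (logical, `lund_kennedy < 2`).
#' @export
endoscopic_totals <- function(per_side_polyp_grades, per_side_lk_items) {
  g <- as.numeric(per_side_polyp_grades)
  lk <- as.numeric(per_side_lk_items)
  if (length(g) != 2 || any(g != round(g)) || any(g < 0) || any(g > 3))
    stop("polyp grades must be two integers in 0..3")
  if (length(lk) != 10 || any(lk != round(lk)) || any(lk < 0) || any(lk > 2))
    stop("Lund-Kennedy items must be 10 integers (5 findings x 2 sides) in 0..2")
  total_lk <- sum(lk)
  list(lildholdt = sum(g), lund_kennedy = total_lk, lk_no_findings = total_lk < 2)
}
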