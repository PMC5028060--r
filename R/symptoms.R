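#' Canonical symptom identifiers
#'
#' The five a-priori selected psychopathology items, in the fixed order used
#' for every matrix row/column and table in the package: three psychosis
#' items (suspiciousness/paranoia, hearing voices, losing control) and two
#' opposite-pole affect items (down, relaxed). All are momentary self-ratings
#' on a 1--7 Likert scale ('1' not at all, '7' very).
#'
#' @return Character vector of the five symptom identifiers, in canonical
#'   order: `down`, `loss_of_control`, `paranoia`, `hearing_voices`,
#'   `relaxed`.
#' @export
#' @examples
#' esm_symptoms()
esm_symptoms <- function() {
  c("down", "loss_of_control", "paranoia", "hearing_voices", "relaxed")
}

#' Display labels for the canonical symptoms
#'
#' @return Named character vector mapping symptom identifiers to display
#'   labels ("Down", "Loss of control", ...).
#' @export
esm_symptom_labels <- function() {
  c(down = "Down",
    loss_of_control = "Loss of control",
    paranoia = "Paranoia",
    hearing_voices = "Hearing voices",
    relaxed = "Relaxed")
}

#' Relapse-state labels
#'
#' @return Character vector of the three state labels in increasing
#'   severity order.
#' @export
esm_states <- function() {
  c("stable", "impending_relapse", "full_relapse")
}

# Sampling-window constants (minutes since midnight): beeps are scheduled
# randomly between 7:30 AM and 10:30 PM, consecutive beeps 10 min - 3 h apart.
.esm_window <- c(450, 1350)
.esm_gap_bounds <- c(10, 180)
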