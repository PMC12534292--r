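#' The 12 key symptom families
#'
#' Early PSP subtyping rests on 12 symptom and sign families chosen to span
#' the known clinical spectrum of progressive supranuclear palsy: ocular motor
#' dysfunction, postural instability (repeated falls / falling backwards),
#' bradykinesia, rigidity, rest tremor, akinesia (including gait freezing),
#' frontal presentation (at least one behavioral or dysexecutive feature),
#' speech/language disorder, cortical signs (apraxia, cortical sensory
#' deficit, simultanagnosia, alien limb), limb rigidity/limb myoclonus, upper
#' or lower motor neuron signs, and ataxia.
#'
#' @return Character vector of the 12 symptom codes, in canonical order.
#' @export
#' @examples
#' psp_symptoms()
psp_symptoms <- function() {
  c("ocular_motor", "postural_instability", "bradykinesia", "rigidity",
    "rest_tremor", "akinesia", "frontal_presentation", "speech_language",
    "cortical_signs", "limb_rigidity_myoclonus", "motor_neuron_signs",
    "ataxia")
}

#' Composite features used by the subtyping tree
#'
#' The decision tree operates on five composite manifestations. Four are
#' single symptom families (frontal presentation, postural instability,
#' speech/language disorder, ocular motor dysfunction); the fifth,
#' parkinsonism, is present when any of bradykinesia, rigidity, or rest
#' tremor is present. Each symptom code belongs to at most one composite.
#'
#' @return Named list mapping composite name to the character vector of its
#'   constituent symptom codes.
#' @export
#' @examples
#' psp_composites()$parkinsonism
psp_composites <- function() {
  list(
    frontal      = "frontal_presentation",
    pi           = "postural_instability",
    sl           = "speech_language",
    om           = "ocular_motor",
    parkinsonism = c("bradykinesia", "rigidity", "rest_tremor")
  )
}

#' The eight early-subtype labels
#'
#' Seven named subtypes plus a miscellaneous class for patients without any of
#' the five composite manifestations in the early window.
#'
#' @return Character vector of the 8 labels.
#' @export
psp_labels <- function() {
  c("PSP-PF", "PSP-RS", "PSP-PI", "PSP-P", "PSP-SL", "PSP-F", "PSP-OM",
    "Misc")
}

# tri-state status codes used throughout: present / absent / not evaluated
.tristate <- c("P", "A", "N")
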