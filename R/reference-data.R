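# Published adult qualification data.

#' Adult model-qualification PK dataset
#'
#' Predicted and observed PK parameters (AUC to the last sample, Cmax,
#' terminal half-life) for the 16 healthy volunteers of the single-dose
#' escalation study used to qualify the adult asunercept model, as published
#' with the adult model. Half-life pairs are available for 14 of the 16
#' subjects (the lowest dose group lacked a terminal estimate).
#'
#' @return data.frame with one row per subject: dose (mg/kg), subject id,
#'   and predicted/observed `auc_last` (h*ug/mL), `cmax` (ug/mL) and
#'   `half_life` (h).
#' @export
adult_qualification_pk <- function() {
  utils::read.csv(system.file("extdata", "adult_qualification_pk.csv",
                              package = "asunpbpk"),
                  colClasses = c(id = "character"))
}
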