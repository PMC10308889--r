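#' Classify a sample pair into an assembly subprocess
#'
#' Two-step decision: a bNTI below -2 indicates homogeneous selection and
#' above +2 heterogeneous selection; otherwise RC-bray above +0.95 indicates
#' dispersal limitation, below -0.95 homogenizing dispersal, and anything
#' else drift. Inequalities are strict; values exactly on a boundary fall to
#' the stochastic/inner region. A degenerate bNTI (`NA` from a zero-variance
#' null) is classified by RC alone.
#'
#' @param bnti numeric vector of bNTI values (`NA` = degenerate null).
#' @param rc numeric vector of RC-bray values in \[-1, 1\].
#' @return factor with the five process levels.
#' @export
classify_pair <- function(bnti, rc) {
  if (length(bnti) != length(rc))
    stop("bnti and rc must have equal length", call. = FALSE)
  if (any(is.nan(bnti)) || any(is.nan(rc)) || anyNA(rc))
    stop("classify_pair: NaN/NA inputs (rc must be defined; use NA bnti only for degenerate nulls)",
         call. = FALSE)
  if (any(rc < -1 | rc > 1))
    stop("rc must lie in [-1, 1]", call. = FALSE)
  out <- ifelse(!is.na(bnti) & bnti < -2, "homogeneous_selection",
         ifelse(!is.na(bnti) & bnti > 2, "heterogeneous_selection",
         ifelse(rc > 0.95, "dispersal_limitation",
         ifelse(rc < -0.95, "homogenizing_dispersal", "drift"))))
  factor(out, levels = process_levels())
}

#' Is a process deterministic?
#' @param process factor/character of process labels.
#' @return logical; TRUE for the two selection subprocesses.
#' @export
is_deterministic <- function(process) {
  as.character(process) %in% c("heterogeneous_selection", "homogeneous_selection")
}
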