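#' Build a stage cohort for the interception simulator
#'
#' @param original numeric vector of 4 per-stage (I-IV) case counts.
#' @param cumulative cumulative screening sensitivity per stage
#'   (non-decreasing, in [0,1]).  Marginal sensitivity per stage is the
#'   difference from the previous stage (stage I marginal = its
#'   cumulative).
#' @param screened logical per stage: is screening performed at that
#'   stage (default all TRUE).
#' @param marginal optional explicit marginal sensitivities; must agree
#'   with \code{diff(c(0, cumulative))} to 1e-9.
#' @return a \linkS4class{StageCohort}.
#' @export
stageCohort <- function(original, cumulative, screened = rep(TRUE, 4),
                        marginal = NULL) {
    m <- diff(c(0, cumulative))
    if (!is.null(marginal)) {
        if (max(abs(marginal - m)) > 1e-9)
            stop("marginal sensitivities inconsistent with cumulative")
        m <- marginal
    }
    new("StageCohort", stages = c("I", "II", "III", "IV"),
        original = as.numeric(original), cumulative = as.numeric(cumulative),
        marginal = as.numeric(m), screened = as.logical(screened),
        detectable = numeric(4), intercepted = numeric(4),
        slipped = numeric(4), final = numeric(0), variant = "unrun")
}

#' Run the stage-interception recurrence
#'
#' Two variants of the stage-shift recurrence are provided.  The
#' \emph{literal} variant applies, stage by stage,
#' detectable_s = original_s * marginal_s + slipped_(s-1);
#' when screening occurs at stage s all detectable individuals are
#' intercepted there, otherwise they slip to the next stage.  The
#' \emph{conserving} variant tracks every individual:
#' arriving_s = original_s + slipped_(s-1), intercepted_s =
#' arriving_s * marginal_s (when screened), slipped_s = arriving_s -
#' intercepted_s, and the stage-IV residue is diagnosed at stage IV, so
#' total mass is conserved exactly.  The final stage-at-diagnosis
#' distribution is filled for the conserving variant.
#'
#' @param cohort a \linkS4class{StageCohort}.
#' @param variant "literal" (default, faithful to the printed recurrence)
#'   or "conserving".
#' @return the cohort with detectable / intercepted / slipped (and, for
#'   the conserving variant, \code{final}) filled in.
#' @export
runInterception <- function(cohort, variant = c("literal", "conserving")) {
    variant <- match.arg(variant)
    m <- cohort@marginal
    orig <- cohort@original
    scr <- cohort@screened
    det <- ic <- sl <- numeric(4)
    if (variant == "literal") {
        slip_prev <- 0
        for (s in 1:4) {
            det[s] <- orig[s] * m[s] + slip_prev
            if (scr[s]) { ic[s] <- det[s]; sl[s] <- 0 }
            else { ic[s] <- 0; sl[s] <- det[s] }
            slip_prev <- sl[s]
        }
        final <- numeric(0)
    } else {
        slip_prev <- 0
        for (s in 1:4) {
            arriving <- orig[s] + slip_prev
            ic[s] <- if (scr[s]) arriving * m[s] else 0
            det[s] <- arriving * m[s]
            sl[s] <- arriving - ic[s]
            slip_prev <- sl[s]
        }
        ## stage-IV residue is diagnosed (clinically) at stage IV
        final <- ic
        final[4] <- final[4] + sl[4]
        names(final) <- cohort@stages
    }
    cohort@detectable <- det
    cohort@intercepted <- ic
    cohort@slipped <- sl
    cohort@final <- final
    cohort@variant <- variant
    cohort
}

#' Cohort-weighted five-year survival
#'
#' Count-weighted mean of per-stage five-year survival over a final
#' stage-at-diagnosis distribution.
#'
#' @param final_counts named (I-IV) or plain numeric vector of 4
#'   non-negative stage counts.
#' @param survival numeric vector of 4 per-stage 5-year survival rates in
#'   [0, 1].
#' @return scalar weighted survival.
#' @export
survivalGain <- function(final_counts, survival) {
    stopifnot(length(final_counts) == 4, length(survival) == 4,
              all(survival >= 0 & survival <= 1))
    if (any(final_counts < 0)) stop("stage counts must be non-negative")
    tot <- sum(final_counts)
    if (tot <= 0) stop("empty stage distribution")
    sum(final_counts * survival) / tot
}
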