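# Reference-plate counter-screen: the reference plate is incubated like
# the screening plate but receives no enzymatic substrate, so its raw
# fluorescence isolates the compounds' own optical behaviour.  Before the
# 4-MU spike, excess fluorescence marks compounds that fluoresce like the
# reaction product; after spiking every well with 4-MU, a deficit marks
# quenchers and an excess marks non-specific additive interaction.
# Verdicts are significance-only (shared Sidak-adjusted alpha, direction
# enforced on top of the two-sided test); effect sizes are reported as
# ratios to the DMSO mean for triage, never thresholded.

artifact_test <- function(compound_rfu, dmso_rfu, params, direction) {
  if (length(compound_rfu) < 2L || length(dmso_rfu) < 2L) {
    stop("artifact tests need >= 2 replicate wells per group")
  }
  tt <- welch_t_test(compound_rfu, dmso_rfu,
                     var_equal = params$t_variant == "pooled")
  delta <- mean(compound_rfu) - mean(dmso_rfu)
  flag <- tt$p_value < params$alpha_adj &&
    ((direction > 0 && delta > 0) || (direction < 0 && delta < 0))
  list(flag = flag,
       effect_size = mean(compound_rfu) / mean(dmso_rfu),
       p_value = tt$p_value)
}

#' Detect a compound that fluoresces like 4-MU
#'
#' Pre-spike reference-plate test: flags the compound when its raw
#' fluorescence is significantly *above* the DMSO background at the
#' Sidak-adjusted level.
#'
#' @param compound_rfu pre-spike RFU replicates of the compound's wells.
#' @param dmso_rfu pre-spike RFU replicates of the DMSO wells.
#' @param params a [test_params()] object.
#' @return list with `flag` (logical), `effect_size` (compound/DMSO mean
#'   ratio) and `p_value`.
#' @export
detect_autofluorescence <- function(compound_rfu, dmso_rfu,
                                    params = test_params()) {
  artifact_test(compound_rfu, dmso_rfu, params, direction = +1)
}

#' Detect a fluorescence quencher
#'
#' Post-spike reference-plate test: after every well is spiked with
#' 4-MU, a compound whose fluorescence is significantly *below* the DMSO
#' wells' is quenching the fluorophore.
#'
#' @inheritParams detect_autofluorescence
#' @param compound_rfu post-spike RFU replicates of the compound's wells.
#' @param dmso_rfu post-spike RFU replicates of the DMSO wells.
#' @return list with `flag`, `effect_size`, `p_value`.
#' @export
detect_quenching <- function(compound_rfu, dmso_rfu,
                             params = test_params()) {
  artifact_test(compound_rfu, dmso_rfu, params, direction = -1)
}

#' Detect non-specific additive interaction with 4-MU
#'
#' Post-spike reference-plate test in the opposite direction: a
#' significant *excess* over the spiked DMSO wells indicates the
#' compound's signal adds to the 4-MU fluorescence.
#'
#' @inheritParams detect_quenching
#' @return list with `flag`, `effect_size`, `p_value`.
#' @export
detect_additive <- function(compound_rfu, dmso_rfu,
                            params = test_params()) {
  artifact_test(compound_rfu, dmso_rfu, params, direction = +1)
}

#' Combine artifact and growth flags into an interference verdict
#'
#' Any fluorescence-artifact flag (autofluorescent, quencher, additive)
#' makes the compound's screening-plate response uninterpretable and sets
#' the interference verdict; growth flags are carried alongside because
#' they gate classification differently (complete growth failure routes
#' to `indeterminate_growth`, suppression/promotion only annotates).
#'
#' @param autofluorescent,quencher,additive logical flags from the
#'   detectors.
#' @param growth character vector of growth flags (see [growth_flags()]).
#' @return list with `interference` (logical) and `flags` (character
#'   vector of all set flag names).
#' @export
merge_flags <- function(autofluorescent, quencher, additive,
                        growth = character(0)) {
  fluor <- c(autofluorescent = isTRUE(autofluorescent),
             quencher = isTRUE(quencher),
             additive_interaction = isTRUE(additive))
  list(interference = any(fluor),
       flags = c(names(fluor)[fluor], growth))
}
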