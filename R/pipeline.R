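#' Simulate a cohort and analyse it end to end
#'
#' Chains the listener simulator, the scorer and the statistical pipeline:
#' one simulated classroom session for a cohort of the default composition
#' (10 boys, 16 girls), scored into the nine measures and analysed with
#' the full nonparametric battery.
#'
#' @param seed integer master seed.
#' @param n_male,n_female cohort composition.
#' @param effects effect structure, see [default_effects()].
#' @param ... further arguments passed to [simulate_cohort()].
#' @return list with `cohort`, `scores` and `report`.
#' @export
run_simulated_study <- function(seed = 1L, n_male = 10, n_female = 16,
                                effects = default_effects(), ...) {
  cohort <- simulate_cohort(n_male = n_male, n_female = n_female,
                            effects = effects, seed = seed, ...)
  scores <- score_cohort(cohort)
  list(cohort = cohort, scores = scores,
       report = run_full_analysis(scores))
}

#' @keywords internal
"_PACKAGE"
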