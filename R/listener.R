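# Synthetic listener cohort: children whose per-syllable recognition in
# babble follows a dynamic-attending-style condition x syllable (x sex)
# effect structure, additive on the logit scale.

#' Default condition x syllable effect calibration
#'
#' Additive logit effects calibrated to the study population's score
#' medians: condition totals 24.5 (RH), 22 (NR), 22 (UnSc) out of 32, with
#' each condition's total split across syllable positions in proportion to
#' the syllable medians (RH 13:11, NR 12:10, UnSc 12:9), the rhythm
#' advantage therefore weighted toward the first syllable. The female
#' advantage on second-syllable rhythm scores (medians 11.5 vs 10 of 16)
#' enters as `sex_rh2_logit`; the male/female split of delta(RH, 2) is
#' solved so the sex-weighted (10:16) population mean stays on target.
#'
#' @param base_p baseline (non-rhythm) per-syllable recognition
#'   probability; the default is the NR total median 22/32.
#' @return list with `base_logit`, `delta` (2 x 3 matrix of logit offsets,
#'   rows = syllable, cols = RH/NR/UnSc) and `sex_rh2_logit`.
#' @export
default_effects <- function(base_p = 22 / 32) {
  base <- logit(base_p)
  totals <- c(RH = 24.5, NR = 22, UnSc = 22)
  split1 <- c(RH = 13 / 24, NR = 12 / 22, UnSc = 12 / 21)
  p <- rbind(totals * split1 / 16, totals * (1 - split1) / 16)
  delta <- logit(p) - base
  # sex split of the (RH, syllable 2) cell: female - male gap from the sex
  # medians (11.5 vs 10 of 16) on the logit scale; male offset solved so
  # the 10:16 weighted mean equals the population cell probability
  gap <- logit(11.5 / 16) - logit(10 / 16)
  target <- p[2, "RH"]
  f <- function(m) (10 * inv_logit(m) + 16 * inv_logit(m + gap)) / 26 - target
  m <- stats::uniroot(f, logit(target) + c(-2, 1))$root
  delta[2, "RH"] <- m - base
  dimnames(delta) <- list(syllable = c("1", "2"),
                          condition = c("RH", "NR", "UnSc"))
  list(base_logit = base, delta = delta, sex_rh2_logit = gap)
}

#' Listener profile
#'
#' @param sex `"male"` or `"female"`.
#' @param base_logit listener's baseline recognition on the logit scale.
#' @param effects effect structure, see [default_effects()].
#' @param lapse probability that an outcome is replaced by a fair coin
#'   flip (attention lapses, transcription slips).
#' @param seed integer seed for this listener's Bernoulli draws.
#' @param listener_id label.
#' @return a `wrrc_listener` object.
#' @export
listener_profile <- function(sex = c("female", "male"),
                             base_logit = logit(22 / 32),
                             effects = default_effects(), lapse = 0.02,
                             seed = 1L, listener_id = "L01") {
  sex <- match.arg(sex)
  if (lapse < 0 || lapse >= 0.5)
    stop("`lapse` must lie in [0, 0.5)", call. = FALSE)
  structure(list(sex = sex, base_logit = base_logit, effects = effects,
                 lapse = lapse, seed = seed, listener_id = listener_id),
            class = "wrrc_listener")
}

#' Per-cell recognition probability
#'
#' Inverse-logit of the listener's baseline plus the condition x syllable
#' effect (plus the female second-syllable rhythm term where applicable),
#' mixed with a fair guess at the lapse rate.
#'
#' @param profile a [listener_profile()].
#' @param condition `"RH"`, `"NR"` or `"UnSc"`.
#' @param syllable 1 or 2.
#' @return recognition probability in (0, 1).
#' @export
syllable_prob <- function(profile, condition, syllable) {
  stopifnot(inherits(profile, "wrrc_listener"),
            condition %in% c("RH", "NR", "UnSc"), syllable %in% c(1, 2))
  lp <- profile$base_logit +
    profile$effects$delta[as.character(syllable), condition]
  if (profile$sex == "female" && condition == "RH" && syllable == 2)
    lp <- lp + profile$effects$sex_rh2_logit
  (1 - profile$lapse) * inv_logit(lp) + profile$lapse * 0.5
}

#' Simulate one listener's response sheet
#'
#' Independent Bernoulli outcome per syllable per trial at the listener's
#' cell probability.
#'
#' @param profile a [listener_profile()].
#' @param manifest a 48-trial session design (see [design_manifest()]).
#' @param seed integer seed; defaults to the profile's.
#' @return a `wrrc_response_sheet` data.frame: `trial`, `word_id`,
#'   `condition`, `syll1_correct`, `syll2_correct`, plus `listener_id` and
#'   `sex` attributes carried as columns.
#' @export
simulate_listener <- function(profile, manifest = design_manifest(),
                              seed = profile$seed) {
  stopifnot(inherits(profile, "wrrc_listener"))
  if (nrow(manifest) != 48 ||
      !all(table(manifest$condition) == c(NR = 16, RH = 16, UnSc = 16)))
    stop("manifest must hold 48 trials, 16 per condition", call. = FALSE)
  rng <- local_rng(seed)
  conds <- c("RH", "NR", "UnSc")
  cell <- vapply(conds, function(cc)
    c(syllable_prob(profile, cc, 1), syllable_prob(profile, cc, 2)),
    numeric(2))
  ci <- match(manifest$condition, conds)
  p1 <- cell[1, ci]
  p2 <- cell[2, ci]
  sheet <- data.frame(
    listener_id = profile$listener_id, sex = profile$sex,
    trial = manifest$trial, word_id = manifest$word_id,
    condition = manifest$condition,
    syll1_correct = rng$runif(48) < p1,
    syll2_correct = rng$runif(48) < p2,
    stringsAsFactors = FALSE)
  class(sheet) <- c("wrrc_response_sheet", "data.frame")
  sheet
}

#' Simulate a cohort of listeners
#'
#' Independent listeners with between-subject variation of the baseline
#' logit; sex composition as requested (the study cohort was 10 boys and
#' 16 girls).
#'
#' @param n_male,n_female cohort composition.
#' @param effects effect structure, see [default_effects()].
#' @param seed integer master seed.
#' @param manifest session design shared by all listeners.
#' @param base_logit_mean population mean baseline logit.
#' @param base_logit_sd between-subject SD of the baseline logit; the
#'   default 0.25 brings total-score dispersion to about 3 points,
#'   matching the observed cohort.
#' @param lapse per-listener lapse rate.
#' @return list of `wrrc_response_sheet`s (class `wrrc_cohort`).
#' @export
simulate_cohort <- function(n_male = 10, n_female = 16,
                            effects = default_effects(), seed = 1L,
                            manifest = design_manifest(seed),
                            base_logit_mean = logit(22 / 32),
                            base_logit_sd = 0.25, lapse = 0.02) {
  if (n_male < 0 || n_female < 0) stop("negative cohort size", call. = FALSE)
  n <- n_male + n_female
  rng <- local_rng(seed)
  sexes <- c(rep("male", n_male), rep("female", n_female))
  bases <- rng$rnorm(n, base_logit_mean, base_logit_sd)
  seeds <- rng$sample_int(2^30, n)
  sheets <- vector("list", n)
  for (i in seq_len(n)) {
    prof <- listener_profile(sexes[i], base_logit = bases[i],
                             effects = effects, lapse = lapse,
                             seed = seeds[i],
                             listener_id = sprintf("L%02d", i))
    sheets[[i]] <- simulate_listener(prof, manifest)
  }
  structure(sheets, class = "wrrc_cohort")
}

#' @export
print.wrrc_cohort <- function(x, ...) {
  sex <- vapply(x, function(s) s$sex[1], character(1))
  cat(sprintf("<wrrc_cohort> %d listeners (%d male, %d female)\n",
              length(x), sum(sex == "male"), sum(sex == "female")))
  invisible(x)
}

#' Write cohort response sheets as one CSV
#'
#' @param cohort a `wrrc_cohort`.
#' @param path output CSV path (one row per trial per listener).
#' @return `path`, invisibly.
#' @export
export_sheets <- function(cohort, path) {
  utils::write.csv(do.call(rbind, lapply(cohort, as.data.frame)), path,
                   row.names = FALSE)
  invisible(path)
}
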