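# Syllable-level scoring into the nine output measures.

#' Score one word
#'
#' One point per correctly recognized syllable; a fully recognized word
#' scores 2, which coincides with the syllable sum.
#'
#' @param syll1_correct,syll2_correct logicals.
#' @return integer points 0, 1 or 2.
#' @export
score_word <- function(syll1_correct, syll2_correct) {
  as.integer(syll1_correct) + as.integer(syll2_correct)
}

#' Score one listener's 48-trial session
#'
#' Sums points per condition (primary measures RH, NR, UnSc, each out of
#' 32) and per condition x syllable position (secondary measures RH1, RH2,
#' NR1, NR2, UnSc1, UnSc2, each out of 16).
#'
#' @param sheet a `wrrc_response_sheet` (48 trials, 16 per condition).
#' @return one-row data.frame with the fixed 11-column schema
#'   `listener_id`, `sex`, `RH`, `NR`, `UnSc`, `RH1`, `RH2`, `NR1`, `NR2`,
#'   `UnSc1`, `UnSc2`.
#' @export
score_session <- function(sheet) {
  need <- c("condition", "syll1_correct", "syll2_correct")
  if (!all(need %in% names(sheet)))
    stop("sheet lacks required columns", call. = FALSE)
  if (nrow(sheet) != 48 || !all(table(sheet$condition) == 16))
    stop("sheet must hold 48 trials, 16 per condition", call. = FALSE)
  s1 <- tapply(as.integer(sheet$syll1_correct), sheet$condition, sum)
  s2 <- tapply(as.integer(sheet$syll2_correct), sheet$condition, sum)
  data.frame(
    listener_id = if ("listener_id" %in% names(sheet))
      sheet$listener_id[1] else NA_character_,
    sex = if ("sex" %in% names(sheet)) sheet$sex[1] else NA_character_,
    RH = s1[["RH"]] + s2[["RH"]], NR = s1[["NR"]] + s2[["NR"]],
    UnSc = s1[["UnSc"]] + s2[["UnSc"]],
    RH1 = s1[["RH"]], RH2 = s2[["RH"]], NR1 = s1[["NR"]], NR2 = s2[["NR"]],
    UnSc1 = s1[["UnSc"]], UnSc2 = s2[["UnSc"]],
    stringsAsFactors = FALSE)
}

#' Score a whole cohort
#'
#' @param cohort a `wrrc_cohort` (list of response sheets).
#' @return a `wrrc_scores` data.frame, one row per listener, schema as
#'   [score_session()].
#' @export
score_cohort <- function(cohort) {
  out <- do.call(rbind, lapply(cohort, score_session))
  rownames(out) <- NULL
  class(out) <- c("wrrc_scores", "data.frame")
  out
}

#' Normalize a free-text syllable transcript for matching
#'
#' Case folding and diacritic stripping only; orthographic fuzzy matching
#' is out of scope.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_transcript <- function(x) {
  x <- tolower(trimws(x))
  x <- stringi_like_nfd(x)
  x <- gsub("\\p{M}", "", x, perl = TRUE)      # combining marks
  gsub("['`^\"~]", "", x)                      # transliteration residue
}

# NFKD via iconv where available; falls back to identity.
stringi_like_nfd <- function(x) {
  y <- tryCatch(iconv(x, to = "ASCII//TRANSLIT"), error = function(e) x)
  ifelse(is.na(y), x, y)
}
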