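# Flexemic verb classes of the positional tagset that are eligible for LCM
# labels. The tagset distinguishes many verb flexemes (non-past, l-participle,
# infinitive, imperative, impersonal, future auxiliary, winien-type, and
# predicatives); the set is configurable because resources differ on which
# flexemes carry verb-dictionary entries.
DEFAULT_VERBAL_CLASSES <- c("fin", "praet", "inf", "impt", "imps",
                            "bedzie", "winien", "pred")

#' Is a tag a verbal grammatical class?
#'
#' The grammatical class is the first field of the colon-separated
#' positional tag; only tokens of verbal classes are eligible for LCM
#' labels.
#'
#' @param msd_tag Character vector of positional tags.
#' @param verbal_classes Set of class names counted as verbal.
#' @return Logical vector.
#' @export
verbal_class <- function(msd_tag,
                         verbal_classes = DEFAULT_VERBAL_CLASSES) {
  cls <- vapply(strsplit(msd_tag, ":", fixed = TRUE),
                function(f) if (length(f)) f[1L] else "", character(1))
  cls %in% verbal_classes
}

#' Select one morphosyntactic interpretation per surface form
#'
#' The upstream disambiguator scores each candidate interpretation with a
#' probability in \[0, 1\]; this selects the candidate of maximal
#' probability, breaking ties by the lexicographically smallest
#' (lemma, msd_tag) pair.
#'
#' @param candidates data.frame of candidate tokens for one surface form
#'   (columns `lemma`, `msd_tag`, `probability`, ...).
#' @return The selected row (a one-row data.frame).
#' @export
select_interpretation <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L)
    stop("select_interpretation: empty candidate set")
  p <- as.numeric(candidates$probability)
  best <- which(p == max(p))
  if (length(best) > 1L) {
    key <- paste(candidates$lemma[best], candidates$msd_tag[best], sep = "\r")
    best <- best[order(key)][1L]
  }
  candidates[best, , drop = FALSE]
}

#' Attach sentiment and LCM labels to a token stream
#'
#' For each token: sentiment is the lexicon polarity of its lemma (any part
#' of speech), else `"none"`; the LCM class is looked up only for tokens of
#' a verbal grammatical class, consulting the sense tier (when a sense id is
#' present and matches), then the lemma tier, then the default tier, with
#' `lcm_tier` recording the source. Punctuation gets `"none"` on both
#' channels. Unknown lemmas are silently unlabeled.
#'
#' @param tokens Token data.frame (see [read_token_table()]).
#' @param sentiment_lexicon A `sentiment_lexicon`.
#' @param lcm_lexicon An `lcm_lexicon`.
#' @param verbal_classes Verbal grammatical classes, see [verbal_class()].
#' @return The token data.frame with `sentiment`, `lcm`, `lcm_tier` columns.
#' @export
annotate <- function(tokens, sentiment_lexicon, lcm_lexicon,
                     verbal_classes = DEFAULT_VERBAL_CLASSES) {
  if (nrow(tokens) == 0L) {
    tokens$sentiment <- character(0)
    tokens$lcm <- character(0)
    tokens$lcm_tier <- character(0)
    return(tokens)
  }
  if (!"is_punct" %in% names(tokens))
    tokens$is_punct <- is_punct_tag(tokens$msd_tag)
  n <- nrow(tokens)
  sentiment <- sentiment_of(sentiment_lexicon, tokens$lemma)
  sentiment[tokens$is_punct] <- "none"
  lcm <- rep("none", n)
  lcm_tier <- rep("none", n)
  verbal <- !tokens$is_punct & verbal_class(tokens$msd_tag, verbal_classes)
  for (i in which(verbal)) {
    hit <- lcm_of(lcm_lexicon, tokens$lemma[i],
                  if (is.na(tokens$sense_id[i])) "" else tokens$sense_id[i])
    lcm[i] <- hit$class
    lcm_tier[i] <- hit$tier
  }
  tokens$sentiment <- sentiment
  tokens$lcm <- lcm
  tokens$lcm_tier <- lcm_tier
  tokens
}
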