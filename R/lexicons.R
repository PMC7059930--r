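LCM_CLASSES <- c("DAV", "IAV", "SV")
POLARITIES <- c("positive", "negative")

read_tsv_lex <- function(path, ncol_expect, what) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", encoding = "UTF-8",
                          quote = "", na.strings = NULL,
                          check.names = FALSE)
  if (ncol(df) < ncol_expect)
    stop("schema error in ", what, " file ", path, ": expected ",
         ncol_expect, " columns, found ", ncol(df))
  df
}

#' Load a sentiment lexicon
#'
#' Reads a two-column TSV (`lemma<TAB>polarity`) mapping lemmas to
#' `positive` or `negative`. Lookups are case-insensitive: lemmas are
#' lower-cased on load. A lemma listed with two conflicting polarities is an
#' error; exact duplicates are collapsed.
#'
#' @param path TSV path.
#' @return An object of class `sentiment_lexicon`: a named character vector
#'   `entries` plus polarity counts.
#' @export
load_sentiment_lexicon <- function(path) {
  df <- read_tsv_lex(path, 2L, "sentiment lexicon")
  names(df)[1:2] <- c("lemma", "polarity")
  df$lemma <- tolower(trimws(df$lemma))
  df$polarity <- trimws(df$polarity)
  if (any(!nzchar(df$lemma))) stop("empty lemma in sentiment lexicon")
  bad <- setdiff(unique(df$polarity), POLARITIES)
  if (length(bad))
    stop("unknown polarity label(s): ", paste(bad, collapse = ", "))
  df <- unique(df[c("lemma", "polarity")])
  dup <- df$lemma[duplicated(df$lemma)]
  if (length(dup))
    stop("conflicting polarity for lemma(s): ",
         paste(unique(dup), collapse = ", "))
  entries <- stats::setNames(df$polarity, df$lemma)
  structure(list(entries = entries,
                 n_positive = sum(entries == "positive"),
                 n_negative = sum(entries == "negative")),
            class = "sentiment_lexicon")
}

#' @export
print.sentiment_lexicon <- function(x, ...) {
  cat("<sentiment_lexicon>", length(x$entries), "lemmas (",
      x$n_positive, "positive,", x$n_negative, "negative )\n")
  invisible(x)
}

#' Look up sentiment polarity of lemmas
#' @param lexicon A `sentiment_lexicon`.
#' @param lemma Character vector of lemmas (case-insensitive).
#' @return Character vector: `"positive"`, `"negative"` or `"none"`.
#' @export
sentiment_of <- function(lexicon, lemma) {
  out <- unname(lexicon$entries[tolower(lemma)])
  out[is.na(out)] <- "none"
  out
}

lcm_tier_df <- function(path, with_sense, what) {
  if (is.null(path))
    return(data.frame(lemma = character(0), sense_id = character(0),
                      class = character(0), stringsAsFactors = FALSE))
  df <- read_tsv_lex(path, if (with_sense) 3L else 2L, what)
  if (with_sense) {
    names(df)[1:3] <- c("lemma", "sense_id", "class")
  } else {
    names(df)[1:2] <- c("lemma", "class")
    df$sense_id <- ""
  }
  df$lemma <- tolower(trimws(df$lemma))
  df$class <- trimws(df$class)
  bad <- setdiff(unique(df$class), LCM_CLASSES)
  if (length(bad))
    stop("LCM class outside {DAV, IAV, SV} in ", what, ": ",
         paste(bad, collapse = ", "))
  unique(df[c("lemma", "sense_id", "class")])
}

#' Load a three-tier LCM lexicon
#'
#' The verb-classification dictionary has three parts, consulted in order
#' during annotation: a sense-level tier (`lemma<TAB>sense_id<TAB>class`),
#' a lemma-level tier and an automatically inferred default tier (both
#' `lemma<TAB>class`). Classes are `DAV` (descriptive action verb), `IAV`
#' (interpretative action verb), `SV` (state verb). Tiers may be empty
#' (pass `NULL`).
#'
#' @param sense_path,lemma_path,default_path TSV paths or `NULL`.
#' @return An object of class `lcm_lexicon`.
#' @export
load_lcm_lexicon <- function(sense_path = NULL, lemma_path = NULL,
                             default_path = NULL) {
  sense <- lcm_tier_df(sense_path, TRUE, "LCM sense tier")
  lemma <- lcm_tier_df(lemma_path, FALSE, "LCM lemma tier")
  default <- lcm_tier_df(default_path, FALSE, "LCM default tier")
  structure(list(
    sense = stats::setNames(sense$class, paste(sense$lemma, sense$sense_id,
                                               sep = "\r")),
    lemma = stats::setNames(lemma$class, lemma$lemma),
    default = stats::setNames(default$class, default$lemma)),
    class = "lcm_lexicon")
}

#' @export
print.lcm_lexicon <- function(x, ...) {
  cat("<lcm_lexicon> sense:", length(x$sense),
      " lemma:", length(x$lemma), " default:", length(x$default), "\n")
  invisible(x)
}

#' Look up the LCM class of a lemma
#'
#' Resolution order: sense tier (if a sense id is supplied and matches),
#' then lemma tier, then default tier.
#'
#' @param lexicon An `lcm_lexicon`.
#' @param lemma Lemma (case-insensitive).
#' @param sense_id Optional sense identifier ("" for none).
#' @return list(class = "DAV"/"IAV"/"SV"/"none", tier = "sense"/"lemma"/
#'   "default"/"none").
#' @export
lcm_of <- function(lexicon, lemma, sense_id = "") {
  lemma <- tolower(lemma)
  if (nzchar(sense_id)) {
    hit <- lexicon$sense[paste(lemma, sense_id, sep = "\r")]
    if (!is.na(hit)) return(list(class = unname(hit), tier = "sense"))
  }
  hit <- lexicon$lemma[lemma]
  if (!is.na(hit)) return(list(class = unname(hit), tier = "lemma"))
  hit <- lexicon$default[lemma]
  if (!is.na(hit)) return(list(class = unname(hit), tier = "default"))
  list(class = "none", tier = "none")
}

#' Cross-validate the sentiment and LCM lexicons
#'
#' Report-only check: computes overlap statistics between the two resources
#' and warns about IAV lemmas that carry no sentiment polarity (IAVs have an
#' evaluative component in LCM theory, so most should appear in the
#' sentiment dictionary).
#'
#' @param sentiment A `sentiment_lexicon`.
#' @param lcm An `lcm_lexicon`.
#' @return list with `overlap` statistics and a character vector `warnings`.
#' @export
validate_lexicons <- function(sentiment, lcm) {
  sent_lemmas <- names(sentiment$entries)
  lcm_lemmas <- unique(c(sub("\r.*$", "", names(lcm$sense)),
                         names(lcm$lemma), names(lcm$default)))
  iav_lemmas <- unique(c(
    sub("\r.*$", "", names(lcm$sense))[lcm$sense == "IAV"],
    names(lcm$lemma)[lcm$lemma == "IAV"],
    names(lcm$default)[lcm$default == "IAV"]))
  uncovered_iav <- setdiff(iav_lemmas, sent_lemmas)
  warnings <- if (length(uncovered_iav))
    paste0("IAV lemma without sentiment polarity: ", uncovered_iav)
  else character(0)
  list(
    overlap = list(
      n_sentiment = length(sent_lemmas),
      n_lcm = length(lcm_lemmas),
      n_shared = length(intersect(sent_lemmas, lcm_lemmas)),
      n_iav = length(iav_lemmas),
      n_iav_covered = length(iav_lemmas) - length(uncovered_iav)),
    warnings = warnings)
}
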