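# Value vocabularies of the positional tagset's inflectional categories.
# A tag field is attributed to the (unique) category whose vocabulary
# contains it; dotted fields (unresolved ambiguity, e.g. "nom.voc") are not
# counted in the marginals.
MSD_CATEGORY_VALUES <- list(
  case   = c("nom", "gen", "dat", "acc", "inst", "loc", "voc"),
  number = c("sg", "pl"),
  gender = c("m1", "m2", "m3", "f", "n"),
  person = c("pri", "sec", "ter"),
  aspect = c("imperf", "perf"),
  degree = c("pos", "com", "sup")
)
DEFAULT_MSD_MARGINALS <- names(MSD_CATEGORY_VALUES)

#' Weighted abstraction score
#'
#' The level of linguistic abstraction of a language sample is the weighted
#' sum of its verb-category counts, `DAV + 2*IAV + 3*SV`: descriptive action
#' verbs weigh 1 (most concrete), interpretative action verbs 2, state
#' verbs 3 (most abstract).
#'
#' @param n_dav,n_iav,n_sv Non-negative counts (vectorized).
#' @return Numeric score(s).
#' @export
abstraction_score <- function(n_dav, n_iav, n_sv) {
  if (any(n_dav < 0) || any(n_iav < 0) || any(n_sv < 0))
    stop("abstraction_score: counts must be non-negative")
  n_dav + 2 * n_iav + 3 * n_sv
}

# Per-token weights; summing weight(lcm) over a sample must equal
# abstraction_score of the category counts.
lcm_weight <- function(lcm) {
  w <- c(DAV = 1, IAV = 2, SV = 3, none = 0)
  unname(w[lcm])
}

msd_frequencies <- function(tags, marginals = DEFAULT_MSD_MARGINALS) {
  fields <- strsplit(tags, ":", fixed = TRUE)
  cls <- vapply(fields, function(f) if (length(f)) f[1L] else "",
                character(1))
  out <- table(paste0("class_", cls))
  freq <- stats::setNames(as.integer(out), names(out))
  rest <- unlist(lapply(fields, function(f) f[-1L]), use.names = FALSE)
  rest <- rest[!grepl(".", rest, fixed = TRUE)]  # skip unresolved values
  for (cat in marginals) {
    vals <- rest[rest %in% MSD_CATEGORY_VALUES[[cat]]]
    if (length(vals)) {
      tb <- table(paste0(cat, "_", vals))
      freq <- c(freq, stats::setNames(as.integer(tb), names(tb)))
    }
  }
  freq
}

#' Extract the per-sample feature vector
#'
#' Aggregates an annotated token stream into the per-participant, per-task
#' feature vector: token and utterance counts, mean length of utterance,
#' sentiment counts, LCM category counts, the abstraction score, and
#' morphosyntactic tag frequencies (grammatical classes plus inflectional
#' category marginals). Punctuation is excluded from `n_tokens` and from the
#' tag frequencies.
#'
#' @param annotated Annotated token data.frame (see [annotate()]).
#' @param participant_id,group,task,duration_s Sample metadata.
#' @param msd_marginals Inflectional categories to count marginals for.
#' @return An object of class `feature_vector` (a list).
#' @export
extract_features <- function(annotated, participant_id, group, task,
                             duration_s = NA_real_,
                             msd_marginals = DEFAULT_MSD_MARGINALS) {
  if (nrow(annotated) == 0L)
    stop("extract_features: empty transcript")
  words <- annotated[!annotated$is_punct, , drop = FALSE]
  n_tokens <- nrow(words)
  n_utterances <- length(unique(annotated$utterance_index))
  mlu <- if (n_utterances > 0L) n_tokens / n_utterances else NA_real_
  n_dav <- sum(words$lcm == "DAV")
  n_iav <- sum(words$lcm == "IAV")
  n_sv <- sum(words$lcm == "SV")
  structure(list(
    participant_id = as.character(participant_id),
    group = match.arg(group, GROUPS),
    task = match.arg(task, TASKS),
    duration_s = as.numeric(duration_s),
    n_tokens = n_tokens,
    n_utterances = n_utterances,
    mlu = mlu,
    n_pos = sum(words$sentiment == "positive"),
    n_neg = sum(words$sentiment == "negative"),
    n_dav = n_dav, n_iav = n_iav, n_sv = n_sv,
    abstraction = abstraction_score(n_dav, n_iav, n_sv),
    msd_freq = msd_frequencies(words$msd_tag, msd_marginals)),
    class = "feature_vector")
}

#' Pooled utterance-level token counts
#'
#' Utterance lengths (non-punctuation tokens per utterance), the unit for a
#' pooled utterance-level length comparison. The per-participant MLU in
#' [extract_features()] is the primary statistic; this variant is provided
#' because the two aggregations can differ.
#'
#' @param annotated Annotated token data.frame.
#' @return Integer vector, one length per utterance.
#' @export
utterance_lengths <- function(annotated) {
  words <- annotated[!annotated$is_punct, , drop = FALSE]
  idx <- factor(annotated$utterance_index,
                levels = unique(annotated$utterance_index))
  as.integer(table(factor(words$utterance_index, levels = levels(idx))))
}

#' Build the corpus feature table
#'
#' One row per participant x task; the `msd_freq` map is flattened into
#' columns (absent tags are 0). Duplicate (participant, task) pairs are an
#' error; missing tasks are simply absent rows.
#'
#' @param feature_vectors List of `feature_vector` objects.
#' @return data.frame.
#' @export
corpus_feature_table <- function(feature_vectors) {
  stopifnot(length(feature_vectors) > 0L,
            all(vapply(feature_vectors, inherits, logical(1),
                       "feature_vector")))
  key <- vapply(feature_vectors,
                function(f) paste(f$participant_id, f$task), character(1))
  if (anyDuplicated(key))
    stop("duplicate (participant_id, task): ", key[duplicated(key)][1L])
  scalar_cols <- c("participant_id", "group", "task", "duration_s",
                   "n_tokens", "n_utterances", "mlu", "n_pos", "n_neg",
                   "n_dav", "n_iav", "n_sv", "abstraction")
  base <- do.call(rbind, lapply(feature_vectors, function(f)
    as.data.frame(f[scalar_cols], stringsAsFactors = FALSE)))
  msd_keys <- sort(unique(unlist(lapply(feature_vectors,
                                        function(f) names(f$msd_freq)))))
  if (length(msd_keys)) {
    msd <- t(vapply(feature_vectors, function(f) {
      v <- stats::setNames(integer(length(msd_keys)), msd_keys)
      v[names(f$msd_freq)] <- f$msd_freq
      v
    }, integer(length(msd_keys))))
    base <- cbind(base, as.data.frame(msd))
  }
  rownames(base) <- NULL
  base
}

#' Write / read the feature table CSV
#' @param table Feature table data.frame.
#' @param path CSV path.
#' @return `path` (write) or data.frame (read).
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
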