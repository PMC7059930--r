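# Synthetic corpus generator. The stated world: two matched groups of 25
# (ASD, TD), two elicitation tasks (book narrative, picture description),
# per-sample category counts (positive/negative sentiment words, DAV/IAV/SV
# verbs, neutral fillers) drawn from negative-binomial distributions
# moment-matched to the published Book-Task group summaries. IAV means are
# derived from the abstraction identity (abstraction = DAV + 2*IAV + 3*SV)
# applied to the published abstraction means; Picture-Task rates are scaled
# down to emulate the published task main effects. The abstraction score is
# always recomputed from the drawn counts, never drawn itself.

default_rates <- function() {
  list(
    ASD = list(
      book = list(pos = c(0.84, 0.75), neg = c(1.08, 1.38),
                  dav = c(13.24, 7.48), iav = c(8.00, 5.00),
                  sv = c(13.00, 7.35), filler = c(254, 90)),
      picture = list(pos = c(0.70, 0.80), neg = c(0.30, 0.55),
                     dav = c(5.30, 3.50), iav = c(3.20, 2.40),
                     sv = c(5.20, 3.60), filler = c(120, 55))),
    TD = list(
      book = list(pos = c(2.28, 2.41), neg = c(2.32, 2.78),
                  dav = c(18.48, 8.48), iav = c(10.28, 6.00),
                  sv = c(18.36, 10.04), filler = c(278, 95)),
      picture = list(pos = c(1.90, 1.70), neg = c(0.60, 0.90),
                     dav = c(7.40, 4.20), iav = c(4.10, 2.80),
                     sv = c(7.30, 4.40), filler = c(110, 50))))
}

default_durations <- function() {
  list(ASD = list(book = c(300, 120), picture = c(160.71, 89.96)),
       TD = list(book = c(300, 120), picture = c(99.11, 48.46)))
}

#' Generator configuration
#'
#' Bundles the parameters of the synthetic world: group sizes, per-category
#' negative-binomial (mean, sd) rates per group and task, utterance-length
#' parameters, task durations, and the per-task missing probability.
#' Defaults are moment-matched to the published Book-Task group summaries;
#' the picture task's default missingness (0.22) reproduces the 39 complete
#' cases implied by the published mixed-ANOVA degrees of freedom.
#'
#' @param n_per_group Participants per group.
#' @param rates Nested list `rates[[group]][[task]][[category]] = c(mean, sd)`
#'   for categories pos, neg, dav, iav, sv, filler.
#' @param mlu Per-group c(mean, sd) of utterance length in tokens.
#' @param durations Nested list of c(mean, sd) task durations in seconds.
#' @param missing Named per-task probability that a participant's sample for
#'   that task is absent.
#' @param seed Integer seed; the whole module is deterministic given it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_per_group = 25,
                             rates = default_rates(),
                             mlu = list(ASD = c(8.37, 6.94),
                                        TD = c(9.78, 7.50)),
                             durations = default_durations(),
                             missing = c(book = 0, picture = 0.22),
                             seed = 1L) {
  stopifnot(n_per_group >= 1)
  for (g in names(rates)) for (tk in names(rates[[g]]))
    for (cat in names(rates[[g]][[tk]])) {
      ms <- rates[[g]][[tk]][[cat]]
      if (ms[1] < 0) stop("rate means must be >= 0")
      if (ms[2] <= 0 && ms[1] > 0) stop("rate dispersions must be > 0")
    }
  if (any(missing < 0 | missing > 1))
    stop("missing probabilities must be in [0, 1]")
  structure(list(n_per_group = as.integer(n_per_group), rates = rates,
                 mlu = mlu, durations = durations, missing = missing,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Moment-matched count draws: negative binomial when overdispersed
# (var > mean), Poisson otherwise; sd -> 0 degenerates to a fixed count and
# mean 0 to all zeros.
rcount_ms <- function(n, mean, sd) {
  if (mean <= 0) return(integer(n))
  if (sd <= 1e-6) return(rep(as.integer(round(mean)), n))
  v <- sd^2
  if (v > mean) {
    size <- mean^2 / (v - mean)
    stats::rnbinom(n, size = size, mu = mean)
  } else {
    stats::rpois(n, mean)
  }
}

CATEGORIES <- c("pos", "neg", "dav", "iav", "sv", "filler")

draw_counts <- function(config) {
  rows <- list()
  for (g in names(config$rates)) {
    ids <- sprintf("%s%02d", g, seq_len(config$n_per_group))
    for (tk in TASKS) {
      present <- stats::runif(config$n_per_group) >= config$missing[[tk]]
      r <- config$rates[[g]][[tk]]
      cnt <- lapply(CATEGORIES, function(cat)
        rcount_ms(config$n_per_group, r[[cat]][1], r[[cat]][2]))
      names(cnt) <- CATEGORIES
      dur <- config$durations[[g]][[tk]]
      duration <- pmax(10, stats::rnorm(config$n_per_group, dur[1], dur[2]))
      df <- data.frame(participant_id = ids, group = g, task = tk,
                       duration_s = round(duration, 1),
                       as.data.frame(cnt), stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- df[present, , drop = FALSE]
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Utterance lengths: negative binomial shifted to >= 1, moment-matched to
# the group's mean length of utterance.
draw_utt_lengths <- function(n_tokens, mlu_ms) {
  if (n_tokens <= 0) return(integer(0))
  lens <- integer(0)
  while (sum(lens) < n_tokens) {
    more <- 1L + rcount_ms(max(8L, ceiling(n_tokens / max(1, mlu_ms[1]))),
                           max(0.01, mlu_ms[1] - 1), mlu_ms[2])
    lens <- c(lens, more)
  }
  cum <- cumsum(lens)
  k <- which(cum >= n_tokens)[1L]
  lens <- lens[seq_len(k)]
  lens[k] <- lens[k] - (cum[k] - n_tokens)
  lens[lens > 0L]
}

#' Generate a synthetic feature table
#'
#' Draws per-participant, per-task category counts from the configured
#' negative-binomial rates (minus simulated task missingness) and derives
#' the dependent quantities: total tokens, utterance counts and MLU, and the
#' abstraction score (always recomputed from the drawn DAV/IAV/SV counts).
#' Deterministic under the config seed.
#'
#' @param config A [generator_config()].
#' @return Feature table data.frame, one row per present participant x task.
#' @export
generate_feature_table <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  cnt <- draw_counts(config)
  n_tokens <- cnt$pos + cnt$neg + cnt$dav + cnt$iav + cnt$sv + cnt$filler
  n_utterances <- pmax(1L, vapply(seq_len(nrow(cnt)), function(i)
    length(draw_utt_lengths(n_tokens[i], config$mlu[[cnt$group[i]]])),
    integer(1)))
  data.frame(
    participant_id = cnt$participant_id, group = cnt$group, task = cnt$task,
    duration_s = cnt$duration_s,
    n_tokens = n_tokens, n_utterances = n_utterances,
    mlu = ifelse(n_utterances > 0, n_tokens / n_utterances, NA_real_),
    n_pos = cnt$pos, n_neg = cnt$neg,
    n_dav = cnt$dav, n_iav = cnt$iav, n_sv = cnt$sv,
    abstraction = abstraction_score(cnt$dav, cnt$iav, cnt$sv),
    stringsAsFactors = FALSE)
}

# Neutral filler vocabulary (not expected in either lexicon; checked).
FILLER_VOCAB <- data.frame(
  lemma = c("woda", "drzewo", "dom", "okno", "stolik", "lilia", "wieczorem",
            "potem", "tam", "bardzo", "i", "ale", "na", "przez"),
  msd_tag = c("subst:sg:nom:f", "subst:sg:nom:n", "subst:sg:nom:m3",
              "subst:sg:nom:n", "subst:sg:nom:m3", "subst:sg:nom:f",
              "adv", "adv", "adv", "adv:pos", "conj", "conj",
              "prep:loc", "prep:acc"),
  stringsAsFactors = FALSE)

category_vocab <- function(sentiment_lexicon, lcm_lexicon) {
  lcm_all <- unique(c(sub("\r.*$", "", names(lcm_lexicon$sense)),
                      names(lcm_lexicon$lemma),
                      names(lcm_lexicon$default)))
  sent <- names(sentiment_lexicon$entries)
  verbs_of <- function(cls) {
    v <- unique(c(names(lcm_lexicon$lemma)[lcm_lexicon$lemma == cls],
                  names(lcm_lexicon$default)[lcm_lexicon$default == cls]))
    setdiff(v, sent)  # keep sentiment and LCM channels disjoint
  }
  fillers <- FILLER_VOCAB[!(FILLER_VOCAB$lemma %in% c(sent, lcm_all)), ,
                          drop = FALSE]
  vocab <- list(
    pos = setdiff(sent[sentiment_lexicon$entries == "positive"], lcm_all),
    neg = setdiff(sent[sentiment_lexicon$entries == "negative"], lcm_all),
    dav = verbs_of("DAV"), iav = verbs_of("IAV"), sv = verbs_of("SV"),
    filler = fillers$lemma)
  attr(vocab, "filler_tags") <- fillers$msd_tag
  vocab
}

token_row <- function(lemma, msd_tag, utt = 0L) {
  data.frame(utterance_index = utt, surface = lemma, lemma = lemma,
             msd_tag = msd_tag, probability = 1, sense_id = "",
             stringsAsFactors = FALSE)
}

build_sample_tokens <- function(counts, vocab, mlu_ms) {
  filler_tags <- attr(vocab, "filler_tags")
  draws <- list()
  tag_of <- c(pos = "subst:sg:nom:f", neg = "subst:sg:nom:f",
              dav = "fin:sg:ter:imperf", iav = "fin:sg:ter:imperf",
              sv = "fin:sg:ter:imperf")
  for (cat in CATEGORIES) {
    k <- counts[[cat]]
    if (k == 0L) next
    if (length(vocab[[cat]]) == 0L)
      stop("category '", cat, "' requested but its vocabulary is empty")
    pick <- sample.int(length(vocab[[cat]]), k, replace = TRUE)
    lem <- vocab[[cat]][pick]
    tags <- if (cat == "filler") filler_tags[pick]
            else rep(tag_of[[cat]], k)
    draws[[cat]] <- token_row(lem, tags)
  }
  words <- do.call(rbind, draws)
  if (is.null(words)) {
    # zero-rate sample: one punctuation-only utterance keeps it well-formed
    out <- token_row(".", "interp", utt = 1L)
    return(out)
  }
  words <- words[sample.int(nrow(words)), , drop = FALSE]
  lens <- draw_utt_lengths(nrow(words), mlu_ms)
  utt_idx <- rep(seq_along(lens), lens)
  words$utterance_index <- utt_idx
  rows <- split(words, words$utterance_index)
  out <- do.call(rbind, lapply(seq_along(rows), function(i) {
    u <- rows[[i]]
    rbind(u, token_row(".", "interp", utt = i))
  }))
  rownames(out) <- NULL
  out
}

#' Generate a synthetic corpus
#'
#' Materializes the feature-table draws of [generate_feature_table()] as
#' CHAT transcripts and annotated token tables, sampling each category's
#' tokens from closed vocabularies built from the supplied toy lexicons
#' (positive/negative sentiment lemmas, DAV/IAV/SV verbs, neutral fillers).
#' By construction, running the annotation and feature-extraction pipeline
#' over the emitted token tables recovers the generating category counts
#' exactly.
#'
#' @param config A [generator_config()].
#' @param sentiment_lexicon,lcm_lexicon Toy lexicons providing the closed
#'   vocabularies.
#' @param out_dir Optional directory; when given, CHAT files, token-table
#'   TSVs and a metadata CSV are written there.
#' @return list with `corpus` (an `lcm_corpus`), `token_tables` (named list
#'   keyed `id_task`), `metadata`, and `truth` (the drawn counts, i.e. the
#'   same table [generate_feature_table()] returns under this seed).
#' @export
generate_corpus <- function(config, sentiment_lexicon, lcm_lexicon,
                            out_dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  vocab <- category_vocab(sentiment_lexicon, lcm_lexicon)
  truth <- generate_feature_table(config)
  set.seed(config$seed + 1L)  # token realization stream
  token_tables <- list()
  transcripts <- list()
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    counts <- list(pos = row$n_pos, neg = row$n_neg, dav = row$n_dav,
                   iav = row$n_iav, sv = row$n_sv,
                   filler = row$n_tokens - row$n_pos - row$n_neg -
                     row$n_dav - row$n_iav - row$n_sv)
    tt <- build_sample_tokens(counts, vocab, config$mlu[[row$group]])
    tt$is_punct <- is_punct_tag(tt$msd_tag)
    key <- paste(row$participant_id, row$task, sep = "_")
    token_tables[[key]] <- tt
    utts <- lapply(split(tt, tt$utterance_index), function(u)
      utterance("PAR", u$surface))
    transcripts[[key]] <- transcript(row$participant_id, row$group,
                                     row$task, unname(utts),
                                     row$duration_s,
                                     target_speaker = "PAR")
  }
  metadata <- truth[c("participant_id", "group", "task", "duration_s")]
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (key in names(token_tables)) {
      write_token_table(token_tables[[key]],
                        file.path(out_dir, paste0(key, ".tsv")))
      writeLines(chat_lines(transcripts[[key]]),
                 file.path(out_dir, paste0(key, ".cha")), useBytes = TRUE)
    }
    utils::write.csv(metadata, file.path(out_dir, "metadata.csv"),
                     row.names = FALSE)
  }
  list(corpus = corpus(unname(transcripts)), token_tables = token_tables,
       metadata = metadata, truth = truth)
}

chat_lines <- function(tr) {
  c("@Begin",
    "@Languages:\tpol",
    "@Participants:\tPAR Participant, EXA Investigator",
    sprintf("@ID:\tpol|synthetic|PAR|||%s||participant|||", tr$group),
    sprintf("*EXA:\tcan you tell me the story as we go along ?"),
    vapply(tr$utterances, function(u)
      paste0("*", u$speaker_code, ":\t", paste(u$tokens, collapse = " ")),
      character(1)),
    "@End")
}

#' Empirical power of the gated two-group test
#'
#' Simulates normal two-group data at each standardized effect size and
#' sample size, runs [compare_groups()], and reports the proportion of
#' two-sided rejections at `alpha` with its Monte-Carlo standard error.
#'
#' @param effect_sizes Standardized mean differences (Cohen's d).
#' @param n_values Per-group sample sizes.
#' @param reps Replicates per cell (>= 100).
#' @param alpha Test level.
#' @param seed Integer seed.
#' @return data.frame(effect, n, power, mc_se, reps).
#' @export
power_curve <- function(effect_sizes, n_values, reps = 500, alpha = 0.05,
                        seed = 1L) {
  stopifnot(reps >= 100)
  set.seed(seed)
  grid <- expand.grid(effect = effect_sizes, n = n_values)
  grid$power <- NA_real_
  for (i in seq_len(nrow(grid))) {
    d <- grid$effect[i]; n <- grid$n[i]
    hits <- vapply(seq_len(reps), function(r) {
      a <- stats::rnorm(n)
      b <- stats::rnorm(n, mean = d)
      compare_groups(a, b, alpha = alpha)$p < alpha
    }, logical(1))
    grid$power[i] <- mean(hits)
  }
  grid$mc_se <- sqrt(grid$power * (1 - grid$power) / reps)
  grid$reps <- reps
  grid
}
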