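GROUPS <- c("ASD", "TD")
TASKS <- c("book", "picture")

#' Construct an utterance
#'
#' One main tier of a transcript: a speaker code plus the cleaned token
#' sequence. Punctuation marks are retained as tokens and flagged downstream.
#'
#' @param speaker_code Short speaker code (e.g. "CHI", "EXA").
#' @param tokens Character vector of surface tokens; no empty strings.
#' @param raw_line Original tier text.
#' @return An object of class `lcm_utterance`.
#' @export
utterance <- function(speaker_code, tokens, raw_line = "") {
  stopifnot(is.character(speaker_code), length(speaker_code) == 1L,
            nzchar(speaker_code))
  tokens <- as.character(tokens)
  if (any(!nzchar(tokens))) stop("utterance tokens must be non-empty strings")
  structure(list(speaker_code = speaker_code, tokens = tokens,
                 raw_line = raw_line),
            class = "lcm_utterance")
}

#' Construct a transcript
#'
#' One participant x task language sample.
#'
#' @param participant_id Participant identifier.
#' @param group Group label, `"ASD"` or `"TD"`.
#' @param task Elicitation task, `"book"` or `"picture"`.
#' @param utterances List of [utterance()] objects; at least one must belong
#'   to the participant speaker.
#' @param duration_s Task duration in seconds (non-negative) or `NA`.
#' @param target_speaker Speaker code of the participant within `utterances`.
#' @return An object of class `lcm_transcript`.
#' @export
transcript <- function(participant_id, group, task, utterances,
                       duration_s = NA_real_, target_speaker = NULL) {
  group <- match.arg(group, GROUPS)
  task <- match.arg(task, TASKS)
  if (!is.na(duration_s) && duration_s < 0)
    stop("duration_s must be non-negative")
  if (length(utterances) == 0L)
    stop("transcript must contain at least one utterance")
  stopifnot(all(vapply(utterances, inherits, logical(1), "lcm_utterance")))
  if (is.null(target_speaker)) target_speaker <- utterances[[1L]]$speaker_code
  codes <- vapply(utterances, `[[`, character(1), "speaker_code")
  if (!any(codes == target_speaker))
    stop("no utterance from the participant speaker '", target_speaker, "'")
  structure(list(participant_id = as.character(participant_id),
                 group = group, task = task,
                 duration_s = as.numeric(duration_s),
                 target_speaker = target_speaker,
                 utterances = utterances),
            class = "lcm_transcript")
}

#' Construct a corpus
#'
#' A collection of transcripts with unique (participant, task) pairs; each
#' participant belongs to exactly one group.
#'
#' @param transcripts List of [transcript()] objects.
#' @return An object of class `lcm_corpus`.
#' @export
corpus <- function(transcripts) {
  stopifnot(all(vapply(transcripts, inherits, logical(1), "lcm_transcript")))
  ids <- vapply(transcripts, `[[`, character(1), "participant_id")
  tasks <- vapply(transcripts, `[[`, character(1), "task")
  grps <- vapply(transcripts, `[[`, character(1), "group")
  key <- paste(ids, tasks)
  if (anyDuplicated(key))
    stop("duplicate (participant_id, task): ", key[duplicated(key)][1L])
  if (any(tapply(grps, ids, function(g) length(unique(g))) > 1L))
    stop("a participant appears in more than one group")
  structure(list(transcripts = transcripts), class = "lcm_corpus")
}

#' @export
print.lcm_corpus <- function(x, ...) {
  cat("<lcm_corpus>", length(x$transcripts), "transcripts\n")
  invisible(x)
}

# ---- CHAT parsing ------------------------------------------------------

# Split a tier into whitespace tokens, then group <...> scopes and [...]
# codes into single units so retracing markers can see what they scope.
chat_units <- function(txt) {
  raw <- strsplit(trimws(txt), "[ \t]+")[[1]]
  raw <- raw[nzchar(raw)]
  units <- list()
  i <- 1L
  while (i <= length(raw)) {
    tk <- raw[i]
    if (startsWith(tk, "<") && !endsWith(tk, ">")) {
      j <- i
      while (j <= length(raw) && !endsWith(raw[j], ">")) j <- j + 1L
      j <- min(j, length(raw))
      units[[length(units) + 1L]] <- raw[i:j]
      i <- j + 1L
    } else if (startsWith(tk, "[") && !endsWith(tk, "]")) {
      j <- i
      while (j <= length(raw) && !endsWith(raw[j], "]")) j <- j + 1L
      j <- min(j, length(raw))
      units[[length(units) + 1L]] <- raw[i:j]
      i <- j + 1L
    } else {
      units[[length(units) + 1L]] <- tk
      i <- i + 1L
    }
  }
  units
}

is_retrace_marker <- function(u) {
  length(u) == 1L && u %in% c("[/]", "[//]", "[///]")
}
is_code_unit <- function(u) startsWith(u[1L], "[")

strip_angles <- function(x) gsub("^<|>$", "", x)

# CHAT cleaning: retracing/repetition markers drop the material they scope:
# the preceding <...> group when present, otherwise the longest run of
# preceding words repeated verbatim after the marker (one word when nothing
# repeats). Bracketed codes and events (&=...) are dropped; pause codes
# dropped; fillers (&-um) kept without the marker; word-internal
# shortenings "(be)cause" are expanded; terminators map to ".".
clean_chat_tokens <- function(txt) {
  units <- chat_units(txt)
  kept <- list()
  for (i in seq_along(units)) {
    u <- units[[i]]
    if (is_retrace_marker(u)) {
      if (length(kept) == 0L) next
      last <- kept[[length(kept)]]
      if (length(last) > 1L || startsWith(last[1L], "<")) {
        kept[[length(kept)]] <- NULL        # <...> group scope
      } else {
        # repetition scope: match trailing single-word units against the
        # words that follow the marker
        follow <- unlist(lapply(units[-seq_len(i)], function(v)
          if (!is_code_unit(v)) strip_angles(v)), use.names = FALSE)
        singles <- rev(which(!vapply(kept, function(v)
          length(v) > 1L || startsWith(v[1L], "<"), logical(1))))
        contiguous <- cumprod(singles == seq(length(kept), by = -1L,
                                             length.out = length(singles)))
        run <- singles[contiguous == 1]
        prev <- vapply(kept[sort(run)], identity, character(1))
        kmax <- 0L
        for (k in seq_len(min(length(prev), length(follow)))) {
          if (identical(utils::tail(prev, k), utils::head(follow, k)))
            kmax <- k
        }
        drop_n <- max(1L, kmax)
        kept <- kept[seq_len(length(kept) - drop_n)]
      }
    } else if (is_code_unit(u)) {
      # any other [...] code: drop silently
    } else {
      kept[[length(kept) + 1L]] <- u
    }
  }
  toks <- unlist(kept, use.names = FALSE)
  if (is.null(toks)) toks <- character(0)
  toks <- gsub("^<|>$", "", toks)
  toks <- toks[!grepl("^&=", toks)]           # events
  toks <- toks[!grepl("^\\(\\.+\\)$", toks)]  # timed pauses (.) (..)
  toks <- toks[!grepl("^#+$", toks)]          # pause marks
  toks <- sub("^&-?", "", toks)               # fillers kept, marker stripped
  is_term <- grepl("^\\+", toks)              # +... +//. etc -> sentence end
  toks[is_term] <- "."
  toks <- gsub("[()]", "", toks)              # (be)cause -> because
  toks <- gsub("@[a-z:]+$", "", toks)         # @o, @c special-form markers
  toks[!nzchar(toks)] <- NA_character_
  toks <- toks[!is.na(toks)]
  toks
}

#' Read a CHAT transcript
#'
#' Parses a CHAT (.cha) file, keeping only the main tiers of
#' `target_speaker`, and applies the package's cleaning conventions:
#' retracing/repetition markers (`[/]`, `[//]`) remove the material they
#' scope, events (`&=...`) and pause codes are dropped, fillers are kept,
#' punctuation is kept as tokens. Dependent tiers (`%...`) are ignored.
#'
#' @param path Path to a .cha file.
#' @param target_speaker Speaker code whose utterances form the transcript.
#' @param participant_id Participant id; defaults to the file name.
#' @param group,task,duration_s Metadata; `group` defaults to the @ID header
#'   group field for the target speaker when present.
#' @return An [transcript()] object.
#' @export
read_chat <- function(path, target_speaker, participant_id = NULL,
                      group = NULL, task = "book", duration_s = NA_real_) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines))))
    stop("parse error: empty CHAT file: ", path)

  # join continuation lines (leading tab) onto the previous tier
  joined <- character(0)
  lineno <- integer(0)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^[ \t]", ln) && length(joined)) {
      joined[length(joined)] <- paste(joined[length(joined)], trimws(ln))
    } else if (nzchar(trimws(ln))) {
      joined <- c(joined, ln)
      lineno <- c(lineno, i)
    }
  }

  header_group <- NA_character_
  utts <- list()
  seen_codes <- character(0)
  for (k in seq_along(joined)) {
    ln <- joined[k]
    first <- substr(ln, 1L, 1L)
    if (first == "@") {
      if (grepl("^@ID:", ln)) {
        fields <- strsplit(sub("^@ID:\\s*", "", ln), "|", fixed = TRUE)[[1]]
        if (length(fields) >= 6L && identical(fields[3L], target_speaker) &&
            nzchar(fields[6L]))
          header_group <- fields[6L]
      }
    } else if (first == "%") {
      # dependent tier: ignored
    } else if (first == "*") {
      m <- regmatches(ln, regexec("^\\*([A-Za-z0-9]+):\\s*(.*)$", ln))[[1]]
      if (length(m) != 3L)
        stop("parse error: malformed main tier at line ", lineno[k],
             ": ", ln)
      seen_codes <- union(seen_codes, m[2L])
      if (m[2L] == target_speaker) {
        toks <- clean_chat_tokens(m[3L])
        if (length(toks))
          utts[[length(utts) + 1L]] <- utterance(m[2L], toks, raw_line = ln)
      }
    } else {
      stop("parse error: unrecognized line ", lineno[k], ": ", ln)
    }
  }
  if (!(target_speaker %in% seen_codes))
    stop("unknown target_speaker '", target_speaker,
         "'; available speaker codes: ",
         paste(sort(seen_codes), collapse = ", "))
  if (length(utts) == 0L)
    stop("no non-empty utterances for speaker '", target_speaker, "'")
  if (is.null(participant_id))
    participant_id <- sub("\\.cha$", "", basename(path))
  if (is.null(group))
    group <- if (!is.na(header_group) && header_group %in% GROUPS)
      header_group else "TD"
  transcript(participant_id, group, task, utts, duration_s,
             target_speaker = target_speaker)
}

# ---- annotated token tables -------------------------------------------

TOKEN_COLS <- c("utterance_index", "surface", "lemma", "msd_tag",
                "probability", "sense_id")

#' Punctuation flag from a morphosyntactic tag
#'
#' Punctuation carries the grammatical class `interp` in the positional
#' tagset used here.
#' @param msd_tag Character vector of colon-separated positional tags.
#' @return Logical vector.
#' @export
is_punct_tag <- function(msd_tag) {
  vapply(strsplit(msd_tag, ":", fixed = TRUE),
         function(f) length(f) > 0L && f[1L] == "interp", logical(1))
}

validate_token_table <- function(df, where = "token table") {
  missing_cols <- setdiff(TOKEN_COLS, names(df))
  if (length(missing_cols))
    stop("schema error in ", where, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  df$probability <- as.numeric(df$probability)
  if (any(is.na(df$probability)) ||
      any(df$probability < 0 | df$probability > 1))
    stop("validation error in ", where,
         ": probability must be a number in [0, 1]")
  df$sense_id[is.na(df$sense_id)] <- ""
  for (col in c("surface", "lemma", "msd_tag", "sense_id"))
    df[[col]] <- as.character(df[[col]])
  df$utterance_index <- as.integer(df$utterance_index)
  punct <- is_punct_tag(df$msd_tag)
  if (any(!punct & !nzchar(df$msd_tag)))
    stop("validation error in ", where,
         ": msd_tag must be non-empty for non-punctuation tokens")
  df$is_punct <- punct
  df[TOKEN_COLS_OUT(df)]
}

TOKEN_COLS_OUT <- function(df) {
  extra <- setdiff(names(df), c(TOKEN_COLS, "is_punct"))
  c(TOKEN_COLS, "is_punct", extra)
}

#' Read an annotated token table
#'
#' TSV with columns `utterance_index, surface, lemma, msd_tag, probability,
#' sense_id` (UTF-8, header row), one token per row in order. This is the
#' output format of an upstream morphosyntactic analyser + disambiguator.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of tokens with a derived `is_punct` flag.
#' @export
read_token_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", encoding = "UTF-8",
                          quote = "", na.strings = NULL,
                          check.names = FALSE)
  validate_token_table(df, where = path)
}

#' Write an annotated token table
#'
#' Inverse of [read_token_table()]; round-trips exactly. Empty sense ids are
#' written as empty fields.
#'
#' @param tokens Token data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_token_table <- function(tokens, path) {
  if (nrow(tokens) > 0L) tokens <- validate_token_table(tokens)
  cols <- intersect(c(TOKEN_COLS, "sentiment", "lcm", "lcm_tier"),
                    names(tokens))
  if (nrow(tokens) == 0L) {
    writeLines(paste(TOKEN_COLS, collapse = "\t"), path, useBytes = TRUE)
    return(invisible(path))
  }
  out <- tokens[cols]
  out$sense_id[is.na(out$sense_id)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read participant metadata
#'
#' CSV with columns `participant_id, group, task, duration_s`.
#' @param path CSV path.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "group", "task")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schema error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  if (!"duration_s" %in% names(df)) df$duration_s <- NA_real_
  if (!all(df$group %in% GROUPS))
    stop("group must be one of: ", paste(GROUPS, collapse = ", "))
  if (!all(df$task %in% TASKS))
    stop("task must be one of: ", paste(TASKS, collapse = ", "))
  df
}
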