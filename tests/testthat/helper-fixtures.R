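# Shared fixtures and independent oracles. Oracles are deliberately naive
# (enumeration / per-token summation) and never call the code paths they
# check.

ext_fixture <- function(f) system.file("extdata", f, package = "lcmsent")

toy_sentiment <- function() load_sentiment_lexicon(ext_fixture("toy_sentiment.tsv"))
toy_lcm <- function() load_lcm_lexicon(ext_fixture("toy_lcm_sense.tsv"),
                                       ext_fixture("toy_lcm_lemma.tsv"),
                                       ext_fixture("toy_lcm_default.tsv"))

table2_tokens <- function() read_token_table(ext_fixture("table2_tokens.tsv"))

# The full candidate sets of the worked-example sentence, as the upstream
# analyser emits them (all interpretations, disambiguator probabilities).
table2_candidates <- function() {
  df <- function(...) data.frame(..., stringsAsFactors = FALSE)
  list(
    Ala = df(surface = "Ala",
             lemma = c("Ala", "Al", "Alo"),
             msd_tag = c("subst:sg:nom:f", "subst:sg:gen:acc:m1",
                         "subst:sg:gen:acc:m1"),
             probability = c(0.89, 0, 0), sense_id = ""),
    ma = df(surface = "ma",
            lemma = c("mój", "mieć"),
            msd_tag = c("adj:sg:nom.voc:f:pos", "fin:sg:ter:imperf"),
            probability = c(0, 1.0), sense_id = ""),
    radosny = df(surface = "radosny",
                 lemma = "radosny",
                 msd_tag = c("adj:sg:acc:m3:pos",
                             "adj:sg:nom.voc:m1.m2.m3:pos"),
                 probability = c(1.0, 0), sense_id = ""),
    nastroj = df(surface = "nastrój",
                 lemma = c("nastrój", "nastroić"),
                 msd_tag = c("subst:sg:nom.acc:m3", "impt:sg:sec:perf"),
                 probability = c(1.0, 0), sense_id = ""))
}

# Brute-force Mann-Whitney U: count pairwise wins (+ half ties) per group,
# report the smaller.
oracle_u <- function(a, b) {
  wins_a <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  wins_b <- sum(outer(b, a, ">")) + 0.5 * sum(outer(b, a, "=="))
  min(wins_a, wins_b)
}

# Per-token abstraction oracle: weight each annotated token 1/2/3 by class.
oracle_abstraction <- function(lcm_labels) {
  sum(vapply(lcm_labels, function(x)
    switch(x, DAV = 1, IAV = 2, SV = 3, 0), numeric(1)))
}

# Random annotated sample over the toy vocabulary categories.
random_annotated_sample <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lcm <- sample(c("DAV", "IAV", "SV", "none"), n, replace = TRUE,
                prob = c(.2, .2, .2, .4))
  data.frame(
    utterance_index = rep(seq_len(max(1L, n %/% 5L)), length.out = n),
    surface = paste0("w", seq_len(n)), lemma = paste0("w", seq_len(n)),
    msd_tag = ifelse(lcm == "none", "subst:sg:nom:f", "fin:sg:ter:imperf"),
    probability = 1, sense_id = "", is_punct = FALSE,
    sentiment = sample(c("positive", "negative", "none"), n, replace = TRUE),
    lcm = lcm,
    lcm_tier = ifelse(lcm == "none", "none", "lemma"),
    stringsAsFactors = FALSE)
}

write_tmp_lines <- function(lines) {
  path <- tempfile(fileext = ".cha")
  writeLines(lines, path, useBytes = TRUE)
  path
}
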