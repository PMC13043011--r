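## Linguistic features from the timed transcript: readability, fluency,
## lexicon-based affect, and lexical descriptors. 25 features total.

#' Load the bundled text lexicons
#'
#' Reads the package's plain-text lexicons: a valence lexicon (word,
#' valence in \[-1, 1\]), positive and negative emotion keyword lists, and
#' a stopword list. Any path can be overridden to substitute a custom
#' lexicon.
#'
#' @param sentimentPath,positivePath,negativePath,stopwordPath Optional
#'   replacement file paths.
#' @return List with elements `sentiment` (named numeric), `positive`,
#'   `negative`, `stopwords` (character vectors).
#' @export
loadLexicons <- function(sentimentPath = NULL, positivePath = NULL,
                         negativePath = NULL, stopwordPath = NULL) {
  pkgFile <- function(f) system.file("extdata", f,
                                     package = "CheckinBiomarkers",
                                     mustWork = TRUE)
  sp <- if (is.null(sentimentPath)) pkgFile("sentiment_lexicon.tsv") else
    sentimentPath
  sent <- utils::read.delim(sp, stringsAsFactors = FALSE)
  list(
    sentiment = stats::setNames(sent$valence, sent$word),
    positive = readLines(if (is.null(positivePath))
      pkgFile("emotion_positive.txt") else positivePath),
    negative = readLines(if (is.null(negativePath))
      pkgFile("emotion_negative.txt") else negativePath),
    stopwords = readLines(if (is.null(stopwordPath))
      pkgFile("stopwords.txt") else stopwordPath))
}

#' Tokenize a response text
#'
#' Lowercases, strips punctuation except intra-word apostrophes, and splits
#' on whitespace. Sentences are split on terminal punctuation (`.`, `!`,
#' `?`); text without terminal punctuation counts as one sentence.
#'
#' @param text A single character string.
#' @return List with `tokens` (character vector) and `sentences` (character
#'   vector of sentence strings).
#' @export
tokenizeText <- function(text) {
  text <- tolower(text)
  sentences <- trimws(strsplit(text, "[.!?]+")[[1]])
  sentences <- sentences[nzchar(sentences)]
  if (!length(sentences)) sentences <- character(0)
  clean <- gsub("[^a-z0-9' ]", " ", gsub("[.!?,;:]", " ", text))
  tokens <- strsplit(trimws(gsub("\\s+", " ", clean)), " ")[[1]]
  tokens <- gsub("^'+|'+$", "", tokens)
  tokens <- tokens[nzchar(tokens)]
  list(tokens = tokens, sentences = sentences)
}

#' Count syllables in a word
#'
#' Vowel-group heuristic: the number of maximal `[aeiouy]+` groups, with a
#' silent final "e" discounted (unless the word ends in "le"), and a
#' minimum of one syllable per word. Deterministic, so readability values
#' are bit-reproducible on fixture texts.
#'
#' @param word Character vector of words.
#' @return Integer vector of syllable counts (>= 1 per word).
#' @export
countSyllables <- function(word) {
  vapply(tolower(word), function(w) {
    w <- gsub("[^a-z]", "", w)
    if (!nchar(w)) return(1L)
    groups <- gregexpr("[aeiouy]+", w)[[1]]
    n <- if (groups[1] == -1L) 0L else length(groups)
    if (n > 1L && grepl("e$", w) && !grepl("le$", w)) n <- n - 1L
    max(1L, n)
  }, integer(1), USE.NAMES = FALSE)
}

#' Readability indices
#'
#' The three published readability formulas on a response text:
#' * ARI = 4.71 (chars/words) + 0.5 (words/sentences) - 21.43
#' * Flesch-Kincaid grade = 0.39 (words/sentences)
#'   + 11.8 (syllables/words) - 15.59
#' * Gunning Fog = 0.4 \[(words/sentences) + 100 (complex words / words)\],
#'   where a complex word has >= 3 syllables (no proper-noun or compound
#'   exclusions; transcribed speech lacks reliable casing).
#'
#' Characters are letters and digits only. Empty text yields `NA`s.
#'
#' @param text A single character string (one response, or a whole
#'   transcript side).
#' @return Named numeric vector (`ari_complexity`, `fk_complexity`,
#'   `gunning_fog_complexity`).
#' @export
readability <- function(text) {
  tk <- tokenizeText(text)
  out <- c(ari_complexity = NA_real_, fk_complexity = NA_real_,
           gunning_fog_complexity = NA_real_)
  nw <- length(tk$tokens)
  ns <- max(1L, length(tk$sentences))
  if (!nw) return(out)
  chars <- sum(nchar(gsub("[^a-z0-9]", "", tk$tokens)))
  syl <- countSyllables(tk$tokens)
  out["ari_complexity"] <- 4.71 * (chars / nw) + 0.5 * (nw / ns) - 21.43
  out["fk_complexity"] <- 0.39 * (nw / ns) + 11.8 * (sum(syl) / nw) - 15.59
  out["gunning_fog_complexity"] <- 0.4 * ((nw / ns) + 100 * mean(syl >= 3))
  out
}

#' Fluency and timing features from the transcript
#'
#' * `words_per_s`: total participant words over summed participant
#'   speaking time (turn spans).
#' * `hesitations_per_s` / `hesitation_prop`: filler tokens (configured
#'   lexicon, default um/uh/er/ah/hmm/mhm/uhm) per second of speaking time
#'   and as a proportion of words.
#' * `transcript_pause_rate` / `transcript_pause_mean_len`: inter-word gaps
#'   of at least `gap_min` (default 0.5 s) within a turn, from word-level
#'   timings;
#'   `NA` when word timings are absent.
#' * `response_latency_mean` / `response_latency_std`: participant turn
#'   start minus the immediately preceding agent turn end.
#'
#' @param transcript A [Transcript].
#' @param config Configuration list, see [defaultConfig()].
#' @return Named numeric vector of the seven fluency features.
#' @export
fluencyFeatures <- function(transcript, config = defaultConfig()) {
  tu <- turns(transcript)
  pt <- which(tu$speaker == "participant")
  if (!length(pt)) stop("transcript has no participant turns")
  speakTime <- sum(tu$end[pt] - tu$start[pt])
  tokensPerTurn <- lapply(tu$text[pt], function(x) tokenizeText(x)$tokens)
  nWords <- sum(lengths(tokensPerTurn))
  fillers <- tolower(config$text$fillers)
  nFill <- sum(unlist(tokensPerTurn) %in% fillers)

  lat <- rep(NA_real_, length(pt))
  for (k in seq_along(pt)) {
    i <- pt[k]
    if (i > 1L && tu$speaker[i - 1L] == "agent") {
      lat[k] <- tu$start[i] - tu$end[i - 1L]
    }
  }
  lat <- lat[!is.na(lat)]

  wo <- wordTimings(transcript)
  pauseRate <- pauseMean <- NA_real_
  if (nrow(wo)) {
    gaps <- numeric(0)
    for (i in pt) {
      w <- wo[wo$turn == i, , drop = FALSE]
      if (nrow(w) > 1L) {
        w <- w[order(w$start), , drop = FALSE]
        g <- w$start[-1] - w$end[-nrow(w)]
        gaps <- c(gaps, g[g >= config$text$gap_min])
      }
    }
    pauseRate <- if (speakTime > 0) length(gaps) / speakTime else NA_real_
    pauseMean <- if (length(gaps)) mean(gaps) else NA_real_
  }

  c(words_per_s = if (speakTime > 0) nWords / speakTime else NA_real_,
    hesitations_per_s = if (speakTime > 0) nFill / speakTime else NA_real_,
    hesitation_prop = if (nWords > 0) nFill / nWords else NA_real_,
    transcript_pause_rate = pauseRate,
    transcript_pause_mean_len = pauseMean,
    response_latency_mean = if (length(lat)) mean(lat) else NA_real_,
    response_latency_std = if (length(lat) > 1L) stats::sd(lat) else NA_real_)
}

#' Lexicon-based sentiment and emotion features
#'
#' Valence is scored per response as the mean lexicon valence over all
#' tokens (tokens outside the lexicon score 0), scaled to \[-1, 1\];
#' `sentiment_mean` and `sentiment_std` are the mean and SD of the
#' per-response scores. Emotion keyword proportions use the positive /
#' negative emotion lists; `emotion_keyword_prop` covers both partitions.
#'
#' @param texts Character vector of participant response texts.
#' @param lexicons Lexicon list from [loadLexicons()].
#' @return Named numeric vector (`sentiment_mean`, `sentiment_std`,
#'   `emotion_keyword_prop`, `positive_emotion_prop`,
#'   `negative_emotion_prop`).
#' @export
affectLexiconFeatures <- function(texts, lexicons = loadLexicons()) {
  perResp <- vapply(texts, function(x) {
    tok <- tokenizeText(x)$tokens
    if (!length(tok)) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    val <- lexicons$sentiment[tok]
    val[is.na(val)] <- 0
    nPos <- sum(tok %in% lexicons$positive)
    nNeg <- sum(tok %in% lexicons$negative)
    c(mean(val), (nPos + nNeg) / length(tok),
      nPos / length(tok), nNeg / length(tok))
  }, numeric(4))
  s <- perResp[1, ]
  c(sentiment_mean = mean(s, na.rm = TRUE),
    sentiment_std = if (sum(!is.na(s)) > 1L) stats::sd(s, na.rm = TRUE) else 0,
    emotion_keyword_prop = mean(perResp[2, ], na.rm = TRUE),
    positive_emotion_prop = mean(perResp[3, ], na.rm = TRUE),
    negative_emotion_prop = mean(perResp[4, ], na.rm = TRUE))
}

firstPersonSingular <- function() {
  c("i", "me", "my", "mine", "myself", "i'm", "i've", "i'll", "i'd")
}

negationWords <- function() {
  c("no", "not", "never", "none", "nothing", "nobody", "neither", "nor",
    "cannot", "without")
}

#' Lexical descriptors
#'
#' Counts and ratios over the participant responses: total and mean
#' response length in words, per-response type-token ratio (lowercased,
#' averaged across responses), mean word length in characters, mean
#' sentence length in words, first-person-singular / negation / content
#' word proportions (content = non-stopword), syllables per word, and
#' the proportion of long words (>= 3 syllables).
#'
#' @param texts Character vector of participant response texts.
#' @param lexicons Lexicon list from [loadLexicons()].
#' @return Named numeric vector of the ten lexical features.
#' @export
lexicalFeatures <- function(texts, lexicons = loadLexicons()) {
  tks <- lapply(texts, tokenizeText)
  perResp <- vapply(tks, function(tk) {
    tok <- tk$tokens
    if (!length(tok)) return(rep(NA_real_, 8L))
    syl <- countSyllables(tok)
    c(length(unique(tok)) / length(tok),
      mean(nchar(gsub("[^a-z0-9']", "", tok))),
      length(tok) / max(1L, length(tk$sentences)),
      mean(tok %in% firstPersonSingular()),
      mean(tok %in% negationWords() | grepl("n't$", tok)),
      mean(!(tok %in% lexicons$stopwords)),
      mean(syl),
      mean(syl >= 3))
  }, numeric(8))
  lens <- lengths(lapply(tks, `[[`, "tokens"))
  agg <- rowMeans(perResp, na.rm = TRUE)
  agg[is.nan(agg)] <- NA_real_
  c(transcript_len_words = sum(lens),
    mean_response_len_words = mean(lens),
    type_token_ratio = agg[1], mean_word_len = agg[2],
    mean_sentence_len = agg[3], first_person_singular_prop = agg[4],
    negation_prop = agg[5], content_word_prop = agg[6],
    syllables_per_word = agg[7], long_word_prop = agg[8])
}

#' Extract the 25 text features of a session
#'
#' Per-response features (readability, sentiment, lexical ratios) are
#' averaged across the participant's responses; timing features come from
#' the turn and word timings. Features undefined on degenerate input carry
#' `NA`, never a silent zero.
#'
#' @param transcript A [Transcript] with at least one participant turn.
#' @param config Configuration list, see [defaultConfig()].
#' @param lexicons Lexicon list from [loadLexicons()].
#' @return Named numeric vector with the 25 text feature names of
#'   [featureRegistry()].
#' @export
extractText <- function(transcript, config = defaultConfig(),
                        lexicons = loadLexicons()) {
  pt <- participantTurns(transcript)
  if (!nrow(pt)) stop("transcript has no participant turns")
  texts <- pt$text

  flu <- fluencyFeatures(transcript, config)
  readPerResp <- vapply(texts, readability, numeric(3))
  readAgg <- rowMeans(readPerResp, na.rm = TRUE)
  readAgg[is.nan(readAgg)] <- NA_real_
  aff <- affectLexiconFeatures(texts, lexicons)
  lex <- lexicalFeatures(texts, lexicons)

  out <- c(
    flu["words_per_s"],
    flu["response_latency_mean"], flu["response_latency_std"],
    lex["transcript_len_words"], lex["mean_response_len_words"],
    readAgg,
    aff,
    flu["hesitations_per_s"], flu["hesitation_prop"],
    flu["transcript_pause_rate"], flu["transcript_pause_mean_len"],
    lex[c("type_token_ratio", "mean_word_len", "mean_sentence_len",
          "first_person_singular_prop", "negation_prop",
          "content_word_prop", "syllables_per_word", "long_word_prop")])
  names(out) <- featureNames66("text")
  out
}
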