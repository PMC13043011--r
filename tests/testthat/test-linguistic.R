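test_that("syllable counting follows the documented heuristic", {
  expect_identical(countSyllables(c("cat", "one", "table", "banana",
                                    "responsibility", "time")),
                   c(1L, 1L, 2L, 3L, 6L, 1L))
})

test_that("readability indices match hand-evaluated published formulas", {
  ## 100 words of 4 letters, 5 sentences of 20 -> ARI = 4.71*4 + 0.5*20 - 21.43
  w4 <- rep("mast", 100)
  text <- paste(sapply(split(w4, rep(1:5, each = 20)), paste, collapse = " "),
                collapse = ". ")
  r <- readability(paste0(text, "."))
  expect_equal(unname(r["ari_complexity"]), 4.71 * 4 + 0.5 * 20 - 21.43,
               tolerance = 1e-9)

  ## 10 monosyllabic words, 1 sentence -> FK = 0.39*10 + 11.8*1 - 15.59
  r <- readability("the cat sat on the mat with one red dog.")
  expect_equal(unname(r["fk_complexity"]), 0.39 * 10 + 11.8 - 15.59,
               tolerance = 1e-9)

  ## 100 words, 5 sentences, 10 three-syllable words -> Fog = 0.4*(20+10) = 12
  toks <- c(rep("cat", 90), rep("banana", 10))
  set.seed(51)
  toks <- sample(toks)
  text <- paste(sapply(split(toks, rep(1:5, each = 20)), paste,
                       collapse = " "), collapse = ". ")
  r <- readability(paste0(text, "."))
  expect_equal(unname(r["gunning_fog_complexity"]), 12, tolerance = 1e-9)

  expect_true(all(is.na(readability(""))))
})

test_that("readability is invariant to token order within sentences", {
  set.seed(52)
  toks <- c(rep("window", 12), rep("impossible", 4), rep("sun", 8))
  t1 <- paste(paste(toks, collapse = " "), ".")
  t2 <- paste(paste(sample(toks), collapse = " "), ".")
  expect_equal(readability(t1), readability(t2))
})

test_that("fluency features count fillers, latency, and speech rate", {
  ## "um i uh think" over 4 s with filler lexicon {um, uh}
  tu <- data.frame(
    speaker = c("agent", "participant"), text = c("Go on.", "um i uh think"),
    start = c(0, 12), end = c(10, 16), stringsAsFactors = FALSE)
  f <- fluencyFeatures(Transcript(tu))
  expect_equal(unname(f["hesitations_per_s"]), 0.5)
  expect_equal(unname(f["hesitation_prop"]), 0.5)
  ## agent ends t=10, participant starts t=12 -> latency 2 s
  expect_equal(unname(f["response_latency_mean"]), 2)
  expect_equal(unname(f["words_per_s"]), 1)
  ## no word timings: pause features flagged missing, rate still computed
  expect_true(is.na(f["transcript_pause_rate"]))

  ## 40 words over 20 s of speaking time -> 2 words/s
  tu <- data.frame(
    speaker = c("agent", "participant"),
    text = c("Go on.", paste(rep("word", 40), collapse = " ")),
    start = c(0, 11), end = c(10, 31), stringsAsFactors = FALSE)
  f <- fluencyFeatures(Transcript(tu))
  expect_equal(unname(f["words_per_s"]), 2)
})

test_that("transcript pauses use the inter-word gap threshold", {
  tu <- data.frame(speaker = c("agent", "participant"),
                   text = c("Hi.", "one two three"),
                   start = c(0, 5), end = c(4, 12), stringsAsFactors = FALSE)
  wo <- data.frame(turn = 2L, token = c("one", "two", "three"),
                   start = c(5, 6.2, 10), end = c(5.5, 6.7, 10.5),
                   stringsAsFactors = FALSE)
  f <- fluencyFeatures(Transcript(tu, wo))
  ## gaps: 0.7 s and 3.3 s; both >= 0.5 s
  expect_equal(unname(f["transcript_pause_rate"]), 2 / 7)
  expect_equal(unname(f["transcript_pause_mean_len"]), 2)
})

test_that("affect lexicon features score valence and keyword proportions", {
  lex <- list(sentiment = c(up = 1, down = -1, happy = 0.8),
              positive = c("up", "happy"), negative = c("down"),
              stopwords = c("the", "a"))
  ## neutral function words only
  a <- affectLexiconFeatures("so then it was and", lex)
  expect_equal(unname(a["sentiment_mean"]), 0)
  expect_equal(unname(a["emotion_keyword_prop"]), 0)

  ## 2 positive among 10 tokens
  a <- affectLexiconFeatures("up happy the a the a the a the a", lex)
  expect_equal(unname(a["positive_emotion_prop"]), 0.2)
  expect_equal(unname(a["negative_emotion_prop"]), 0)

  ## balanced +1 / -1 keywords cancel (lexicon-average oracle)
  a <- affectLexiconFeatures("up down up down", lex)
  expect_equal(unname(a["sentiment_mean"]), 0)
})

test_that("lexical descriptors match direct counts", {
  lex <- loadLexicons()
  f <- lexicalFeatures("I think I can", lex)
  expect_equal(unname(f["type_token_ratio"]), 0.75)
  expect_equal(unname(f["first_person_singular_prop"]), 0.5)

  f <- lexicalFeatures(rep(paste(rep("sun", 10), collapse = " "), 4), lex)
  expect_equal(unname(f["transcript_len_words"]), 40)
  expect_equal(unname(f["mean_response_len_words"]), 10)
  expect_equal(unname(f["syllables_per_word"]), 1)
  expect_equal(unname(f["long_word_prop"]), 0)
})

test_that("extractText returns the 25-name registry with averaging", {
  tx <- simpleTranscript(rep("i felt tired today but i kept working.", 4))
  f <- extractText(tx)
  expect_identical(names(f), featureNames66("text"))
  expect_identical(length(f), 25L)
  ## identical responses: per-response values equal session values
  f1 <- extractText(simpleTranscript("i felt tired today but i kept working."))
  perResp <- setdiff(names(f), c("transcript_len_words",
                                 "response_latency_std", "sentiment_std"))
  expect_equal(f[perResp], f1[perResp], tolerance = 1e-9)
  expect_equal(unname(f["transcript_len_words"]),
               4 * unname(f1["transcript_len_words"]))
})

test_that("duplicating responses preserves proportions and readability", {
  resp <- c("i walked a long way home yesterday.",
            "work was genuinely difficult and exhausting.",
            "my sleep felt better this particular week.",
            "um i think everything is generally okay.")
  f4 <- extractText(simpleTranscript(resp))
  f8 <- extractText(simpleTranscript(rep(resp, 2)))
  stable <- c("type_token_ratio", "long_word_prop", "content_word_prop",
              "syllables_per_word", "ari_complexity", "fk_complexity",
              "gunning_fog_complexity", "hesitation_prop",
              "first_person_singular_prop", "negation_prop")
  expect_equal(f8[stable], f4[stable], tolerance = 1e-9)
  expect_equal(unname(f8["transcript_len_words"]),
               2 * unname(f4["transcript_len_words"]))
})

test_that("proportion features always lie in [0, 1]", {
  set.seed(53)
  props <- c("hesitation_prop", "type_token_ratio",
             "first_person_singular_prop", "negation_prop",
             "content_word_prop", "long_word_prop", "emotion_keyword_prop",
             "positive_emotion_prop", "negative_emotion_prop")
  for (i in 1:5) {
    p <- baseParams(filler_rate = runif(1, 0, 0.5),
                    long_word_prop = runif(1, 0.02, 0.5),
                    sentiment = runif(1, -1, 1),
                    sentence_len = runif(1, 4, 20))
    f <- extractText(synthTranscript(p)$transcript)
    expect_true(all(f[props] >= 0 & f[props] <= 1, na.rm = TRUE))
  }
})

test_that("generated filler rate survives the extraction round trip", {
  set.seed(54)
  rates <- replicate(8, {
    p <- baseParams(filler_rate = 0.3)
    unname(extractText(synthTranscript(p)$transcript)["hesitations_per_s"])
  })
  expect_equal(mean(rates), 0.3, tolerance = 0.25)
})
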