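lex <- load_lexicon(write_tiny_lexicon())

test_that("segmentation splits sentences and assigns exact spans", {
  s <- segment_text("No liver mets. Bone mets present.")
  expect_length(s, 2)
  expect_equal(s[[1]]$token, c("No", "liver", "mets"))
  expect_equal(s[[2]]$token, c("Bone", "mets", "present"))
  # spans index the raw text, 0-based half-open
  txt <- "No liver mets. Bone mets present."
  for (sent in s) {
    for (i in seq_len(nrow(sent))) {
      expect_equal(substring(txt, sent$start[i] + 1, sent$end[i]),
                   sent$token[i])
    }
  }
  expect_equal(segment_text(""), list())
  # every non-whitespace character belongs to exactly one token
  txt2 <- "a-b c; d!e"
  toks <- do.call(rbind, segment_text(txt2))
  covered <- unlist(mapply(function(a, b) (a + 1):b, toks$start, toks$end))
  nonspace <- which(strsplit(txt2, "")[[1]] != " ")
  expect_setequal(union(covered, which(strsplit(txt2, "")[[1]] %in%
                                         c(";", "!"))), nonspace)
})

test_that("Windows and Unix line endings yield identical segmentation", {
  unix <- "liver mets noted\n\nbone mets too"
  win <- "liver mets noted\r\n\r\nbone mets too"
  su <- segment_text(unix)
  sw <- segment_text(win)
  expect_equal(lapply(su, `[[`, "token"), lapply(sw, `[[`, "token"))
  expect_equal(lapply(su, `[[`, "start"), lapply(sw, `[[`, "start"))
  expect_length(su, 2)  # blank line is a sentence break
})

test_that("longest match wins and consumes tokens", {
  n <- make_note("diffuse skeletal mets noted")
  m <- tag_note(n, lex)
  expect_equal(nrow(m), 1L)
  expect_equal(m$class, "METSBONE")
  expect_equal(m$surface, "diffuse skeletal mets")

  # "mets" alone still matches its own class when not part of a longer term
  m2 <- tag_note(make_note("mets suspected"), lex)
  expect_equal(m2$class, "MBCLOW")

  m3 <- tag_note(make_note("recurrent metastatic tnbc follow up"), lex)
  expect_equal(m3$class, "DRECUR")

  expect_equal(nrow(tag_note(make_note("entirely benign visit"), lex)), 0L)
})

test_that("mentions never cross sentences nor overlap; matching is
           case-insensitive with raw surfaces preserved", {
  n <- make_note("Severe BONE pain. Mets to the LIVER MetS noted.")
  m <- tag_note(n, lex)
  # "bone . mets" crosses a sentence boundary: no METSBONE mention
  expect_false("METSBONE" %in% m$class)
  # raw text is preserved in the surface
  expect_true(all(m$surface == substring(
    "Severe BONE pain. Mets to the LIVER MetS noted.", m$start + 1, m$end)))
  if (nrow(m) > 1) {
    m <- m[order(m$start), ]
    expect_true(all(m$start[-1] >= m$end[-nrow(m)]))
  }
})

test_that("context triggers set polarity, experiencer, temporality", {
  txt <- "No evidence of liver mets. Her mother had bone mets. If lung mets appear we will rescan."
  n <- make_note(txt)
  m <- resolve_context(tag_note(n, lex), segment_text(txt), lex)
  m <- m[order(m$start), ]
  expect_equal(m$class, c("METSLIVER", "METSBONE", "METSLUNG"))
  expect_equal(m$polarity, c("negated", "positive", "positive"))
  expect_equal(m$experiencer, c("patient", "family", "patient"))
  expect_equal(m$temporality, c("present", "present", "hypothetical"))
})

test_that("scope terminators cut the context window", {
  txt <- "No evidence of progression but new bone mets"
  m <- resolve_context(tag_note(make_note(txt), lex), segment_text(txt), lex)
  expect_equal(m$class, "METSBONE")
  expect_equal(m$polarity, "positive")
})

test_that("pseudo-negation blocks the contained negation trigger", {
  txt <- "no increase in bone mets"
  m <- resolve_context(tag_note(make_note(txt), lex), segment_text(txt), lex)
  expect_equal(m$polarity, "positive")
  # but a real negation right before still fires
  txt2 <- "no bone mets"
  m2 <- resolve_context(tag_note(make_note(txt2), lex),
                        segment_text(txt2), lex)
  expect_equal(m2$polarity, "negated")
})

test_that("attributes are independent: negated + family can co-occur", {
  txt <- "mother had no bone mets"
  m <- resolve_context(tag_note(make_note(txt), lex), segment_text(txt), lex)
  expect_equal(m$polarity, "negated")
  expect_equal(m$experiencer, "family")
})

test_that("context window is sentence-bounded and length-limited", {
  # negation 7 tokens away (window 6) does not reach the mention
  txt <- "no w1 w2 w3 w4 w5 w6 bone mets"
  m <- resolve_context(tag_note(make_note(txt), lex), segment_text(txt), lex,
                       window = 6)
  expect_equal(m$polarity, "positive")
  # ... but reaches with a wider window
  m2 <- resolve_context(tag_note(make_note(txt), lex), segment_text(txt),
                        lex, window = 8)
  expect_equal(m2$polarity, "negated")
  # trigger in the previous sentence never applies
  txt3 <- "No evidence of progression. Bone mets present."
  m3 <- resolve_context(tag_note(make_note(txt3), lex), segment_text(txt3),
                        lex)
  expect_equal(m3$polarity, "positive")
})

test_that("tag_corpus is deterministic, skips malformed notes, and
           aggregates", {
  notes <- rbind(make_note("bone mets", "P1", "N1"),
                 make_note("liver mets", "P2", "N2"),
                 make_note("text", NA, "N3"))
  notes$patient_id[3] <- NA
  expect_warning(m <- tag_corpus(notes, lex), "malformed")
  expect_equal(nrow(m), 2L)
  expect_equal(attr(m, "skipped"), 1L)
  suppressWarnings({
    m2 <- tag_corpus(notes, lex)
  })
  attr(m, "skipped") <- attr(m2, "skipped") <- NULL
  expect_identical(m, m2)
  expect_equal(nrow(tag_corpus(notes[0, ], lex)), 0L)
})

test_that("notes JSONL round-trips", {
  notes <- rbind(make_note("bone mets noted", "P1", "N1"),
                 make_note("all clear", "P2", "N2"))
  p <- tempfile(fileext = ".jsonl")
  write_notes_jsonl(notes, p)
  back <- read_notes_jsonl(p)
  expect_equal(back[names(notes)], notes)
})
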