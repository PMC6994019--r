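mk_mention <- function(patient_id = "P1", class = "METSLIVER",
                       polarity = "positive", experiencer = "patient",
                       temporality = "present") {
  data.frame(patient_id = patient_id, note_id = "N1", note_type = "med_onc",
             start = 0L, end = 5L, surface = "x", class = class,
             polarity = polarity, experiencer = experiencer,
             temporality = temporality, stringsAsFactors = FALSE)
}

no_mentions <- mk_mention()[0, ]

test_that("the distant-label rule follows stage, notes and mention status", {
  rec <- list(patient_id = "P1", stage_at_dx = "II")

  expect_equal(assign_label(rec, mk_mention(), TRUE)$label,
               "distant_positive")
  expect_equal(assign_label(rec, mk_mention(polarity = "negated"),
                            TRUE)$label, "distant_negative")
  expect_equal(assign_label(rec, mk_mention(experiencer = "family"),
                            TRUE)$label, "distant_negative")
  expect_equal(assign_label(rec, mk_mention(temporality = "hypothetical"),
                            TRUE)$label, "distant_negative")
  # non-site classes never qualify, even positive-present
  expect_equal(assign_label(rec, mk_mention(class = "DRECUR"), TRUE)$label,
               "distant_negative")
  expect_equal(assign_label(rec, no_mentions, TRUE)$label,
               "distant_negative")
  # stage IV wins regardless of notes
  expect_equal(assign_label(list(patient_id = "P1", stage_at_dx = "IV"),
                            no_mentions, FALSE)$label, "de_novo_mbc")
  # early stage without notes is non-MBC by exclusion
  expect_equal(assign_label(rec, no_mentions, FALSE)$label,
               "non_mbc_no_notes")
  # missing stage flows through the distant branch
  expect_equal(assign_label(list(patient_id = "P1", stage_at_dx = "missing"),
                            mk_mention(), TRUE)$label, "distant_positive")
  # evidence lists exactly the qualifying mentions
  both <- rbind(mk_mention(), mk_mention(polarity = "negated"))
  ev <- assign_label(rec, both, TRUE)$evidence
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$polarity, "positive")
  expect_error(assign_label(rec, mk_mention(patient_id = "P9"), TRUE),
               "patient")
})

test_that("adding a qualifying mention is monotone toward distant_positive", {
  rec <- list(patient_id = "P1", stage_at_dx = "I")
  m <- mk_mention(class = "RECUR")
  expect_equal(assign_label(rec, m, TRUE)$label, "distant_negative")
  expect_equal(assign_label(rec, rbind(m, mk_mention(class = "METSBONE")),
                            TRUE)$label, "distant_positive")
})

test_that("label_cohort partitions patients and applies overrides", {
  registry <- data.frame(patient_id = c("A", "B", "C", "D"),
                         stage_at_dx = c("IV", "II", "II", "III"),
                         stringsAsFactors = FALSE)
  notes <- make_note("bone mets present", "B", "N1")
  notes <- rbind(notes, make_note("no events", "C", "N2"))
  mentions <- mk_mention("B", class = "METSBONE")
  labs <- label_cohort(registry, mentions, notes)
  expect_setequal(labs$patient_id, registry$patient_id)
  expect_equal(labs$label[labs$patient_id == "A"], "de_novo_mbc")
  expect_equal(labs$label[labs$patient_id == "B"], "distant_positive")
  expect_equal(labs$label[labs$patient_id == "C"], "distant_negative")
  expect_equal(labs$label[labs$patient_id == "D"], "non_mbc_no_notes")
  expect_equal(labs$n_evidence_mentions[labs$patient_id == "B"], 1L)

  adj <- data.frame(patient_id = "C", label = "distant_positive",
                    stringsAsFactors = FALSE)
  labs2 <- label_cohort(registry, mentions, notes, adjudicated = adj)
  expect_equal(labs2$label[labs2$patient_id == "C"], "distant_positive")
  expect_error(label_cohort(registry, mentions, notes,
                            adjudicated = data.frame(patient_id = "Z",
                                                     label = "de_novo_mbc")),
               "unknown")
  expect_error(label_cohort(registry[c(1, 1), ], mentions, notes),
               "duplicate")
})

test_that("cohort summary arithmetic matches its definitions", {
  mk <- function(n, label) {
    data.frame(patient_id = paste0(label, seq_len(n)), label = label,
               stringsAsFactors = FALSE)
  }
  labs <- rbind(mk(512, "de_novo_mbc"), mk(1374, "distant_positive"),
                mk(7590, "distant_negative"), mk(1983, "non_mbc_no_notes"))
  s <- summarize_cohort(labs)
  expect_equal(s$n_mbc, 1886)
  expect_equal(s$n_total, 11459)
  expect_equal(s$pct_de_novo_of_mbc, 27.1)
  expect_equal(s$pct_recurrent_of_mbc, 72.9)
  expect_equal(s$n_non_mbc, 9573)

  single <- mk(1, "de_novo_mbc")
  expect_equal(summarize_cohort(single)$pct_de_novo_of_mbc, 100.0)
  expect_error(summarize_cohort(rbind(single, single)), "duplicate")
})

test_that("ICD-9 rule matches 196-199 prefixes only", {
  expect_true(classify_icd9("197.7"))
  expect_true(classify_icd9("196"))       # bare code, XX wildcard
  expect_true(classify_icd9(c("195.9", "199.1")))
  expect_false(classify_icd9(c("195.9", "V10.3")))
  expect_false(classify_icd9("1967.1"))   # string prefix, not numeric range
  expect_false(classify_icd9(character(0)))
  # monotone: adding codes never flips TRUE -> FALSE
  set.seed(1)
  for (i in 1:20) {
    base <- sample(c("196.9", "250.00", "V10.3", "199.0"), 3, replace = TRUE)
    extra <- sample(c("401.9", "197.0"), 1)
    if (classify_icd9(base)) expect_true(classify_icd9(c(base, extra)))
  }
})

test_that("cohort-level ICD-9 classification covers codeless patients", {
  d <- data.frame(patient_id = c("A", "A", "B"),
                  code = c("250.00", "197.7", "V10.3"),
                  stringsAsFactors = FALSE)
  res <- classify_icd9_cohort(d, patient_ids = c("A", "B", "C"))
  expect_equal(res$icd9_mbc, c(TRUE, FALSE, FALSE))
})
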