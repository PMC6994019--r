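# Seeded synthetic cohorts: registry records, templated clinical notes with
# planted mentions, ICD-9 diagnosis codes, and a ground-truth manifest.
#
# Notes are assembled from sentence templates that embed lexicon surfaces
# and context triggers, so every planted mention's character span, class and
# attributes are known exactly — the tagger is oracle-testable against the
# manifest. Mention counts are negative-binomial to give the over-dispersion
# real notes have.

POS_TEMPLATES <- c("Imaging shows %s.", "Findings compatible with %s.",
                   "Consistent with %s.", "She has %s.",
                   "Recent scan demonstrates %s.")
NEG_TEMPLATES <- c("No evidence of %s.", "Negative for %s.",
                   "She denies %s.", "No sign of %s.")
FAM_TEMPLATES <- c("Her mother had %s.", "Family history of %s.",
                   "Her sister was treated for %s.")
HYP_TEMPLATES <- c("Concern for %s.", "Rule out %s.",
                   "Discussed risk of %s.")
FILLER_SENTENCES <- c("Patient seen in clinic today.", "Vitals stable.",
                      "Tolerating treatment well.",
                      "Will follow up in 3 months.", "Labs reviewed.",
                      "Chemotherapy cycle completed.")

MET_ICD9 <- c("196.9", "197.0", "197.7", "198.3", "198.5", "199.0", "199.1")
BENIGN_ICD9 <- c("174.9", "V10.3", "250.00", "401.9", "611.72", "E849.0")

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions the generator emulates: a
#' registry-like stage distribution with about 4.3% de novo stage IV, a
#' recurrence risk of 14% among early-stage patients, over-dispersed note
#' and mention counts, text-noise rates at the distant-label operating point
#' (false-negative 0.111, false-positive 0.203), and an ICD-9 code rule with
#' sensitivity 0.93 and specificity 0.47.
#'
#' @param n_patients Cohort size.
#' @param p_stage Named probabilities over stages 0, I, II, III, IV, missing.
#' @param p_recurrence_given_early_stage Recurrence probability for non-stage
#'   IV patients.
#' @param notes_mu_case,notes_mu_control,notes_size Negative-binomial note
#'   counts; cases get `1 + NB(mu, size)` (a recurrent patient always has at
#'   least one note), controls `NB(mu, size)` and may have none.
#' @param note_type_probs Named mixing proportions over note types.
#' @param site_pos_mu Extra positive site-class mentions per case beyond the
#'   guaranteed one.
#' @param nonsite_pos_mu_case,nonsite_pos_mu_control Named per-class means of
#'   positive non-site mentions (the classifier's signal-carrying features).
#' @param distractor_negated_mu,distractor_family_mu,distractor_hypothetical_mu
#'   Mean counts of negated / family / hypothetical distractor mentions per
#'   patient (any class, both cases and controls).
#' @param p_false_negative_text Probability a recurrent patient's notes carry
#'   no positive present site mention.
#' @param p_false_positive_text Probability a non-MBC patient with notes gets
#'   one spurious positive present site mention.
#' @param p_code_given_case,p_code_given_control Probability of at least one
#'   metastatic ICD-9 code (196-199) for true MBC / non-MBC patients.
#' @param seed Integer seed; same config + seed gives byte-identical output.
#' @return An object of class `mbc_sim_config`.
#' @export
sim_config <- function(
    n_patients = 1000L,
    p_stage = c("0" = 0.204, "I" = 0.333, "II" = 0.300, "III" = 0.098,
                "IV" = 0.043, "missing" = 0.022),
    p_recurrence_given_early_stage = 0.14,
    notes_mu_case = 7, notes_mu_control = 4, notes_size = 1.2,
    note_type_probs = c(med_onc = 0.35, rad_onc = 0.10, pathology = 0.15,
                        radiology = 0.20, primary_care = 0.20),
    site_pos_mu = 1.5,
    nonsite_pos_mu_case = c(DRECUR = 1.5, MBC = 1.2, MBCLOW = 1.0,
                            METSNOS = 0.8, RECUR = 1.0, LRECUR = 0.3,
                            DIED = 0.1),
    nonsite_pos_mu_control = c(DRECUR = 0.05, MBC = 0.05, MBCLOW = 0.2,
                               METSNOS = 0.05, RECUR = 0.3, LRECUR = 0.2,
                               DIED = 0.05),
    distractor_negated_mu = 0.7,
    distractor_family_mu = 0.12,
    distractor_hypothetical_mu = 0.15,
    p_false_negative_text = 0.111,
    p_false_positive_text = 0.203,
    p_code_given_case = 0.93,
    p_code_given_control = 0.53,
    seed = 1L) {
  p_stage <- p_stage / sum(p_stage)
  stopifnot(all(c(p_stage, p_recurrence_given_early_stage,
                  p_false_negative_text, p_false_positive_text,
                  p_code_given_case, p_code_given_control) >= 0),
            all(c(p_recurrence_given_early_stage, p_false_negative_text,
                  p_false_positive_text, p_code_given_case,
                  p_code_given_control) <= 1),
            abs(sum(note_type_probs) - 1) < 1e-8)
  if (p_recurrence_given_early_stage > 0 && notes_mu_case <= 0) {
    stop("inconsistent config: recurrent patients require notes_mu_case > 0")
  }
  structure(mget(names(formals(sim_config))), class = "mbc_sim_config")
}

rnb <- function(n, mu, size = 1) {
  if (mu <= 0) return(integer(n))
  stats::rnbinom(n, mu = mu, size = size)
}

random_date <- function(n) {
  d <- as.Date("2000-01-01") + sample.int(5478L, n, replace = TRUE) - 1L
  format(d, "%Y-%m-%d")
}

sample_level <- function(n, levels, p_missing = 0.04) {
  real <- setdiff(levels, "missing")
  p <- c(rep((1 - p_missing) / length(real), length(real)), p_missing)
  sample(c(real, "missing"), n, replace = TRUE, prob = p)
}

# One planted-mention sentence. Returns the sentence text and the term's
# char offsets relative to the sentence start (0-based half-open).
render_sentence <- function(surface, kind) {
  tpl <- switch(kind,
    positive = sample(POS_TEMPLATES, 1L),
    negated = sample(NEG_TEMPLATES, 1L),
    family = sample(FAM_TEMPLATES, 1L),
    hypothetical = sample(HYP_TEMPLATES, 1L))
  pre <- sub("%s.*$", "", tpl)
  list(text = sprintf(tpl, surface),
       start = nchar(pre), end = nchar(pre) + nchar(surface))
}

#' Generate a seeded synthetic cohort
#'
#' Draws registry records, plants mentions into templated clinical notes,
#' emits ICD-9 diagnosis codes, and records a ground-truth manifest of every
#' planted mention (class, polarity, experiencer, temporality, span).
#' Recurrent and de novo patients receive positive present site-class
#' mentions plus correlated non-site mentions; controls receive distractors
#' (negated / family / hypothetical mentions and low-rate non-site positives).
#' Text noise implements the distant-label operating point: a false-negative
#' case gets no positive site mention, a false-positive control gets one.
#'
#' @param config An [sim_config()].
#' @param lexicon Lexicon whose surfaces are planted (default: bundled).
#' @return A list of class `mbc_cohort`: `notes`, `registry`, `diagnoses`
#'   data.frames, `truth` (list with `patients` and `manifest`), and the
#'   config.
#' @export
generate_cohort <- function(config = sim_config(), lexicon = load_lexicon()) {
  stopifnot(inherits(config, "mbc_sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%05d", seq_len(n))

  stage <- sample(names(config$p_stage), n, replace = TRUE,
                  prob = config$p_stage)
  status <- ifelse(stage == "IV", "de_novo",
                   ifelse(stats::runif(n) <
                            config$p_recurrence_given_early_stage,
                          "recurrent", "non_mbc"))

  registry <- data.frame(
    patient_id = ids,
    stage_at_dx = stage,
    age_at_dx = pmin(pmax(round(stats::rnorm(n, 54, 13)), 25), 95),
    year_of_dx = sample(2000:2014, n, replace = TRUE),
    race = sample_level(n, REGISTRY_LEVELS$race),
    ethnicity = sample_level(n, REGISTRY_LEVELS$ethnicity),
    marital_status = sample_level(n, REGISTRY_LEVELS$marital_status),
    ses_quintile = sample_level(n, REGISTRY_LEVELS$ses_quintile),
    payer = sample_level(n, REGISTRY_LEVELS$payer),
    grade = sample_level(n, REGISTRY_LEVELS$grade),
    histology = sample_level(n, REGISTRY_LEVELS$histology),
    receptor_subtype = sample_level(n, REGISTRY_LEVELS$receptor_subtype),
    comorbidity = sample_level(n, REGISTRY_LEVELS$comorbidity),
    stringsAsFactors = FALSE)

  is_case_text <- status %in% c("recurrent", "de_novo")
  n_notes <- ifelse(is_case_text,
                    1L + rnb(n, config$notes_mu_case, config$notes_size),
                    rnb(n, config$notes_mu_control, config$notes_size))
  fn_flag <- status == "recurrent" &
    stats::runif(n) < config$p_false_negative_text
  fp_flag <- status == "non_mbc" & n_notes > 0 &
    stats::runif(n) < config$p_false_positive_text

  tgt <- target_surfaces(lexicon)
  surfaces_of <- split(tgt$surface, tgt$class)
  nonsite_classes <- setdiff(names(surfaces_of), SITE_CLASSES)
  all_classes <- names(surfaces_of)

  notes_list <- vector("list", n)
  manifest_list <- vector("list", n)
  diag_list <- vector("list", n)

  for (i in seq_len(n)) {
    plan <- list()  # rows: class, kind (positive/negated/family/hypothetical)
    add_plan <- function(classes, kind) {
      if (length(classes)) {
        plan[[length(plan) + 1L]] <<-
          data.frame(class = classes, kind = kind, stringsAsFactors = FALSE)
      }
    }
    if (n_notes[i] > 0) {
      if (is_case_text[i] && !fn_flag[i]) {
        k <- 1L + rnb(1L, config$site_pos_mu)
        add_plan(sample(SITE_CLASSES, k, replace = TRUE), "positive")
      }
      if (fp_flag[i]) {
        add_plan(sample(SITE_CLASSES, 1L), "positive")
      }
      mus <- if (is_case_text[i] && !fn_flag[i]) config$nonsite_pos_mu_case
             else config$nonsite_pos_mu_control
      for (cls in intersect(names(mus), nonsite_classes)) {
        add_plan(rep(cls, rnb(1L, mus[[cls]])), "positive")
      }
      k <- rnb(1L, config$distractor_negated_mu)
      add_plan(sample(all_classes, k, replace = TRUE), "negated")
      k <- rnb(1L, config$distractor_family_mu)
      add_plan(sample(all_classes, k, replace = TRUE), "family")
      k <- rnb(1L, config$distractor_hypothetical_mu)
      add_plan(sample(all_classes, k, replace = TRUE), "hypothetical")
    }
    plan <- if (length(plan)) do.call(rbind, plan) else
      data.frame(class = character(), kind = character(),
                 stringsAsFactors = FALSE)
    if (nrow(plan)) plan <- plan[sample.int(nrow(plan)), , drop = FALSE]

    nn <- n_notes[i]
    if (nn > 0) {
      note_ids <- sprintf("%s-N%03d", ids[i], seq_len(nn))
      note_types <- sample(names(config$note_type_probs), nn, replace = TRUE,
                           prob = config$note_type_probs)
      note_dates <- random_date(nn)
      assign_to <- if (nrow(plan)) sample.int(nn, nrow(plan), replace = TRUE)
                   else integer(0)
      texts <- character(nn)
      man <- vector("list", nn)
      for (j in seq_len(nn)) {
        sents <- character(0)
        rows <- list()
        offset <- 0L
        n_fill_lead <- sample(0:2, 1L)
        for (f in seq_len(n_fill_lead)) {
          s <- sample(FILLER_SENTENCES, 1L)
          sents <- c(sents, s)
          offset <- offset + nchar(s) + 1L
        }
        for (p in which(assign_to == j)) {
          surf <- sample(surfaces_of[[plan$class[p]]], 1L)
          kind <- plan$kind[p]
          r <- render_sentence(surf, kind)
          sents <- c(sents, r$text)
          rows[[length(rows) + 1L]] <- data.frame(
            patient_id = ids[i], note_id = note_ids[j],
            note_type = note_types[j],
            start = offset + r$start, end = offset + r$end,
            surface = surf, class = plan$class[p],
            polarity = if (kind == "negated") "negated" else "positive",
            experiencer = if (kind == "family") "family" else "patient",
            temporality = if (kind == "hypothetical") "hypothetical"
                          else "present",
            stringsAsFactors = FALSE)
          offset <- offset + nchar(r$text) + 1L
        }
        if (length(sents) == 0L) {
          sents <- sample(FILLER_SENTENCES, 1L)
        }
        texts[j] <- paste(sents, collapse = " ")
        man[[j]] <- if (length(rows)) do.call(rbind, rows) else NULL
      }
      notes_list[[i]] <- data.frame(
        patient_id = ids[i], note_id = note_ids, note_type = note_types,
        date = note_dates, text = texts, stringsAsFactors = FALSE)
      man <- man[!vapply(man, is.null, logical(1))]
      if (length(man)) manifest_list[[i]] <- do.call(rbind, man)
    }

    is_mbc <- status[i] != "non_mbc"
    p_code <- if (is_mbc) config$p_code_given_case
              else config$p_code_given_control
    codes <- sample(BENIGN_ICD9, 1L + stats::rpois(1L, 1.5), replace = TRUE)
    if (stats::runif(1) < p_code) {
      codes <- c(codes, sample(MET_ICD9, 1L + stats::rpois(1L, 0.5),
                               replace = TRUE))
    }
    diag_list[[i]] <- data.frame(patient_id = ids[i], code = codes,
                                 date = random_date(length(codes)),
                                 stringsAsFactors = FALSE)
  }

  notes <- do.call(rbind, c(notes_list[!vapply(notes_list, is.null,
                                               logical(1))],
                            list(make.row.names = FALSE)))
  if (is.null(notes)) {
    notes <- data.frame(patient_id = character(), note_id = character(),
                        note_type = character(), date = character(),
                        text = character(), stringsAsFactors = FALSE)
  }
  manifest_list <- manifest_list[!vapply(manifest_list, is.null, logical(1))]
  manifest <- if (length(manifest_list)) {
    do.call(rbind, c(manifest_list, list(make.row.names = FALSE)))
  } else empty_mentions()
  diagnoses <- do.call(rbind, c(diag_list, list(make.row.names = FALSE)))

  truth_patients <- data.frame(
    patient_id = ids, true_status = status,
    text_false_negative = fn_flag, text_false_positive = fp_flag,
    n_notes = n_notes, stringsAsFactors = FALSE)

  structure(list(notes = notes, registry = registry, diagnoses = diagnoses,
                 truth = list(patients = truth_patients, manifest = manifest),
                 config = config),
            class = "mbc_cohort")
}

#' @export
print.mbc_cohort <- function(x, ...) {
  tab <- table(x$truth$patients$true_status)
  cat("<mbc_cohort> ", nrow(x$truth$patients), " patients (",
      paste(names(tab), unname(tab), sep = "=", collapse = ", "), "); ",
      nrow(x$notes), " notes, ", nrow(x$truth$manifest),
      " planted mentions\n", sep = "")
  invisible(x)
}

#' Draw an adjudicated gold-standard evaluation subset
#'
#' Stratified sample of recurrent cases and non-MBC controls with notes,
#' mirroring an expert-reviewed balanced evaluation set (default 72 cases
#' and 74 controls). Truth comes from the generator manifest, standing in
#' for physician adjudication.
#'
#' @param cohort An `mbc_cohort`.
#' @param n_cases,n_controls Numbers of recurrent cases / non-MBC controls.
#' @param seed Integer seed (independent of the cohort seed).
#' @return Data.frame (patient_id, truth) with truth 1 = recurrent.
#' @export
generate_gold_set <- function(cohort, n_cases = 72L, n_controls = 74L,
                              seed = 1L) {
  stopifnot(inherits(cohort, "mbc_cohort"), n_cases >= 1L, n_controls >= 1L)
  tp <- cohort$truth$patients
  cases <- tp$patient_id[tp$true_status == "recurrent"]
  controls <- tp$patient_id[tp$true_status == "non_mbc" & tp$n_notes > 0]
  if (length(cases) < n_cases || length(controls) < n_controls) {
    stop("cohort has only ", length(cases), " cases and ", length(controls),
         " noted controls; cannot draw ", n_cases, "/", n_controls)
  }
  set.seed(seed)
  sel <- data.frame(
    patient_id = c(sample(cases, n_cases), sample(controls, n_controls)),
    truth = c(rep(1L, n_cases), rep(0L, n_controls)),
    stringsAsFactors = FALSE)
  sel[order(sel$patient_id), , drop = FALSE]
}
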