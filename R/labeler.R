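# Cohort flow: registry-derived de novo labels, no-note exclusion, and the
# distant (text-derived) label for metastatic recurrence.

LABEL_LEVELS <- c("de_novo_mbc", "distant_positive", "distant_negative",
                  "non_mbc_no_notes")

#' Assign a cohort label to one patient
#'
#' Stage IV at diagnosis is de novo metastatic disease, taken directly from
#' the registry. Early-stage (0-III or missing-stage) patients with no notes
#' are non-MBC by exclusion. The remaining patients get a distant label:
#' positive iff at least one mention from a site class (bone, brain, liver,
#' lung) is positive, present, and about the patient.
#'
#' @param record One-row data.frame or list with `patient_id` and
#'   `stage_at_dx` (one of "0","I","II","III","IV","missing").
#' @param mentions The patient's mention data.frame (may have zero rows).
#' @param has_notes Does the patient have at least one note?
#' @return A list with `patient_id`, `label`, and `evidence` (the qualifying
#'   mention rows; empty unless distant_positive).
#' @export
assign_label <- function(record, mentions, has_notes) {
  pid <- as.character(record$patient_id)
  if (nrow(mentions) && any(mentions$patient_id != pid)) {
    stop("mentions for patient ", pid, " contain other patient ids")
  }
  evidence <- mentions[0, , drop = FALSE]
  if (identical(as.character(record$stage_at_dx), "IV")) {
    label <- "de_novo_mbc"
  } else if (!isTRUE(has_notes)) {
    label <- "non_mbc_no_notes"
  } else {
    qual <- mentions$class %in% SITE_CLASSES &
      mentions$polarity == "positive" &
      mentions$experiencer == "patient" &
      mentions$temporality == "present"
    if (any(qual)) {
      label <- "distant_positive"
      evidence <- mentions[qual, , drop = FALSE]
    } else {
      label <- "distant_negative"
    }
  }
  list(patient_id = pid, label = label, evidence = evidence)
}

#' Label a whole cohort
#'
#' Applies [assign_label()] per patient and optionally merges adjudicated
#' expert labels, which supersede the text-derived ones (mirroring physician
#' review of borderline cases).
#'
#' @param registry Registry data.frame, one row per patient, with
#'   `patient_id` and `stage_at_dx`.
#' @param mentions Mentions table from [tag_corpus()].
#' @param notes Notes data.frame (used to determine who has notes).
#' @param adjudicated Optional data.frame (patient_id, label) of expert
#'   overrides; labels must be in the legal set.
#' @return Data.frame with patient_id, label, n_evidence_mentions.
#' @export
label_cohort <- function(registry, mentions, notes, adjudicated = NULL) {
  if (anyDuplicated(registry$patient_id)) {
    stop("duplicate patient_id in registry")
  }
  noted <- unique(as.character(notes$patient_id))
  split_m <- split(seq_len(nrow(mentions)), mentions$patient_id)
  labs <- character(nrow(registry))
  nev <- integer(nrow(registry))
  for (i in seq_len(nrow(registry))) {
    pid <- as.character(registry$patient_id[i])
    idx <- split_m[[pid]]
    m <- if (is.null(idx)) empty_mentions() else mentions[idx, , drop = FALSE]
    res <- assign_label(registry[i, ], m, has_notes = pid %in% noted)
    labs[i] <- res$label
    nev[i] <- nrow(res$evidence)
  }
  out <- data.frame(patient_id = as.character(registry$patient_id),
                    label = labs, n_evidence_mentions = nev,
                    stringsAsFactors = FALSE)
  if (!is.null(adjudicated)) {
    if (!all(adjudicated$label %in% LABEL_LEVELS)) {
      stop("adjudicated labels must be one of: ",
           paste(LABEL_LEVELS, collapse = ", "))
    }
    j <- match(as.character(adjudicated$patient_id), out$patient_id)
    if (anyNA(j)) stop("adjudicated override for unknown patient_id")
    out$label[j] <- adjudicated$label
  }
  out
}

#' Summarize cohort label counts
#'
#' MBC patients are the union of de novo (stage IV at diagnosis) and
#' text/adjudication-labeled recurrent patients; percentages are of the MBC
#' total, rounded to one decimal.
#'
#' @param labels Data.frame with `patient_id` and `label`.
#' @return A list: n_total, n_mbc, n_de_novo, n_recurrent,
#'   pct_de_novo_of_mbc, pct_recurrent_of_mbc, n_non_mbc.
#' @examples
#' labs <- data.frame(
#'   patient_id = as.character(1:4),
#'   label = c("de_novo_mbc", "distant_positive", "distant_negative",
#'             "non_mbc_no_notes"))
#' summarize_cohort(labs)
#' @export
summarize_cohort <- function(labels) {
  if (anyDuplicated(labels$patient_id)) {
    stop("duplicate patient_id in labels")
  }
  stopifnot(all(labels$label %in% LABEL_LEVELS))
  tab <- table(factor(labels$label, levels = LABEL_LEVELS))
  n_de_novo <- unname(tab["de_novo_mbc"])
  n_recurrent <- unname(tab["distant_positive"])
  n_non <- unname(tab["distant_negative"] + tab["non_mbc_no_notes"])
  n_mbc <- n_de_novo + n_recurrent
  list(n_total = n_mbc + n_non,
       n_mbc = n_mbc,
       n_de_novo = n_de_novo,
       n_recurrent = n_recurrent,
       pct_de_novo_of_mbc = if (n_mbc > 0) round(100 * n_de_novo / n_mbc, 1)
                            else NA_real_,
       pct_recurrent_of_mbc = if (n_mbc > 0) round(100 * n_recurrent / n_mbc, 1)
                              else NA_real_,
       n_non_mbc = n_non)
}

#' Rule-based ICD-9 metastasis classifier
#'
#' The structured-data benchmark: a patient is called metastatic iff at least
#' one diagnosis code falls in 196.XX-199.XX (secondary and unspecified
#' malignant neoplasms). Matching is on the string prefix before the decimal
#' point, so "1967.1" does not qualify and a bare "196" does. Codes that do
#' not look like ICD-9 (digits, optionally V/E-prefixed) never qualify.
#'
#' @param codes Character vector of one patient's ICD-9-CM codes.
#' @return Logical: does any code fall in the metastatic range?
#' @examples
#' classify_icd9(c("197.7"))         # TRUE
#' classify_icd9(c("195.9", "V10.3")) # FALSE
#' @export
classify_icd9 <- function(codes) {
  if (length(codes) == 0L) return(FALSE)
  prefix <- sub("\\..*$", "", trimws(as.character(codes)))
  any(prefix %in% c("196", "197", "198", "199"))
}

#' Apply the ICD-9 benchmark to a diagnosis table
#'
#' @param diagnoses Data.frame with `patient_id` and `code`.
#' @param patient_ids Patients to classify (defaults to those present in
#'   `diagnoses`); patients with no codes are classified FALSE.
#' @return Data.frame (patient_id, icd9_mbc).
#' @export
classify_icd9_cohort <- function(diagnoses,
                                 patient_ids = unique(diagnoses$patient_id)) {
  by_pat <- split(as.character(diagnoses$code),
                  as.character(diagnoses$patient_id))
  flag <- vapply(as.character(patient_ids), function(p) {
    classify_icd9(by_pat[[p]] %||% character(0))
  }, logical(1), USE.NAMES = FALSE)
  data.frame(patient_id = as.character(patient_ids), icd9_mbc = flag,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
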