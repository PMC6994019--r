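# Patient-level feature construction for the recurrence classifiers.
#
# NLP features are mention counts per (word class x note type x polarity
# stat); the four site classes are excluded because they define the training
# labels — keeping them would let the model learn the labeling rule back.
# Registry features are one-hot with an explicit "missing" level.

REGISTRY_LEVELS <- list(
  stage_at_dx = c("0", "I", "II", "III", "IV", "missing"),
  year_bin = c("lt2005", "y2005_2009", "y2010_2015"),
  race = c("white", "black", "asian_pi", "other", "missing"),
  ethnicity = c("hispanic", "non_hispanic", "missing"),
  marital_status = c("single", "married", "divorced", "widowed",
                     "separated_or_partner", "missing"),
  ses_quintile = c("q1", "q2", "q3", "q4", "q5", "missing"),
  payer = c("not_insured", "insurance_nos", "managed_care", "medicaid",
            "medicare", "other", "missing"),
  grade = c("1", "2", "3", "missing"),
  histology = c("ductal", "lobular", "other", "missing"),
  receptor_subtype = c("hr_pos_her2_neg", "her2_pos", "triple_negative",
                       "missing"),
  comorbidity = c("none", "mild", "moderate", "severe", "missing")
)

DEFAULT_NOTE_TYPES <- c("med_onc", "rad_onc", "pathology", "radiology",
                        "primary_care")

#' Feature specification for classifier configurations A, B, C
#'
#' Configuration A uses registry features only, B mention-count (NLP)
#' features only, C both. NLP classes never include the four site classes.
#'
#' @param configuration One of "A", "B", "C"; sets `use_nlp`/`use_registry`.
#' @param note_types Ordered note-type strings; an "ALL" aggregate is always
#'   added.
#' @param nlp_classes Target classes to count; site classes are removed if
#'   supplied.
#' @param lexicon Optional `mbc_lexicon` from which to take the default
#'   class list.
#' @return An object of class `mbc_feature_spec`.
#' @export
feature_spec <- function(configuration = c("C", "A", "B"),
                         note_types = DEFAULT_NOTE_TYPES,
                         nlp_classes = NULL,
                         lexicon = NULL) {
  configuration <- match.arg(configuration)
  if (is.null(nlp_classes)) {
    nlp_classes <- if (!is.null(lexicon)) target_class_names(lexicon)
                   else c("DIED", "DRECUR", "LRECUR", "MBC", "MBCLOW",
                          "METSNOS", "RECUR")
  }
  nlp_classes <- setdiff(nlp_classes, SITE_CLASSES)
  use_nlp <- configuration %in% c("B", "C")
  use_registry <- configuration %in% c("A", "C")
  if (use_nlp && length(note_types) == 0L) {
    stop("note_types must be non-empty when NLP features are used")
  }
  structure(list(configuration = configuration, use_nlp = use_nlp,
                 use_registry = use_registry, note_types = note_types,
                 nlp_classes = nlp_classes,
                 polarity_stats = c("total", "positive", "negated")),
            class = "mbc_feature_spec")
}

#' @export
print.mbc_feature_spec <- function(x, ...) {
  cat("<mbc_feature_spec> configuration ", x$configuration,
      " (nlp=", x$use_nlp, ", registry=", x$use_registry, ")\n", sep = "")
  if (x$use_nlp) {
    cat("  ", length(x$nlp_classes), " classes x ",
        length(x$note_types) + 1L, " note types x 3 stats + ",
        length(x$nlp_classes), " auxiliary = ",
        length(nlp_feature_names(x)), " NLP features\n", sep = "")
  }
  invisible(x)
}

nlp_feature_names <- function(spec) {
  nt <- c(spec$note_types, "ALL")
  grid <- expand.grid(stat = spec$polarity_stats, note_type = nt,
                      class = spec$nlp_classes, stringsAsFactors = FALSE)
  c(paste("nlp", grid$class, grid$note_type, grid$stat, sep = "."),
    paste("nlp", spec$nlp_classes, "ALL", "nonpatient_or_hypothetical",
          sep = "."))
}

#' Build NLP mention-count features for one patient
#'
#' For each (class, note type, stat) cell: the number of the patient's
#' present-tense, patient-experiencer mentions of that class in that note
#' type, where stat is total / positive / negated (total = positive +
#' negated). Family-member and hypothetical mentions are kept out of these
#' counts and aggregated into one auxiliary `nonpatient_or_hypothetical`
#' count per class.
#'
#' @param mentions One patient's mention data.frame.
#' @param spec An `mbc_feature_spec` with `use_nlp = TRUE`.
#' @return Named numeric vector (stable order given the spec).
#' @export
build_nlp_features <- function(mentions, spec) {
  stopifnot(inherits(spec, "mbc_feature_spec"), spec$use_nlp)
  nms <- nlp_feature_names(spec)
  v <- stats::setNames(numeric(length(nms)), nms)
  m <- mentions[mentions$class %in% spec$nlp_classes, , drop = FALSE]
  if (nrow(m) == 0L) return(v)
  unknown <- !m$note_type %in% spec$note_types
  if (any(unknown)) {
    warning(sum(unknown), " mention(s) with note types outside the feature ",
            "spec counted under ALL only")
  }
  patient_present <- m$experiencer == "patient" & m$temporality == "present"
  aux <- m[!patient_present, , drop = FALSE]
  m <- m[patient_present, , drop = FALSE]
  add <- function(name, k = 1L) {
    if (name %in% names(v)) v[name] <<- v[name] + k
  }
  for (i in seq_len(nrow(m))) {
    cls <- m$class[i]
    pol <- m$polarity[i]
    nts <- "ALL"
    if (m$note_type[i] %in% spec$note_types) nts <- c(m$note_type[i], "ALL")
    for (nt in nts) {
      add(paste("nlp", cls, nt, "total", sep = "."))
      add(paste("nlp", cls, nt, pol, sep = "."))
    }
  }
  for (i in seq_len(nrow(aux))) {
    add(paste("nlp", aux$class[i], "ALL", "nonpatient_or_hypothetical",
              sep = "."))
  }
  v
}

registry_feature_names <- function() {
  onehot <- unlist(lapply(names(REGISTRY_LEVELS), function(f) {
    paste("ccr", f, REGISTRY_LEVELS[[f]], sep = ".")
  }), use.names = FALSE)
  c("ccr.age_at_dx", onehot)
}

year_bin <- function(year) {
  ifelse(is.na(year), "lt2005",
         ifelse(year < 2005, "lt2005",
                ifelse(year <= 2009, "y2005_2009", "y2010_2015")))
}

#' Build one-hot registry features for one patient
#'
#' Age stays numeric (standardized at training time); year of diagnosis is
#' binned (<2005, 2005-2009, 2010-2015); every other field is one-hot encoded
#' with an explicit `missing` column. A category not in the known level set
#' is mapped to `missing` with a warning, so prediction never fails on an
#' unseen level.
#'
#' @param record One-row registry data.frame (see [generate_cohort()] for the
#'   schema).
#' @param spec An `mbc_feature_spec` with `use_registry = TRUE`.
#' @return Named numeric vector.
#' @export
build_registry_features <- function(record, spec) {
  stopifnot(inherits(spec, "mbc_feature_spec"), spec$use_registry)
  nms <- registry_feature_names()
  v <- stats::setNames(numeric(length(nms)), nms)
  v["ccr.age_at_dx"] <- as.numeric(record$age_at_dx)
  vals <- list(year_bin = year_bin(as.integer(record$year_of_dx)))
  for (f in setdiff(names(REGISTRY_LEVELS), "year_bin")) {
    vals[[f]] <- as.character(record[[f]])
  }
  for (f in names(REGISTRY_LEVELS)) {
    val <- vals[[f]]
    if (is.na(val) || !val %in% REGISTRY_LEVELS[[f]]) {
      if (!is.na(val) && !val %in% REGISTRY_LEVELS[[f]]) {
        warning("unknown level '", val, "' for registry field '", f,
                "' mapped to missing")
      }
      val <- "missing"
    }
    v[paste("ccr", f, val, sep = ".")] <- 1
  }
  v
}

#' Assemble the design matrix for classifier training
#'
#' Rows are the patients routed through distant labeling (de novo stage IV
#' and no-note patients are excluded — they never enter training); columns
#' follow the feature spec; `y` is 1 for distant_positive, 0 for
#' distant_negative.
#'
#' @param registry Registry data.frame (one row per patient).
#' @param mentions Mentions table from [tag_corpus()].
#' @param labels Labels from [label_cohort()].
#' @param spec An `mbc_feature_spec`.
#' @return List with `X` (numeric matrix, rownames = patient ids), `y`
#'   (0/1 integer vector), `feature_names`.
#' @export
assemble_design_matrix <- function(registry, mentions, labels, spec) {
  keep <- labels$label %in% c("distant_positive", "distant_negative")
  ids <- as.character(labels$patient_id[keep])
  y <- as.integer(labels$label[keep] == "distant_positive")
  reg_idx <- match(ids, as.character(registry$patient_id))
  if (anyNA(reg_idx)) stop("labels contain patient ids absent from registry")
  split_m <- split(seq_len(nrow(mentions)), mentions$patient_id)
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    parts <- numeric(0)
    if (spec$use_nlp) {
      idx <- split_m[[ids[i]]]
      m <- if (is.null(idx)) empty_mentions() else mentions[idx, , drop = FALSE]
      parts <- c(parts, build_nlp_features(m, spec))
    }
    if (spec$use_registry) {
      parts <- c(parts, build_registry_features(registry[reg_idx[i], ], spec))
    }
    rows[[i]] <- parts
  }
  X <- do.call(rbind, rows)
  rownames(X) <- ids
  zv <- apply(X, 2, function(col) length(unique(col)) == 1L)
  if (any(zv)) {
    message(sum(zv), " zero-variance feature column(s) retained: ",
            paste(utils::head(colnames(X)[zv], 5), collapse = ", "),
            if (sum(zv) > 5) ", ..." else "")
  }
  list(X = X, y = y, feature_names = colnames(X))
}
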