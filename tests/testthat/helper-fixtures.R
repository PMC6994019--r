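# Shared fixtures and independent oracles, built in code at test time.

# Minimal valid lexicon TSV (must include the four site classes).
write_tiny_lexicon <- function(extra_rows = character(0)) {
  path <- tempfile(fileext = ".tsv")
  rows <- c(
    "surface\tclass\tkind\tcontext_role",
    "bone mets\tMETSBONE\ttarget\tnone",
    "diffuse skeletal mets\tMETSBONE\ttarget\tnone",
    "brain mets\tMETSBRAIN\ttarget\tnone",
    "liver mets\tMETSLIVER\ttarget\tnone",
    "liver metastases\tMETSLIVER\ttarget\tnone",
    "lung mets\tMETSLUNG\ttarget\tnone",
    "mets\tMBCLOW\ttarget\tnone",
    "recurrent metastatic tnbc\tDRECUR\ttarget\tnone",
    "no\tNEG\tcontext\tnegation",
    "no evidence of\tNEG\tcontext\tnegation",
    "no increase in\tPSEUDONEG\tcontext\tpseudo_negation",
    "mother\tFAM\tcontext\tfamily",
    "if\tHYPO\tcontext\thypothetical",
    "but\tTERM\tcontext\tscope_terminator",
    extra_rows)
  writeLines(rows, path)
  path
}

make_note <- function(text, patient_id = "P1", note_id = "N1",
                      note_type = "med_onc", date = "2010-01-01") {
  data.frame(patient_id = patient_id, note_id = note_id,
             note_type = note_type, date = date, text = text,
             stringsAsFactors = FALSE)
}

# O(n^2) pair-counting AUC oracle: concordant pairs + half ties over all
# case-control pairs. Independent of the rank-based implementation.
auc_pair_oracle <- function(scores, y) {
  cases <- scores[y == 1]
  controls <- scores[y == 0]
  tot <- 0
  for (a in cases) {
    for (b in controls) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(cases) * length(controls))
}

# Direct numerical minimizer of the ridge logistic objective
#   mean NLL + (lambda/2) ||slopes||^2  (intercept unpenalized).
ridge_logistic_oracle <- function(X, y, lambda) {
  obj <- function(par) {
    eta <- par[1] + X %*% par[-1]
    mean(log1p(exp(eta)) - y * eta) + lambda / 2 * sum(par[-1]^2)
  }
  stats::optim(rep(0, ncol(X) + 1L), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))$par
}

# Brute-force PPMI matrix over a tokenized-sentence list (symmetric window),
# independent of the package's embedding pipeline.
ppmi_oracle <- function(sents, vocab, window) {
  V <- length(vocab)
  co <- matrix(0, V, V, dimnames = list(vocab, vocab))
  for (s in sents) {
    n <- length(s)
    for (j in seq_len(n)) {
      for (k in seq_len(n)) {
        if (k != j && abs(k - j) <= window) {
          co[s[j], s[k]] <- co[s[j], s[k]] + 1
        }
      }
    }
  }
  total <- sum(co)
  rs <- rowSums(co); cs <- colSums(co)
  pmi <- log(co * total / outer(rs, cs))
  pmi[!is.finite(pmi)] <- 0
  pmax(pmi, 0)
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Small noise-free cohort shared by several tests (generated once per run).
tiny_quiet_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(sim_config(
        n_patients = 150, p_false_negative_text = 0,
        p_false_positive_text = 0, seed = 401L))
    }
    cache
  }
})
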