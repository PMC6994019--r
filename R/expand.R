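# Corpus-driven terminology expansion: PPMI co-occurrence embedding with
# truncated SVD, cosine-ranked candidates per seed term. Deterministic given
# the corpus — no stochastic training. Output is a review file for human
# curation; candidates are never merged into the lexicon automatically.

#' Expand lexicon terminology from a note corpus
#'
#' Builds a vocabulary of unigrams plus contiguous bigram/trigram phrases
#' whose pointwise mutual information exceeds `phrase_pmi_min` (multi-word
#' seed surfaces are always treated as phrases), counts co-occurrences in a
#' symmetric `window`-token window within sentences, transforms to positive
#' PMI, reduces to `d` dimensions by truncated SVD, and returns for each
#' seed term up to `top_k` non-seed vocabulary items with cosine similarity
#' at least `min_similarity`, ranked descending.
#'
#' Candidates are suggestions for expert review: terminology growth is an
#' iterative human-in-the-loop process, so this function never modifies the
#' lexicon.
#'
#' @param corpus Data.frame of notes (column `text`), or character vector.
#' @param seeds An `mbc_lexicon`; its target surfaces are the seed terms.
#' @param top_k Maximum candidates per seed (default 10).
#' @param min_similarity Cosine threshold in \[0, 1\] (default 0.5).
#' @param window Symmetric co-occurrence window in tokens (default 5).
#' @param d Embedding dimensionality (default 50).
#' @param phrase_pmi_min PMI threshold for mining candidate phrases
#'   (default 3).
#' @return Data.frame (candidate, seed, similarity, decision) sorted by seed
#'   then descending similarity; `decision` is an empty placeholder column
#'   for reviewers. Out-of-vocabulary seeds produce a warning and no rows.
#' @export
expand_terminology <- function(corpus, seeds, top_k = 10L,
                               min_similarity = 0.5, window = 5L, d = 50L,
                               phrase_pmi_min = 3) {
  stopifnot(top_k >= 1L, min_similarity >= 0, min_similarity <= 1,
            window >= 1L, d >= 1L)
  texts <- if (is.data.frame(corpus)) corpus$text else as.character(corpus)
  texts <- texts[!is.na(texts) & nzchar(texts)]
  if (length(texts) == 0L) stop("corpus is empty")
  seed_keys <- unique(vapply(target_surfaces(seeds)$surface, function(s) {
    paste(tolower(tokenize(s)$token), collapse = " ")
  }, character(1), USE.NAMES = FALSE))

  sents <- unlist(lapply(texts, function(t) {
    lapply(segment_text(t), function(s) tolower(s$token))
  }), recursive = FALSE)
  sents <- sents[lengths(sents) > 0L]

  # Multi-word seed surfaces are merged first (they are known phrases and
  # must not be fragmented by mined ones); then one PMI-thresholded bigram
  # pass mines candidate phrases from the corpus itself.
  sents <- lapply(sents, merge_phrases,
                  phrases = seed_keys[grepl(" ", seed_keys)])
  mined <- mine_phrases(sents, phrase_pmi_min)
  # never let a mined phrase absorb a merged multi-word seed occurrence
  mined <- mined[!vapply(strsplit(mined$phrase, " ", fixed = TRUE),
                         function(w) any(grepl("_", w, fixed = TRUE)),
                         logical(1)), , drop = FALSE]
  sents <- lapply(sents, merge_phrases, phrases = mined$phrase,
                  scores = mined$pmi)

  vocab <- sort(unique(unlist(sents)))
  if (length(vocab) < 2L) stop("corpus vocabulary too small")
  co <- cooccurrence_matrix(sents, vocab, window)
  ppmi <- ppmi_transform(co)

  d_eff <- min(d, nrow(ppmi) - 1L)
  if (d_eff < 1L) stop("corpus too small for the requested dimensionality; ",
                       "try a smaller d")
  sv <- svd(ppmi, nu = d_eff, nv = 0)
  emb <- sv$u %*% diag(sqrt(sv$d[seq_len(d_eff)]), d_eff)
  rownames(emb) <- vocab
  norms <- sqrt(rowSums(emb^2))

  out <- list()
  space_keys <- gsub("_", " ", vocab, fixed = TRUE)
  for (seed in seed_keys) {
    v_seed <- gsub(" ", "_", seed, fixed = TRUE)
    i <- match(v_seed, vocab)
    if (is.na(i) || norms[i] == 0) {
      warning("seed term '", seed, "' not in corpus vocabulary")
      next
    }
    sims <- drop(emb %*% emb[i, ]) / (norms * norms[i])
    sims[norms == 0] <- -Inf
    cand <- data.frame(candidate = space_keys, seed = seed,
                       similarity = sims, stringsAsFactors = FALSE)
    cand <- cand[!(space_keys %in% seed_keys), , drop = FALSE]
    cand <- cand[is.finite(cand$similarity) &
                   cand$similarity >= min_similarity, , drop = FALSE]
    cand <- cand[order(-cand$similarity, cand$candidate), , drop = FALSE]
    out[[seed]] <- utils::head(cand, top_k)
  }
  res <- if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
         else data.frame(candidate = character(), seed = character(),
                         similarity = numeric(), stringsAsFactors = FALSE)
  res$decision <- rep("", nrow(res))
  res
}

# Contiguous bigrams with PMI above the threshold (seen at least twice):
# PMI(w1 w2) = log( p(w1 w2) / (p(w1) p(w2)) ). Units already merged (seed
# phrases) count as single tokens, so a mined bigram may itself contain a
# phrase.
mine_phrases <- function(sents, pmi_min) {
  toks <- unlist(sents)
  n_tok <- length(toks)
  if (n_tok == 0L) return(character(0))
  uni <- table(toks)
  p_uni <- as.numeric(uni) / n_tok
  names(p_uni) <- names(uni)
  grams <- unlist(lapply(sents, function(s) {
    if (length(s) < 2L) return(character(0))
    paste(s[-length(s)], s[-1L])
  }))
  empty <- data.frame(phrase = character(), pmi = numeric(),
                      stringsAsFactors = FALSE)
  if (length(grams) == 0L) return(empty)
  gtab <- table(grams)
  words <- strsplit(names(gtab), " ", fixed = TRUE)
  indep <- vapply(words, function(w) prod(p_uni[w]), numeric(1))
  pmi <- log(as.numeric(gtab) / length(grams) / indep)
  keep <- pmi >= pmi_min & as.numeric(gtab) >= 2
  data.frame(phrase = names(gtab)[keep], pmi = pmi[keep],
             stringsAsFactors = FALSE)
}

# Replace phrase token runs with single underscore-joined tokens. Candidate
# occurrences anywhere in the sentence are accepted greedily by descending
# score (longer phrases win ties), so a high-PMI phrase is never fragmented
# by an overlapping weaker one. Default scores favor longer phrases.
merge_phrases <- function(tokens, phrases, scores = NULL) {
  n <- length(tokens)
  if (length(phrases) == 0L || n == 0L) return(tokens)
  plist <- strsplit(phrases, " ", fixed = TRUE)
  lens <- lengths(plist)
  if (is.null(scores)) scores <- lens
  occ_start <- integer(0); occ_len <- integer(0); occ_score <- numeric(0)
  for (p in seq_along(phrases)) {
    L <- lens[p]
    if (L > n) next
    for (i in seq_len(n - L + 1L)) {
      if (all(tokens[i:(i + L - 1L)] == plist[[p]])) {
        occ_start <- c(occ_start, i); occ_len <- c(occ_len, L)
        occ_score <- c(occ_score, scores[p])
      }
    }
  }
  if (length(occ_start) == 0L) return(tokens)
  ord <- order(-occ_score, -occ_len, occ_start)
  taken <- logical(n)
  merged_at <- integer(0); merged_len <- integer(0)
  for (k in ord) {
    span <- occ_start[k]:(occ_start[k] + occ_len[k] - 1L)
    if (!any(taken[span])) {
      taken[span] <- TRUE
      merged_at <- c(merged_at, occ_start[k])
      merged_len <- c(merged_len, occ_len[k])
    }
  }
  out <- character(0)
  i <- 1L
  while (i <= n) {
    j <- match(i, merged_at)
    if (!is.na(j)) {
      out <- c(out, paste(tokens[i:(i + merged_len[j] - 1L)],
                          collapse = "_"))
      i <- i + merged_len[j]
    } else {
      out <- c(out, tokens[i])
      i <- i + 1L
    }
  }
  out
}

# Symmetric windowed co-occurrence counts (dense; desk-scale vocabularies).
cooccurrence_matrix <- function(sents, vocab, window) {
  V <- length(vocab)
  co <- matrix(0, V, V, dimnames = list(vocab, vocab))
  for (s in sents) {
    idx <- match(s, vocab)
    n <- length(idx)
    for (j in seq_len(n)) {
      lo <- max(1L, j - window); hi <- min(n, j + window)
      ctx <- idx[setdiff(lo:hi, j)]
      for (c in ctx) co[idx[j], c] <- co[idx[j], c] + 1
    }
  }
  co
}

ppmi_transform <- function(co) {
  total <- sum(co)
  if (total == 0) return(co)
  rs <- rowSums(co); cs <- colSums(co)
  expected <- outer(rs, cs) / total
  pmi <- log((co * total) / (rs %o% cs))
  pmi[!is.finite(pmi)] <- 0
  pmax(pmi, 0)
}

#' Write an expansion review file
#'
#' TSV with columns candidate, seed, similarity, decision — the decision
#' column is left blank for reviewers to fill in.
#'
#' @param candidates Output of [expand_terminology()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_review_file <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
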