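# Mention detection and NegEx/ConText-style context resolution.
#
# Matching is token based: note text and lexicon surfaces go through the same
# tokenizer, so multi-word and hyphenated surfaces ("in-breast recurrence")
# align regardless of spacing. Character spans are 0-based half-open into the
# newline-normalized note text; lowercasing is used for matching only.

# Tokens are maximal alnum/apostrophe runs; every other non-space character is
# its own token. Returns 0-based half-open char spans.
tokenize <- function(text) {
  text <- normalize_newlines(text)
  if (!nzchar(text)) {
    return(data.frame(token = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  m <- gregexpr("[[:alnum:]']+|[^[:alnum:]'[:space:]]", text)[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(token = substring(text, m, m + len - 1L),
             start = start, end = start + len,
             stringsAsFactors = FALSE)
}

normalize_newlines <- function(text) {
  gsub("\r\n?", "\n", text)
}

#' Segment note text into sentences of tokens
#'
#' Sentences break on `.`, `!`, `?`, `;` and on blank lines; tokens split on
#' whitespace and punctuation boundaries. Character spans are 0-based
#' half-open into the newline-normalized text (`\r\n`/`\r` become `\n`, so
#' Windows and Unix line endings segment identically).
#'
#' @param text A single note text string.
#' @return A list of sentences; each sentence is a data.frame with columns
#'   `token`, `start`, `end`. Empty text gives an empty list.
#' @examples
#' segment_text("No liver mets. Bone mets present.")
#' @export
segment_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- normalize_newlines(text)
  toks <- tokenize(text)
  n <- nrow(toks)
  if (n == 0L) return(list())
  # A sentence ends at a terminator token or when the gap to the next token
  # contains a blank line.
  terminator <- toks$token %in% c(".", "!", "?", ";")
  gap_break <- logical(n)
  if (n > 1L) {
    gaps <- substring(text, toks$end[-n] + 1L, toks$start[-1])
    gap_break[-n] <- grepl("\n[ \t]*\n", gaps)
  }
  ends_here <- terminator | gap_break
  sent_id <- cumsum(c(0L, ends_here[-n])) + 1L
  keep <- !terminator  # terminators delimit, they are not content tokens
  out <- split(toks[keep, , drop = FALSE], sent_id[keep])
  out <- out[vapply(out, nrow, integer(1)) > 0L]
  lapply(unname(out), function(d) { rownames(d) <- NULL; d })
}

# Longest-match left-to-right over lowercased tokens against a surface table
# (columns surface, class, surface_key, key_len). Matched tokens are
# consumed. n-gram keys are built vectorized per length, so the greedy walk
# itself is cheap. Returns token-index ranges.
match_surfaces <- function(tokens, surfaces) {
  empty <- data.frame(first = integer(), last = integer(),
                      surface = character(), class = character(),
                      stringsAsFactors = FALSE)
  n <- nrow(tokens)
  if (n == 0L || nrow(surfaces) == 0L) return(empty)
  low <- tolower(tokens$token)
  lens <- sort(unique(surfaces$key_len), decreasing = TRUE)
  lens <- lens[lens <= n]
  if (length(lens) == 0L) return(empty)
  # hit[[as.character(L)]][i] = surface row matching tokens i..i+L-1, or NA
  hit <- list()
  for (L in lens) {
    parts <- lapply(seq_len(L) - 1L, function(o) low[(1L + o):(n - L + 1L + o)])
    keys <- if (L == 1L) parts[[1L]] else do.call(paste, parts)
    sub <- which(surfaces$key_len == L)
    hit[[as.character(L)]] <- sub[match(keys, surfaces$surface_key[sub])]
  }
  first <- integer(0); last <- integer(0); row <- integer(0)
  i <- 1L
  while (i <= n) {
    matched <- FALSE
    for (L in lens) {
      if (i > n - L + 1L) next
      j <- hit[[as.character(L)]][i]
      if (!is.na(j)) {
        first <- c(first, i); last <- c(last, i + L - 1L); row <- c(row, j)
        i <- i + L
        matched <- TRUE
        break
      }
    }
    if (!matched) i <- i + 1L
  }
  if (length(first) == 0L) return(empty)
  data.frame(first = first, last = last,
             surface = surfaces$surface[row], class = surfaces$class[row],
             stringsAsFactors = FALSE)
}

surface_table <- function(terms) {
  if (nrow(terms) == 0L) {
    terms$surface_key <- character(0)
    terms$key_len <- integer(0)
    return(terms)
  }
  keys <- lapply(terms$surface, function(s) tolower(tokenize(s)$token))
  terms$surface_key <- vapply(keys, paste, character(1), collapse = " ")
  terms$key_len <- lengths(keys)
  terms
}

#' Tag target-term mentions in one clinical note
#'
#' Greedy longest-match, left-to-right, within sentences, over lowercased
#' tokens against the lexicon's target surfaces. Matched tokens are consumed,
#' so "bone mets" never also fires a shorter contained term. Attributes
#' default to positive / patient / present; use [resolve_context()] (or
#' [tag_corpus()], which does both) to resolve them.
#'
#' @param note A list or one-row data.frame with `patient_id`, `note_id`,
#'   `note_type`, `text`.
#' @param lexicon An `mbc_lexicon`.
#' @return A data.frame of mentions: patient_id, note_id, note_type, start,
#'   end (0-based half-open), surface (raw matched text), class, polarity,
#'   experiencer, temporality.
#' @export
tag_note <- function(note, lexicon, .sentences = NULL, .targets = NULL) {
  stopifnot(inherits(lexicon, "mbc_lexicon"))
  sents <- .sentences %||% segment_text(as.character(note$text))
  tgt <- .targets %||% surface_table(target_surfaces(lexicon))
  res <- lapply(sents, function(sent) {
    h <- match_surfaces(sent, tgt)
    if (nrow(h) == 0L) return(NULL)
    data.frame(start = sent$start[h$first], end = sent$end[h$last],
               surface = h$surface, class = h$class,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    res <- data.frame(start = integer(), end = integer(),
                      surface = character(), class = character(),
                      stringsAsFactors = FALSE)
  }
  text <- normalize_newlines(as.character(note$text))
  surf <- if (nrow(res)) substring(text, res$start + 1L, res$end)
          else character(0)
  data.frame(patient_id = rep(as.character(note$patient_id), nrow(res)),
             note_id = rep(as.character(note$note_id), nrow(res)),
             note_type = rep(as.character(note$note_type), nrow(res)),
             start = res$start, end = res$end,
             surface = surf,
             class = res$class,
             polarity = rep("positive", nrow(res)),
             experiencer = rep("patient", nrow(res)),
             temporality = rep("present", nrow(res)),
             stringsAsFactors = FALSE)
}

#' Resolve mention context: polarity, experiencer, temporality
#'
#' Scans up to `window` tokens before and after each mention within its
#' sentence. Scope terminators ("but", "however", ...) truncate the window on
#' their side. Trigger phrases are matched longest-first, so a pseudo-negation
#' phrase ("no increase in") consumes its tokens and blocks the bare negation
#' trigger it contains. Attributes are independent: a mention can be both
#' negated and attributed to a family member.
#'
#' @param mentions Mention data.frame from [tag_note()] (one note).
#' @param sentences Output of [segment_text()] on the same note text.
#' @param lexicon An `mbc_lexicon` providing context triggers.
#' @param window Token window on each side (default 6, NegEx-style).
#' @return The mentions with `polarity`, `experiencer`, `temporality` set.
#' @export
resolve_context <- function(mentions, sentences, lexicon, window = 6L,
                            .contexts = NULL) {
  stopifnot(window >= 1L)
  if (nrow(mentions) == 0L) return(mentions)
  ctx <- .contexts %||% surface_table(context_surfaces(lexicon))
  role_of <- stats::setNames(ctx$context_role, ctx$class)
  for (k in seq_len(nrow(mentions))) {
    sent <- NULL
    for (s in sentences) {
      if (nrow(s) && s$start[1] <= mentions$start[k] &&
          s$end[nrow(s)] >= mentions$end[k]) { sent <- s; break }
    }
    if (is.null(sent)) next
    a <- which(sent$start == mentions$start[k])[1]
    b <- which(sent$end == mentions$end[k])[1]
    if (is.na(a) || is.na(b)) next
    pre <- sent[seq_len(a - 1L), , drop = FALSE]
    pre <- pre[pre$end > 0, , drop = FALSE]
    if (nrow(pre) > window) pre <- pre[(nrow(pre) - window + 1L):nrow(pre), ,
                                       drop = FALSE]
    post <- if (b < nrow(sent)) sent[(b + 1L):nrow(sent), , drop = FALSE]
            else sent[0, , drop = FALSE]
    if (nrow(post) > window) post <- post[seq_len(window), , drop = FALSE]

    roles <- c(window_roles(pre, ctx, role_of, side = "pre"),
               window_roles(post, ctx, role_of, side = "post"))
    if ("negation" %in% roles) mentions$polarity[k] <- "negated"
    if ("family" %in% roles) mentions$experiencer[k] <- "family"
    if ("hypothetical" %in% roles) mentions$temporality[k] <- "hypothetical"
  }
  mentions
}

# Roles of triggers active in one side window, honoring scope terminators.
window_roles <- function(tokens, ctx, role_of, side) {
  if (nrow(tokens) == 0L) return(character(0))
  h <- match_surfaces(tokens, ctx)
  if (nrow(h) == 0L) return(character(0))
  roles <- unname(role_of[h$class])
  term <- which(roles == "scope_terminator")
  if (length(term)) {
    if (side == "pre") {
      # keep only triggers after the last terminator (closest to the mention)
      keep <- h$first > max(h$last[term])
    } else {
      keep <- h$last < min(h$first[term])
    }
    roles <- roles[keep]
  }
  setdiff(roles, c("pseudo_negation", "scope_terminator"))
}

#' Tag and context-resolve a corpus of notes
#'
#' Applies [tag_note()] and [resolve_context()] to every note. Deterministic:
#' identical input bytes give an identical mentions table. Malformed note
#' records (missing patient_id/note_id or non-character text) are skipped with
#' a warning and counted in the `skipped` attribute.
#'
#' @param notes Data.frame of notes with columns patient_id, note_id,
#'   note_type, date, text (see [read_notes_jsonl()]).
#' @param lexicon An `mbc_lexicon`.
#' @param window Context window passed to [resolve_context()].
#' @return Mentions data.frame (one row per mention) with attribute `skipped`
#'   giving the number of malformed notes dropped.
#' @export
tag_corpus <- function(notes, lexicon, window = 6L) {
  stopifnot(is.data.frame(notes))
  tgt <- surface_table(target_surfaces(lexicon))
  ctx <- surface_table(context_surfaces(lexicon))
  skipped <- 0L
  out <- vector("list", nrow(notes))
  for (i in seq_len(nrow(notes))) {
    note <- notes[i, ]
    if (is.na(note$patient_id) || is.na(note$note_id) ||
        !nzchar(as.character(note$patient_id)) ||
        !nzchar(as.character(note$note_id)) || is.na(note$text)) {
      skipped <- skipped + 1L
      next
    }
    sents <- segment_text(as.character(note$text))
    m <- tag_note(note, lexicon, .sentences = sents, .targets = tgt)
    if (nrow(m)) {
      m <- resolve_context(m, sents, lexicon, window = window,
                           .contexts = ctx)
    }
    out[[i]] <- m
  }
  if (skipped > 0L) {
    warning(skipped, " malformed note record(s) skipped")
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_mentions()
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

empty_mentions <- function() {
  data.frame(patient_id = character(), note_id = character(),
             note_type = character(), start = integer(), end = integer(),
             surface = character(), class = character(),
             polarity = character(), experiencer = character(),
             temporality = character(), stringsAsFactors = FALSE)
}

#' Read / write clinical notes as JSON Lines
#'
#' One JSON object per line with fields patient_id, note_id, note_type, date,
#' text.
#'
#' @param path File path.
#' @return `read_notes_jsonl`: a data.frame of notes.
#' @export
read_notes_jsonl <- function(path) {
  df <- jsonlite::stream_in(file(path), verbose = FALSE)
  for (col in c("patient_id", "note_id", "note_type", "date", "text")) {
    if (is.null(df[[col]])) stop("notes file missing field '", col, "'")
    df[[col]] <- as.character(df[[col]])
  }
  df
}

#' @rdname read_notes_jsonl
#' @param notes Data.frame of notes.
#' @export
write_notes_jsonl <- function(notes, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  jsonlite::stream_out(notes, con, verbose = FALSE)
  invisible(path)
}
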