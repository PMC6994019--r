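# Word classes whose positive present mentions define the distant case label:
# metastatic disease at a named distant site.
SITE_CLASSES <- c("METSBONE", "METSBRAIN", "METSLIVER", "METSLUNG")

CONTEXT_ROLES <- c("none", "negation", "family", "hypothetical",
                   "pseudo_negation", "scope_terminator")

#' Site word classes used by the distant labeling rule
#'
#' The four word classes (bone, brain, liver, lung metastasis) whose positive,
#' present, patient-experienced mentions assign a distant case label. They are
#' excluded from classifier features to avoid learning back the labeling rule.
#'
#' @return Character vector of the four class names.
#' @export
site_classes <- function() SITE_CLASSES

#' Load a term-to-concept lexicon from TSV
#'
#' Reads a tab-separated lexicon with columns `surface`, `class`, `kind`
#' (`target` or `context`) and `context_role`. Lines starting with `#` are
#' comments. Surfaces are lowercased on load; duplicate (surface, class) rows
#' are collapsed. Misspelled surfaces are kept verbatim: they reflect real
#' note text.
#'
#' @param path Path to a UTF-8 TSV file. Defaults to the bundled MBC lexicon.
#' @return An object of class `mbc_lexicon`: a list with `terms` (data.frame
#'   surface/class/kind/context_role/n_tokens), `classes` (data.frame
#'   name/kind/context_role) and `site_classes`.
#' @examples
#' lex <- load_lexicon()
#' lex
#' @export
load_lexicon <- function(path = system.file("extdata", "mbc_lexicon.tsv",
                                            package = "mbcdetect")) {
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(validate_lexicon(new_lexicon(empty_terms())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    bad <- lineno[which(nf != 4L)[1L]]
    stop("lexicon parse error at line ", bad, ": expected 4 tab-separated ",
         "fields (surface, class, kind, context_role)")
  }
  m <- do.call(rbind, fields)
  df <- data.frame(surface = trimws(m[, 1]), class = trimws(m[, 2]),
                   kind = trimws(m[, 3]), context_role = trimws(m[, 4]),
                   stringsAsFactors = FALSE)
  hdr <- df$surface == "surface" & df$class == "class"
  df <- df[!hdr, , drop = FALSE]
  lineno <- lineno[!hdr]
  df$surface <- tolower(df$surface)

  bad_kind <- !df$kind %in% c("target", "context")
  if (any(bad_kind)) {
    stop("lexicon parse error at line ", lineno[which(bad_kind)[1L]],
         ": unknown kind '", df$kind[which(bad_kind)[1L]], "'")
  }
  bad_role <- !df$context_role %in% CONTEXT_ROLES
  if (any(bad_role)) {
    stop("lexicon parse error at line ", lineno[which(bad_role)[1L]],
         ": unknown context_role '", df$context_role[which(bad_role)[1L]], "'")
  }
  df <- df[!duplicated(df[c("surface", "class")]), , drop = FALSE]
  validate_lexicon(new_lexicon(df))
}

empty_terms <- function() {
  data.frame(surface = character(), class = character(), kind = character(),
             context_role = character(), stringsAsFactors = FALSE)
}

new_lexicon <- function(terms) {
  terms$n_tokens <- vapply(terms$surface,
                           function(s) length(tokenize(s)$token), integer(1),
                           USE.NAMES = FALSE)
  classes <- unique(terms[c("class", "kind", "context_role")])
  names(classes)[1] <- "name"
  rownames(terms) <- rownames(classes) <- NULL
  structure(list(terms = terms, classes = classes,
                 site_classes = SITE_CLASSES),
            class = "mbc_lexicon")
}

validate_lexicon <- function(lex) {
  terms <- lex$terms
  cls <- lex$classes
  if (any(!nzchar(terms$surface))) stop("lexicon contains an empty surface")
  if (any(terms$n_tokens < 1L)) stop("lexicon surface tokenizes to nothing")
  bad <- cls$kind == "target" & cls$context_role != "none"
  if (any(bad)) {
    stop("target class '", cls$name[bad][1L], "' must have context_role 'none'")
  }
  bad <- cls$kind == "context" & cls$context_role == "none"
  if (any(bad)) {
    stop("context class '", cls$name[bad][1L],
         "' must declare a context_role")
  }
  if (anyDuplicated(cls$name)) {
    dup <- cls$name[duplicated(cls$name)][1L]
    stop("word class '", dup, "' declared with conflicting kind/context_role")
  }
  tgt <- terms[terms$kind == "target", , drop = FALSE]
  ncls <- tapply(tgt$class, tgt$surface, function(x) length(unique(x)))
  if (any(ncls > 1L)) {
    s <- names(ncls)[ncls > 1L][1L]
    stop("surface '", s, "' maps to multiple target classes: ",
         paste(unique(tgt$class[tgt$surface == s]), collapse = ", "))
  }
  target_names <- unique(tgt$class)
  missing_site <- setdiff(SITE_CLASSES, target_names)
  if (length(missing_site)) {
    stop("lexicon is missing site class(es) required by the labeling rule: ",
         paste(missing_site, collapse = ", "))
  }
  lex
}

#' Write a lexicon back to TSV
#'
#' Inverse of [load_lexicon()] up to row order, comments and case.
#'
#' @param lex An `mbc_lexicon`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  stopifnot(inherits(lex, "mbc_lexicon"))
  out <- lex$terms[c("surface", "class", "kind", "context_role")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.mbc_lexicon <- function(x, ...) {
  tgt <- x$terms$kind == "target"
  cat("<mbc_lexicon> ", sum(tgt), " target terms in ",
      length(unique(x$terms$class[tgt])), " classes; ",
      sum(!tgt), " context triggers\n", sep = "")
  cat("  site classes: ", paste(x$site_classes, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

target_surfaces <- function(lex) {
  lex$terms[lex$terms$kind == "target", , drop = FALSE]
}

context_surfaces <- function(lex) {
  lex$terms[lex$terms$kind == "context", , drop = FALSE]
}

target_class_names <- function(lex) {
  sort(unique(lex$terms$class[lex$terms$kind == "target"]))
}
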