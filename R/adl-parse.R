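# Tokenizer for the supported ADL dialect. Comments ("-- ...") are stripped
# from the token stream but retained per line, so the parser can attach them
# as node labels.
adl_tokenize <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0L) lines <- ""
  tok_re <- paste0(
    '"[^"]*"', "|\\.\\.|\\{|\\}|\\[|\\]|\\||;|/|\\*|=|,",
    "|[A-Za-z_][A-Za-z0-9_.:-]*|[0-9]+"
  )
  values <- character()
  tok_lines <- integer()
  comments <- rep(NA_character_, length(lines))
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    cpos <- regexpr("--", line, fixed = TRUE)
    if (cpos > 0) {
      comments[[i]] <- trimws(substring(line, cpos + 2L))
      line <- substring(line, 1L, cpos - 1L)
    }
    m <- gregexpr(tok_re, line)[[1]]
    if (m[1] != -1) {
      toks <- regmatches(line, list(m))[[1]]
      covered <- gsub("\\s+", "", paste(toks, collapse = ""))
      stripped <- gsub("\\s+", "", line)
      if (!identical(covered, stripped)) {
        stop_tiss(sprintf("line %d: unrecognized characters in '%s'", i, trimws(line)),
                  "tiss_parse_error")
      }
      values <- c(values, toks)
      tok_lines <- c(tok_lines, rep(i, length(toks)))
    } else if (nzchar(gsub("\\s+", "", line))) {
      stop_tiss(sprintf("line %d: unrecognized characters in '%s'", i, trimws(line)),
                "tiss_parse_error")
    }
  }
  list(values = values, lines = tok_lines, comments = comments)
}

# Token stream with one-symbol lookahead, carried in an environment.
new_stream <- function(toks) {
  env <- new.env(parent = emptyenv())
  env$values <- toks$values
  env$lines <- toks$lines
  env$comments <- toks$comments
  env$pos <- 1L
  env
}

st_eof <- function(st) st$pos > length(st$values)
st_peek <- function(st, k = 0L) {
  i <- st$pos + k
  if (i > length(st$values)) NA_character_ else st$values[[i]]
}
st_line <- function(st) {
  if (st_eof(st)) {
    if (length(st$lines)) st$lines[[length(st$lines)]] else 1L
  } else {
    st$lines[[st$pos]]
  }
}
st_next <- function(st) {
  if (st_eof(st)) stop_tiss("unexpected end of input (unbalanced braces?)", "tiss_parse_error")
  v <- st$values[[st$pos]]
  st$pos <- st$pos + 1L
  v
}
st_expect <- function(st, what) {
  v <- st_peek(st)
  if (is.na(v) || !identical(v, what)) {
    stop_tiss(sprintf("line %d: expected '%s', found '%s'",
                      st_line(st), what, if (is.na(v)) "end of input" else v),
              "tiss_parse_error")
  }
  st_next(st)
}
st_comment <- function(st, line) {
  cm <- st$comments[[line]]
  if (is.na(cm) || !nzchar(cm)) NULL else cm
}

parse_interval_body <- function(st, cardinality = FALSE) {
  lo <- st_next(st)
  if (!grepl("^[0-9]+$", lo)) {
    stop_tiss(sprintf("line %d: malformed interval lower bound '%s'", st_line(st), lo),
              "tiss_parse_error")
  }
  st_expect(st, "..")
  up <- st_next(st)
  upper <- if (identical(up, "*")) Inf else if (grepl("^[0-9]+$", up)) as.numeric(up) else {
    stop_tiss(sprintf("line %d: malformed interval upper bound '%s'", st_line(st), up),
              "tiss_parse_error")
  }
  ordered <- NA
  if (cardinality && identical(st_peek(st), ";")) {
    st_next(st)
    flag <- st_next(st)
    ordered <- switch(flag, ordered = TRUE, unordered = FALSE,
                      stop_tiss(sprintf("line %d: expected ordered/unordered, found '%s'",
                                        st_line(st), flag), "tiss_parse_error"))
  }
  adl_interval(as.numeric(lo), upper, ordered)
}

parse_braced_interval <- function(st, cardinality = FALSE) {
  st_expect(st, "{")
  iv <- parse_interval_body(st, cardinality)
  st_expect(st, "}")
  iv
}

parse_c_object <- function(st, types) {
  line <- st_line(st)
  rm_type <- st_next(st)
  if (!(rm_type %in% types)) {
    stop_tiss(sprintf("line %d: unregistered rm type '%s'", line, rm_type),
              "tiss_parse_error")
  }
  st_expect(st, "[")
  node_id <- st_next(st)
  if (!is_node_id(node_id)) {
    stop_tiss(sprintf("line %d: malformed node id '%s'", line, node_id), "tiss_parse_error")
  }
  st_expect(st, "]")
  occurrences <- adl_interval(1, 1)
  if (identical(st_peek(st), "occurrences")) {
    st_next(st)
    st_expect(st, "matches")
    occurrences <- parse_braced_interval(st)
  }
  st_expect(st, "matches")
  open_line <- st_line(st)
  st_expect(st, "{")
  label <- st_comment(st, open_line)
  if (identical(st_peek(st), "*")) {
    st_next(st)
    st_expect(st, "}")
    return(c_object(rm_type, node_id, occurrences, label, any = TRUE))
  }
  attributes <- list()
  while (!identical(st_peek(st), "}")) {
    attributes[[length(attributes) + 1L]] <- parse_c_attribute(st, types)
  }
  st_expect(st, "}")
  c_object(rm_type, node_id, occurrences, label, attributes)
}

parse_c_attribute <- function(st, types) {
  name <- st_next(st)
  if (!grepl("^[a-z_][a-z0-9_]*$", name)) {
    stop_tiss(sprintf("line %d: malformed attribute name '%s'", st_line(st), name),
              "tiss_parse_error")
  }
  cardinality <- NULL
  if (identical(st_peek(st), "cardinality")) {
    st_next(st)
    st_expect(st, "matches")
    cardinality <- parse_braced_interval(st, cardinality = TRUE)
  }
  st_expect(st, "matches")
  st_expect(st, "{")
  children <- list()
  while (!identical(st_peek(st), "}")) {
    children[[length(children) + 1L]] <- parse_child(st, types)
  }
  st_expect(st, "}")
  c_attribute(name, cardinality, children)
}

parse_child <- function(st, types) {
  tok <- st_peek(st)
  if (identical(tok, "allow_archetype")) return(parse_slot(st, types))
  if (!is.na(tok) && tok %in% dv_known_types()) return(parse_primitive(st))
  parse_c_object(st, types)
}

parse_primitive <- function(st) {
  rm_type <- st_next(st)
  st_expect(st, "matches")
  st_expect(st, "{")
  st_expect(st, "*")
  st_expect(st, "}")
  c_primitive(rm_type, "*")
}

parse_slot <- function(st, types) {
  st_expect(st, "allow_archetype")
  line <- st_line(st)
  rm_type <- st_next(st)
  if (!(rm_type %in% types)) {
    stop_tiss(sprintf("line %d: unregistered rm type '%s'", line, rm_type),
              "tiss_parse_error")
  }
  st_expect(st, "[")
  node_id <- st_next(st)
  if (!is_node_id(node_id)) {
    stop_tiss(sprintf("line %d: malformed node id '%s'", line, node_id), "tiss_parse_error")
  }
  st_expect(st, "]")
  occurrences <- adl_interval(0, Inf)
  if (identical(st_peek(st), "occurrences")) {
    st_next(st)
    st_expect(st, "matches")
    occurrences <- parse_braced_interval(st)
  }
  label <- st_comment(st, line)
  st_expect(st, "matches")
  st_expect(st, "{")
  st_expect(st, "include")
  st_expect(st, "archetype_id")
  st_expect(st, "/")
  st_expect(st, "value")
  st_expect(st, "matches")
  st_expect(st, "{")
  includes <- character()
  repeat {
    id <- st_next(st)
    parse_archetype_id(id) # malformed id -> parse error
    includes <- c(includes, id)
    if (identical(st_peek(st), "|")) st_next(st) else break
  }
  st_expect(st, "}")
  st_expect(st, "}")
  c_slot(rm_type, node_id, occurrences, includes, label)
}

parse_ontology <- function(st) {
  terms <- list()
  while (!st_eof(st)) {
    id <- st_next(st)
    if (!is_node_id(id)) {
      stop_tiss(sprintf("line %d: malformed node id '%s' in ontology", st_line(st), id),
                "tiss_parse_error")
    }
    st_expect(st, "=")
    text <- st_next(st)
    if (!grepl('^".*"$', text)) {
      stop_tiss(sprintf("line %d: expected a quoted term text", st_line(st)),
                "tiss_parse_error")
    }
    text <- substr(text, 2L, nchar(text) - 1L)
    descr <- text
    if (identical(st_peek(st), ";")) {
      st_next(st)
      d <- st_next(st)
      if (!grepl('^".*"$', d)) {
        stop_tiss(sprintf("line %d: expected a quoted description", st_line(st)),
                  "tiss_parse_error")
      }
      descr <- substr(d, 2L, nchar(d) - 1L)
    }
    terms[[id]] <- list(text = text, description = descr)
  }
  terms
}

#' Parse an archetype definition
#'
#' Parses the supported ADL dialect: an optional `archetype` header naming the
#' identifier, an optional `definition` keyword, one constraint tree
#' (`matches` blocks with `occurrences`, `cardinality` with an
#' ordered/unordered flag, `DV_*` leaf constraints with `{*}`,
#' `allow_archetype` slots with `|`-separated include ids, and `--` comments
#' as term labels), and an optional `ontology` section with
#' `atNNNN = "text" ; "description"` lines. Unstated occurrences default to
#' `{1..1}`. Node ids must be unique within the archetype. RM type names must
#' be registered; the registry includes the extended claim classes, so
#' `INSTITUTIONAL_CLAIM`-rooted definitions parse.
#'
#' @param text ADL source text.
#' @param id optional archetype id for a headerless definition section.
#' @param types registered rm type names.
#' @return an [archetype_definition()].
#' @export
parse_archetype <- function(text, id = NULL, types = rm_known_types()) {
  st <- new_stream(adl_tokenize(text))
  if (identical(st_peek(st), "archetype")) {
    st_next(st)
    id <- parse_archetype_id(st_next(st))
  }
  if (identical(st_peek(st), "definition")) st_next(st)
  root <- parse_c_object(st, types)
  terms <- NULL
  if (identical(st_peek(st), "ontology")) {
    st_next(st)
    terms <- parse_ontology(st)
  }
  if (!st_eof(st)) {
    stop_tiss(sprintf("line %d: trailing content after the definition ('%s')",
                      st_line(st), st_peek(st)), "tiss_parse_error")
  }
  ids <- constraint_node_ids(root)
  if (anyDuplicated(ids)) {
    stop_tiss(sprintf("duplicate node id(s): %s",
                      paste(unique(ids[duplicated(ids)]), collapse = ", ")),
              "tiss_parse_error")
  }
  if (is.null(terms)) {
    def <- archetype_definition(id, root)
  } else {
    # ontology text wins over comment labels for term definitions
    def <- archetype_definition(id, root, terms)
  }
  def
}

#' @rdname parse_archetype
#' @param path path of a `.adl` file, UTF-8.
#' @export
read_archetype <- function(path, types = rm_known_types()) {
  parse_archetype(paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                        collapse = "\n"),
                  types = types)
}
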