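# Canonical pretty-printer for the supported ADL dialect. parse() of the
# output structurally equals the input; printing a parsed fixture reaches a
# fixed point after one canonicalization. Occurrences are omitted exactly
# when they are the default {1..1}.
print_c_object <- function(node, indent) {
  pad <- strrep("    ", indent)
  cm <- if (!is.null(node$label)) paste0("    -- ", node$label) else ""
  if (node$kind == "slot") {
    head <- sprintf("%sallow_archetype %s[%s] occurrences matches {%s} matches {%s",
                    pad, node$rm_type, node$node_id, format(node$occurrences), cm)
    inc_pad <- strrep("    ", indent + 2L)
    incs <- paste0(inc_pad, node$includes,
                   c(rep(" |", length(node$includes) - 1L), ""))
    return(c(head,
             paste0(strrep("    ", indent + 1L), "include archetype_id/value matches {"),
             incs,
             paste0(strrep("    ", indent + 1L), "}"),
             paste0(pad, "}")))
  }
  occ <- if (node$occurrences$lower == 1 && node$occurrences$upper == 1) "" else {
    sprintf(" occurrences matches {%s}", format(node$occurrences))
  }
  head <- sprintf("%s%s[%s]%s matches {", pad, node$rm_type, node$node_id, occ)
  if (isTRUE(node$any)) return(paste0(head, "*}", cm))
  head <- paste0(head, cm)
  body <- unlist(lapply(node$attributes, print_c_attribute, indent = indent + 1L))
  c(head, body, paste0(pad, "}"))
}

print_c_attribute <- function(attr, indent) {
  pad <- strrep("    ", indent)
  card <- if (!is.null(attr$cardinality)) {
    sprintf(" cardinality matches {%s}", format(attr$cardinality))
  } else ""
  head <- sprintf("%s%s%s matches {", pad, attr$name, card)
  body <- unlist(lapply(attr$children, function(ch) {
    if (ch$kind == "primitive") {
      sprintf("%s%s matches {*}", strrep("    ", indent + 1L), ch$rm_type)
    } else {
      print_c_object(ch, indent + 1L)
    }
  }))
  c(head, body, paste0(pad, "}"))
}

#' Serialize an archetype definition to ADL text
#'
#' Emits the canonical pretty-printed dialect: an `archetype` header when the
#' definition has an identifier, the constraint tree with labels as trailing
#' `--` comments, and an `ontology` section when term definitions exist.
#' `parse_archetype(serialize_archetype(d))` structurally equals `d`.
#'
#' @param def an [archetype_definition()].
#' @return a single string of ADL source.
#' @export
serialize_archetype <- function(def) {
  out <- character()
  if (!is.null(def$id)) {
    out <- c(out, "archetype", paste0("    ", format(def$id)), "")
  }
  out <- c(out, "definition", print_c_object(def$root, 1L))
  if (length(def$term_definitions)) {
    out <- c(out, "", "ontology")
    ids <- names(def$term_definitions)
    for (id in ids) {
      td <- def$term_definitions[[id]]
      line <- sprintf('    %s = "%s"', id, td$text)
      if (!identical(td$description, td$text)) {
        line <- sprintf('%s ; "%s"', line, td$description)
      }
      out <- c(out, line)
    }
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' @rdname serialize_archetype
#' @param path output file path (UTF-8).
#' @export
write_archetype <- function(def, path) {
  writeLines(serialize_archetype(def), path, useBytes = TRUE, sep = "")
  invisible(path)
}

#' Token-level comparison of ADL sources
#'
#' `adl_tokens()` returns the token stream of an ADL source with comments and
#' whitespace removed; `adl_token_diff()` compares two sources token by
#' token, restricted to their definition sections (header and ontology are
#' ignored), and returns a character vector of differences — empty when the
#' definitions are token-identical.
#'
#' @param text,a,b ADL source strings.
#' @return `adl_tokens()`: character vector; `adl_token_diff()`: character
#'   vector of difference descriptions.
#' @export
adl_tokens <- function(text) {
  adl_tokenize(text)$values
}

definition_tokens <- function(text) {
  toks <- adl_tokens(text)
  if (length(toks) && identical(toks[[1]], "archetype")) toks <- toks[-(1:2)]
  if (length(toks) && identical(toks[[1]], "definition")) toks <- toks[-1]
  ont <- which(toks == "ontology")
  if (length(ont)) toks <- toks[seq_len(ont[[1]] - 1L)]
  toks
}

#' @rdname adl_tokens
#' @export
adl_token_diff <- function(a, b) {
  ta <- definition_tokens(a)
  tb <- definition_tokens(b)
  out <- character()
  n <- max(length(ta), length(tb))
  for (i in seq_len(n)) {
    va <- if (i <= length(ta)) ta[[i]] else "<end>"
    vb <- if (i <= length(tb)) tb[[i]] else "<end>"
    if (!identical(va, vb)) {
      out <- c(out, sprintf("token %d: '%s' vs '%s'", i, va, vb))
    }
  }
  out
}
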