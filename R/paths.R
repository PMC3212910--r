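#' Instance paths
#'
#' Paths address nodes inside an instance tree with the archetype-path syntax
#' `/attribute[atNNNN]`, optionally with a 0-based sibling index in a second
#' bracket (`/items[at0002][1]`) when several siblings share a node id. At a
#' filled archetype slot, the bracket holds the filler's archetype identifier
#' instead of a node id (`/content[openEHR-EHR-ADMIN_ENTRY.authorization.v1]`),
#' since every archetype root reuses `at0000`. The empty string is the
#' identity path. `parse_instance_path()` and the `format()` method round-trip
#' every canonical path string.
#'
#' @param s a path string.
#' @return `parse_instance_path()` returns a `tiss_path` object (a list of
#'   segments with `attr`, `node_id`, `index`).
#' @examples
#' p <- parse_instance_path("/data[at0001]/items[at0004]")
#' format(p)
#' @export
parse_instance_path <- function(s) {
  assert_string(s, "path")
  if (identical(s, "")) return(structure(list(), class = "tiss_path"))
  seg_re <- "/([A-Za-z_][A-Za-z0-9_]*)(\\[([^]/[]+)\\])?(\\[([0-9]+)\\])?"
  m <- gregexpr(seg_re, s)[[1]]
  pieces <- regmatches(s, gregexpr(seg_re, s))[[1]]
  if (length(pieces) == 0L || paste(pieces, collapse = "") != s) {
    covered <- paste(pieces, collapse = "")
    bad <- substr(s, nchar(covered) + 1L, nchar(s))
    stop_tiss(sprintf("malformed path near '%s' in '%s'", bad, s), "tiss_parse_error")
  }
  segs <- lapply(pieces, function(p) {
    mm <- regmatches(p, regexec(seg_re, p))[[1]]
    node_id <- if (nzchar(mm[4])) mm[4] else NULL
    if (!is.null(node_id) && !grepl("\\.", node_id)) {
      if (!is_node_id(node_id)) {
        stop_tiss(sprintf("malformed node id in path segment '%s'", p), "tiss_parse_error")
      }
    }
    list(attr = mm[2], node_id = node_id,
         index = if (nzchar(mm[6])) as.integer(mm[6]) else NULL)
  })
  structure(segs, class = "tiss_path")
}

#' @export
format.tiss_path <- function(x, ...) {
  if (length(x) == 0L) return("")
  paste(vapply(x, function(seg) {
    out <- paste0("/", seg$attr)
    if (!is.null(seg$node_id)) out <- paste0(out, "[", seg$node_id, "]")
    if (!is.null(seg$index)) out <- paste0(out, "[", seg$index, "]")
    out
  }, character(1)), collapse = "")
}

#' @export
print.tiss_path <- function(x, ...) {
  cat("<path>", if (length(x)) format(x) else "(identity)", "\n")
  invisible(x)
}

#' @export
as.character.tiss_path <- function(x, ...) format(x)

path_append <- function(path_str, attr, id) {
  paste0(path_str, "/", attr, "[", id, "]")
}

#' Resolve an instance path
#'
#' Returns every node in `root` matched by `path`, in document order. A
#' node-id segment must match the node's `archetype_node_id`; an archetype-id
#' segment (bracket content containing a dot) must match the node's
#' `archetype_id`. An unmatched path yields an empty list, not an error.
#'
#' @param root a locatable node.
#' @param path a `tiss_path` or a path string.
#' @return list of matched nodes.
#' @examples
#' # an element "submission Date" at at0004 under the entry's data tree:
#' # resolve_path(entry, "/data[at0001]/items[at0004]")
#' @export
resolve_path <- function(root, path) {
  if (!is_locatable(root)) stop_tiss("root must be a locatable node", "tiss_type_error")
  if (is.character(path)) path <- parse_instance_path(path)
  nodes <- list(root)
  for (seg in path) {
    nxt <- list()
    for (node in nodes) {
      kids <- child_nodes(node, seg$attr)
      if (!is.null(seg$node_id)) {
        if (grepl("\\.", seg$node_id)) {
          kids <- Filter(function(k) identical(k$archetype_id, seg$node_id), kids)
        } else {
          kids <- Filter(function(k) identical(k$node_id, seg$node_id), kids)
        }
      }
      if (!is.null(seg$index)) {
        kids <- if (seg$index < length(kids)) kids[seg$index + 1L] else list()
      }
      nxt <- c(nxt, kids)
    }
    nodes <- nxt
    if (length(nodes) == 0L) break
  }
  nodes
}

#' Collect the links of an instance tree
#'
#' Walks the tree in document order and returns every link together with the
#' path of the node that owns it. Links support associations the flat form
#' model cannot express, e.g. one performed service related to two diagnoses.
#'
#' @param root a locatable node.
#' @return a list of `list(path =, link =)` pairs in document order.
#' @export
collect_links <- function(root) {
  out <- list()
  walk <- function(node, path) {
    for (lk in node$links) out[[length(out) + 1L]] <<- list(path = path, link = lk)
    for (f in tiss_child_fields(node$rm_type)) {
      kids <- child_nodes(node, f)
      for (k in kids) {
        id <- if (!is.null(k$archetype_id) && identical(k$node_id, "at0000")) {
          k$archetype_id
        } else {
          k$node_id
        }
        walk(k, path_append(path, f, id))
      }
    }
  }
  walk(root, "")
  out
}
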