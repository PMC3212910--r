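#' Validation findings and reports
#'
#' Validation never throws on bad data: every violated constraint becomes a
#' finding with the instance path where it occurred, a rule name, a detail
#' message and a severity. A report is valid iff it contains no ERROR
#' finding. Findings are emitted in canonical path order, so two runs over
#' the same instance are byte-identical.
#'
#' @param path instance path string of the offending node.
#' @param rule rule name, one of `RM_TYPE_MISMATCH`, `NODE_ID_UNKNOWN`,
#'   `OCCURRENCES_EXCEEDED`, `OCCURRENCES_UNMET`, `CARDINALITY_VIOLATION`,
#'   `VALUE_TYPE_MISMATCH`, `SLOT_INCLUDE_VIOLATION`, `SLOT_FILLER_INVALID`,
#'   `CODE_BINDING_VIOLATION` (plus the lifecycle rules of
#'   [validate_history()]).
#' @param detail human-readable description.
#' @param severity `"ERROR"` or `"WARNING"`.
#' @param findings list of findings.
#' @return a `validation_finding` / `validation_report` object.
#' @export
validation_finding <- function(path, rule, detail, severity = "ERROR") {
  if (!severity %in% c("ERROR", "WARNING")) {
    stop_tiss("severity must be ERROR or WARNING", "tiss_value_error")
  }
  structure(list(path = path, rule = rule, detail = detail, severity = severity),
            class = "tiss_validation_finding")
}

#' @rdname validation_finding
#' @export
validation_report <- function(findings = list()) {
  ord <- order(vapply(findings, `[[`, character(1), "path"),
               vapply(findings, `[[`, character(1), "rule"),
               method = "radix")
  findings <- findings[ord]
  valid <- !any(vapply(findings, function(f) identical(f$severity, "ERROR"), logical(1)))
  structure(list(findings = findings, valid = valid), class = "tiss_validation_report")
}

#' @export
print.tiss_validation_report <- function(x, ...) {
  cat(sprintf("<validation report> %s, %d finding(s)\n",
              if (x$valid) "valid" else "INVALID", length(x$findings)))
  for (f in x$findings) {
    cat(sprintf("  [%s] %s at %s: %s\n", f$severity, f$rule,
                if (nzchar(f$path)) f$path else "/", f$detail))
  }
  invisible(x)
}

#' @export
as.data.frame.tiss_validation_report <- function(x, ...) {
  data.frame(
    path = vapply(x$findings, `[[`, character(1), "path"),
    rule = vapply(x$findings, `[[`, character(1), "rule"),
    severity = vapply(x$findings, `[[`, character(1), "severity"),
    detail = vapply(x$findings, `[[`, character(1), "detail"),
    stringsAsFactors = FALSE
  )
}

#' @rdname validation_finding
#' @param report a validation report.
#' @export
report_to_json <- function(report) {
  jsonlite::toJSON(list(valid = report$valid,
                        findings = lapply(report$findings, unclass)),
                   auto_unbox = TRUE, pretty = TRUE)
}

#' Check a data value against a primitive constraint
#'
#' The `{*}` pattern accepts any value of the constrained value type; a value
#' of the wrong variant yields a `VALUE_TYPE_MISMATCH` finding. Coded text
#' satisfies a plain `DV_TEXT` constraint.
#'
#' @param value a data value.
#' @param constraint a primitive constraint (from a parsed archetype).
#' @param path path reported in the finding.
#' @return `NULL` when the value conforms, otherwise a [validation_finding()].
#' @export
check_value_constraint <- function(value, constraint, path = "/value") {
  kind <- dv_kind(value)
  ok <- identical(kind, constraint$rm_type) ||
    (identical(constraint$rm_type, "DV_TEXT") && kind == "DV_CODED_TEXT")
  if (ok) return(NULL)
  validation_finding(path, "VALUE_TYPE_MISMATCH",
                     sprintf("expected %s, found %s", constraint$rm_type, kind))
}

# -- core recursive walk -----------------------------------------------------

instance_bracket_id <- function(node) {
  if (!is.null(node$archetype_id) && identical(node$node_id, "at0000")) {
    node$archetype_id
  } else {
    node$node_id
  }
}

# Match one instance child against the candidate constraints of an attribute.
# Returns the index into `cands` or NA. Fillers (flattened slots) match by
# archetype id; plain object constraints by node id; slots by rm-type
# compatibility for archetype-rooted children.
match_child <- function(child, cands, repo) {
  for (j in seq_along(cands)) {
    cn <- cands[[j]]
    if (cn$kind == "object" && !is.null(cn$filler_id)) {
      if (!is.null(child$archetype_id) && !is.null(repo) &&
          same_archetype(repo, child$archetype_id, cn$filler_id)) {
        return(j)
      }
    } else if (cn$kind == "object") {
      if (identical(child$node_id, cn$node_id) && is.null(child$archetype_id)) return(j)
      if (identical(child$node_id, cn$node_id) && !is.null(child$archetype_id) &&
          !identical(child$node_id, "at0000")) {
        return(j)
      }
    }
  }
  # slots last, so fillers take precedence in flattened trees
  for (j in seq_along(cands)) {
    cn <- cands[[j]]
    if (cn$kind == "slot" && !is.null(child$archetype_id) &&
        is_rm_subtype(child$rm_type, cn$rm_type)) {
      return(j)
    }
  }
  NA_integer_
}

validate_object <- function(node, cons, path, repo, findings) {
  add <- function(p, rule, detail, severity = "ERROR") {
    findings[[length(findings) + 1L]] <<- validation_finding(p, rule, detail, severity)
  }
  if (!is_rm_subtype(node$rm_type, cons$rm_type)) {
    add(path, "RM_TYPE_MISMATCH",
        sprintf("expected %s (or a subtype), found %s", cons$rm_type, node$rm_type))
    return(findings)
  }
  if (isTRUE(cons$any)) return(findings)
  if (!is.null(cons$binding) && identical(node$rm_type, "ELEMENT") &&
      !is.null(node$value) && dv_kind(node$value) == "DV_CODED_TEXT") {
    if (!(node$value$code %in% cons$binding$codes)) {
      add(paste0(path, "/value"), "CODE_BINDING_VIOLATION",
          sprintf("code '%s' is not in the %s binding [%s]", node$value$code,
                  cons$binding$terminology_id,
                  paste(cons$binding$codes, collapse = ", ")))
    }
  }
  for (attr in cons$attributes) {
    if (identical(attr$name, "value") && identical(node$rm_type, "ELEMENT")) {
      prims <- Filter(function(ch) ch$kind == "primitive", attr$children)
      if (!is.null(node$value) && length(prims)) {
        hits <- lapply(prims, function(p) {
          check_value_constraint(node$value, p, paste0(path, "/value"))
        })
        if (!any(vapply(hits, is.null, logical(1)))) {
          findings[[length(findings) + 1L]] <- hits[[1L]]
        }
      }
      next
    }
    children <- child_nodes(node, attr$name)
    if (!is.null(attr$cardinality)) {
      n <- length(children)
      if (n < attr$cardinality$lower || n > attr$cardinality$upper) {
        add(paste0(path, "/", attr$name), "CARDINALITY_VIOLATION",
            sprintf("%d child(ren) under '%s', cardinality {%s}", n, attr$name,
                    format(attr$cardinality)))
      }
    }
    counts <- integer(length(attr$children))
    matched <- rep(NA_integer_, length(children))
    for (i in seq_along(children)) {
      j <- match_child(children[[i]], attr$children, repo)
      matched[[i]] <- j
      if (!is.na(j)) counts[[j]] <- counts[[j]] + 1L
    }
    for (i in seq_along(children)) {
      child <- children[[i]]
      cpath <- path_append(path, attr$name, instance_bracket_id(child))
      j <- matched[[i]]
      if (is.na(j)) {
        add(cpath, "NODE_ID_UNKNOWN",
            sprintf("no constraint for node '%s' under '%s'",
                    instance_bracket_id(child), attr$name))
        next
      }
      cn <- attr$children[[j]]
      if (cn$kind == "slot") {
        inc_ok <- any(vapply(cn$includes, function(id) {
          if (is.null(repo)) identical(normalize_archetype_id(id),
                                       normalize_archetype_id(child$archetype_id))
          else same_archetype(repo, id, child$archetype_id)
        }, logical(1)))
        if (!inc_ok) {
          add(cpath, "SLOT_INCLUDE_VIOLATION",
              sprintf("archetype '%s' is not included by slot %s [%s]",
                      child$archetype_id, cn$node_id,
                      paste(cn$includes, collapse = " | ")))
          next
        }
        filler <- if (!is.null(repo)) repo_get(repo, child$archetype_id) else NULL
        if (is.null(filler)) {
          add(cpath, "SLOT_FILLER_INVALID",
              sprintf("filler archetype '%s' is not in the repository",
                      child$archetype_id))
          next
        }
        findings <- validate_object(child, filler$root, cpath, repo, findings)
      } else {
        findings <- validate_object(child, cn, cpath, repo, findings)
      }
    }
    # occurrence checks, one finding per constrained node
    for (j in seq_along(attr$children)) {
      cn <- attr$children[[j]]
      if (cn$kind == "primitive") next
      occ <- cn$occurrences
      id_for_path <- if (cn$kind == "object" && !is.null(cn$filler_id)) {
        cn$filler_id
      } else {
        cn$node_id
      }
      npath <- path_append(path, attr$name, id_for_path)
      if (counts[[j]] > occ$upper) {
        add(npath, "OCCURRENCES_EXCEEDED",
            sprintf("%d occurrence(s) of node %s, allowed {%s}", counts[[j]],
                    id_for_path, format(occ)))
      }
      if (counts[[j]] < occ$lower) {
        add(npath, "OCCURRENCES_UNMET",
            sprintf("%d occurrence(s) of node %s, required {%s}", counts[[j]],
                    id_for_path, format(occ)))
      }
    }
  }
  findings
}

#' Validate an instance tree against an archetype
#'
#' Walks the instance and the archetype's constraint tree in parallel and
#' enumerates every violated constraint as a finding with its instance path.
#' Reference-model subtype substitutability holds (an institutional claim
#' entry satisfies an `ADMIN_ENTRY` constraint). Filled slots are checked
#' against the slot's include list (alias-aware) and the filler subtree is
#' then validated recursively against its own archetype from the repository;
#' a filler whose archetype is absent from the repository yields a
#' `SLOT_FILLER_INVALID` finding, not an exception. Attributes the archetype
#' does not constrain (such as links) are permitted: the archetype
#' constrains, it does not enumerate.
#'
#' @param node a locatable instance node.
#' @param archetype an [archetype_definition()].
#' @param repo an [archetype_repository()] holding slot-filler archetypes.
#' @return a [validation_report()].
#' @export
validate_instance <- function(node, archetype, repo = NULL) {
  if (!is_locatable(node)) stop_tiss("node must be a locatable", "tiss_type_error")
  if (!inherits(archetype, "tiss_archetype_definition")) {
    stop_tiss("archetype must be an archetype definition", "tiss_type_error")
  }
  validation_report(validate_object(node, archetype$root, "", repo, list()))
}
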