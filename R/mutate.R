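# Single-violation mutant generator: produces a minimally mutated copy of a
# valid composition guaranteed to trigger one named validation rule at a
# known path, for validator soundness testing.

#' @export
#' @rdname mutate_for_violation
mutation_skip <- function(reason) {
  structure(list(reason = reason), class = "tiss_mutation_skip")
}

#' @export
#' @rdname mutate_for_violation
is_mutation_skip <- function(x) inherits(x, "tiss_mutation_skip")

# Parallel walk over the instance and the flattened constraint tree,
# mirroring the validator's matching; collects (path, instance node,
# constraint) triples in document order.
instance_constraint_pairs <- function(node, cons, repo, path = "") {
  out <- list(list(path = path, node = node, cons = cons))
  if (cons$kind != "object" || isTRUE(cons$any)) return(out)
  for (attr in cons$attributes) {
    if (identical(attr$name, "value")) next
    children <- child_nodes(node, attr$name)
    for (child in children) {
      j <- match_child(child, attr$children, repo)
      if (is.na(j)) next
      cn <- attr$children[[j]]
      if (cn$kind == "slot") next
      cpath <- path_append(path, attr$name, instance_bracket_id(child))
      out <- c(out, instance_constraint_pairs(child, cn, repo, cpath))
    }
  }
  out
}

# Structural modification at a path: fn is applied to the node addressed by
# the segments; ancestors are rebuilt (R copy semantics keep the original
# intact).
tree_modify <- function(node, segs, fn) {
  if (length(segs) == 0L) return(fn(node))
  seg <- segs[[1L]]
  kids <- child_nodes(node, seg$attr)
  hit <- 0L
  for (i in seq_along(kids)) {
    k <- kids[[i]]
    id <- instance_bracket_id(k)
    if (is.null(seg$node_id) || identical(id, seg$node_id)) {
      if (!is.null(seg$index) && hit != seg$index) {
        hit <- hit + 1L
        next
      }
      kids[[i]] <- tree_modify(k, segs[-1L], fn)
      if (is_locatable(node[[seg$attr]])) {
        node[[seg$attr]] <- kids[[i]]
      } else {
        node[[seg$attr]] <- kids
      }
      return(node)
    }
  }
  stop_tiss(sprintf("path segment /%s[%s] not found", seg$attr,
                    seg$node_id %||% ""), "tiss_value_error")
}

set_children <- function(parent, attr, kids) {
  if (attr %in% c("data", "item") && length(kids) == 1L) {
    parent[[attr]] <- kids[[1L]]
  } else {
    parent[[attr]] <- kids
  }
  parent
}

path_parent <- function(path) {
  segs <- parse_instance_path(path)
  list(parent = structure(segs[-length(segs)], class = "tiss_path"),
       last = segs[[length(segs)]])
}

#' Mutate a valid composition to violate one rule
#'
#' Returns a minimally mutated copy of `comp` guaranteed to trigger the named
#' validation rule at the returned path under
#' [validate_against_template()], together with the expected finding; the
#' original composition is never modified. When the rule cannot be triggered
#' on this composition (e.g. `SLOT_FILLER_INVALID`, which requires a
#' repository gap rather than an instance defect), an explicit
#' [mutation_skip()] signal is returned instead.
#'
#' @param comp a valid composition generated for `template`.
#' @param rule one of `OCCURRENCES_EXCEEDED`, `OCCURRENCES_UNMET`,
#'   `NODE_ID_UNKNOWN`, `RM_TYPE_MISMATCH`, `VALUE_TYPE_MISMATCH`,
#'   `CARDINALITY_VIOLATION`, `SLOT_INCLUDE_VIOLATION`, `SLOT_FILLER_INVALID`,
#'   `CODE_BINDING_VIOLATION`.
#' @param opt the operational template the composition instantiates.
#' @param repo the archetype repository.
#' @return `list(composition =, expected =)` with `expected` a
#'   [validation_finding()], or a [mutation_skip()].
#' @export
mutate_for_violation <- function(comp, rule, opt, repo) {
  pairs <- instance_constraint_pairs(comp, opt$root, repo)
  find_pair <- function(pred) {
    for (p in pairs) if (isTRUE(pred(p))) return(p)
    NULL
  }

  if (rule == "OCCURRENCES_EXCEEDED") {
    p <- find_pair(function(p) {
      p$cons$kind == "object" && identical(p$cons$rm_type, "ELEMENT") &&
        is.finite(p$cons$occurrences$upper) && p$cons$occurrences$upper == 1 &&
        nzchar(p$path)
    })
    if (is.null(p)) return(mutation_skip("no {0..1} element present"))
    pp <- path_parent(p$path)
    seg <- pp$last
    mut <- tree_modify(comp, unclass(pp$parent), function(parent) {
      kids <- child_nodes(parent, seg$attr)
      idx <- which(vapply(kids, function(k) identical(instance_bracket_id(k), seg$node_id),
                          logical(1)))[1]
      set_children(parent, seg$attr, append(kids, kids[idx], after = idx))
    })
    return(list(composition = mut,
                expected = validation_finding(p$path, rule, "duplicated element")))
  }

  if (rule == "OCCURRENCES_UNMET") {
    p <- find_pair(function(p) {
      p$cons$kind == "object" && p$cons$occurrences$lower >= 1 && nzchar(p$path)
    })
    if (is.null(p)) return(mutation_skip("no mandatory node present"))
    pp <- path_parent(p$path)
    seg <- pp$last
    mut <- tree_modify(comp, unclass(pp$parent), function(parent) {
      kids <- child_nodes(parent, seg$attr)
      idx <- which(vapply(kids, function(k) identical(instance_bracket_id(k), seg$node_id),
                          logical(1)))[1]
      set_children(parent, seg$attr, kids[-idx])
    })
    return(list(composition = mut,
                expected = validation_finding(p$path, rule, "removed mandatory node")))
  }

  if (rule == "NODE_ID_UNKNOWN") {
    p <- find_pair(function(p) {
      p$cons$kind == "object" && identical(p$cons$rm_type, "ITEM_TREE")
    })
    if (is.null(p)) return(mutation_skip("no item tree present"))
    mut <- tree_modify(comp, unclass(parse_instance_path(p$path)), function(tree) {
      tree$items <- c(tree$items, list(element("bogus", "at9999", dv_text("bogus"))))
      tree
    })
    return(list(composition = mut,
                expected = validation_finding(paste0(p$path, "/items[at9999]"),
                                              rule, "inserted unknown node")))
  }

  if (rule == "RM_TYPE_MISMATCH") {
    p <- find_pair(function(p) {
      p$cons$kind == "object" && identical(p$cons$rm_type, "ITEM_TREE")
    })
    if (is.null(p)) return(mutation_skip("no item tree present"))
    mut <- tree_modify(comp, unclass(parse_instance_path(p$path)), function(tree) {
      els <- Filter(function(i) identical(i$rm_type, "ELEMENT"), tree$items)
      item_list(tree$name, tree$node_id, els)
    })
    return(list(composition = mut,
                expected = validation_finding(p$path, rule, "tree replaced by list")))
  }

  if (rule == "VALUE_TYPE_MISMATCH") {
    p <- find_pair(function(p) {
      if (!(p$cons$kind == "object" && identical(p$cons$rm_type, "ELEMENT"))) return(FALSE)
      if (is.null(p$node$value)) return(FALSE)
      kind <- "DV_TEXT"
      for (a in p$cons$attributes) {
        for (ch in a$children) if (ch$kind == "primitive") kind <- ch$rm_type
      }
      !kind %in% c("DV_TEXT", "DV_CODED_TEXT")
    })
    if (is.null(p)) return(mutation_skip("no non-text element populated"))
    mut <- tree_modify(comp, unclass(parse_instance_path(p$path)), function(el) {
      el$value <- dv_text("not of the constrained type")
      el
    })
    return(list(composition = mut,
                expected = validation_finding(paste0(p$path, "/value"), rule,
                                              "text substituted for a typed value")))
  }

  if (rule == "CARDINALITY_VIOLATION") {
    card <- NULL
    for (a in opt$root$attributes) {
      if (identical(a$name, "content") && !is.null(a$cardinality) &&
          a$cardinality$lower >= 1) {
        card <- a
      }
    }
    if (is.null(card)) return(mutation_skip("content has no lower cardinality bound"))
    mut <- comp
    mut$content <- list()
    return(list(composition = mut,
                expected = validation_finding("/content", rule, "content emptied")))
  }

  if (rule == "SLOT_INCLUDE_VIOLATION") {
    p <- find_pair(function(p) {
      p$cons$kind == "object" && identical(p$cons$rm_type, "CLUSTER") &&
        !is.null(p$cons$filler_id)
    })
    if (is.null(p)) return(mutation_skip("no filled cluster slot present"))
    foreign <- "openEHR-EHR-CLUSTER.unrelated_concept.v1"
    pp <- path_parent(p$path)
    seg <- pp$last
    mut <- tree_modify(comp, unclass(parse_instance_path(p$path)), function(cl) {
      cl$archetype_id <- foreign
      cl
    })
    new_path <- paste0(format(pp$parent), "/", seg$attr, "[", foreign, "]")
    return(list(composition = mut,
                expected = validation_finding(new_path, rule, "filler id swapped")))
  }

  if (rule == "SLOT_FILLER_INVALID") {
    return(mutation_skip(
      "requires a repository gap, not an instance defect; see validator tests"))
  }

  if (rule == "CODE_BINDING_VIOLATION") {
    p <- find_pair(function(p) {
      p$cons$kind == "object" && identical(p$cons$rm_type, "ELEMENT") &&
        !is.null(p$cons$binding) && !is.null(p$node$value) &&
        dv_kind(p$node$value) == "DV_CODED_TEXT"
    })
    if (is.null(p)) return(mutation_skip("no bound coded element populated"))
    mut <- tree_modify(comp, unclass(parse_instance_path(p$path)), function(el) {
      el$value <- dv_coded_text("ZZ-out-of-binding", el$value$terminology_id)
      el
    })
    return(list(composition = mut,
                expected = validation_finding(paste0(p$path, "/value"), rule,
                                              "code outside the binding")))
  }

  stop_tiss(sprintf("unknown mutation rule '%s'", rule), "tiss_value_error")
}

#' @rdname mutate_for_violation
#' @export
mutation_rules <- function() {
  c("OCCURRENCES_EXCEEDED", "OCCURRENCES_UNMET", "NODE_ID_UNKNOWN",
    "RM_TYPE_MISMATCH", "VALUE_TYPE_MISMATCH", "CARDINALITY_VIOLATION",
    "SLOT_INCLUDE_VIOLATION", "SLOT_FILLER_INVALID", "CODE_BINDING_VIOLATION")
}
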