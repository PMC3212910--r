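#' Template definitions
#'
#' A template combines archetypes into one concrete form: it names the root
#' composition archetype, assigns filler archetypes to slots (by flattened
#' path), excludes optional elements that are not part of the form, narrows
#' occurrences, and binds coded elements to local code lists. Exclusions may
#' only target nodes whose occurrences lower bound is 0, and occurrence
#' overrides may only narrow, never widen. Exclusion is implemented as an
#' occurrences override to `{0..0}` rather than node deletion, so provenance
#' stays total over the flattened tree.
#'
#' @param name template (form) name.
#' @param root_archetype archetype id string of the root composition archetype.
#' @param slot_fills named list: flattened slot path -> character vector of
#'   filler archetype ids.
#' @param exclusions character vector of flattened paths to exclude.
#' @param code_bindings named list: flattened element path ->
#'   `list(terminology_id =, codes =)`.
#' @param occurrence_overrides named list: flattened path -> interval string
#'   (`"0..1"`) or [adl_interval()].
#' @return a `tiss_template` object.
#' @export
template_definition <- function(name, root_archetype, slot_fills = list(),
                                exclusions = character(), code_bindings = list(),
                                occurrence_overrides = list()) {
  assert_string(name, "name")
  assert_string(root_archetype, "root_archetype")
  occurrence_overrides <- lapply(occurrence_overrides, as_interval)
  structure(list(name = name, root_archetype = root_archetype,
                 slot_fills = slot_fills, exclusions = exclusions,
                 code_bindings = code_bindings,
                 occurrence_overrides = occurrence_overrides),
            class = "tiss_template")
}

as_interval <- function(x) {
  if (inherits(x, "tiss_interval")) return(x)
  m <- regexec("^([0-9]+)\\.\\.([0-9]+|\\*)$", x)[[1]]
  p <- regmatches(x, list(m))[[1]]
  if (length(p) == 0L) {
    stop_tiss(sprintf("malformed interval '%s'", x), "tiss_parse_error")
  }
  adl_interval(as.numeric(p[2]), if (p[3] == "*") Inf else as.numeric(p[3]))
}

#' @export
print.tiss_template <- function(x, ...) {
  cat(sprintf("<template> %s\n  root: %s\n  %d slot fill(s), %d exclusion(s), %d binding(s), %d override(s)\n",
              x$name, x$root_archetype, length(x$slot_fills), length(x$exclusions),
              length(x$code_bindings), length(x$occurrence_overrides)))
  invisible(x)
}

#' Read and write template config files
#'
#' Templates are stored one per file as JSON (`*.tpl.json`) with the keys of
#' [template_definition()]; `load_template()` additionally validates the
#' definition against a repository and fails with a message listing every
#' unresolvable id or path, every exclusion of a mandatory node and every
#' widening override — not just the first.
#'
#' @param path file path.
#' @param tpl a template definition.
#' @param repo an [archetype_repository()].
#' @return `load_template()`: a validated `tiss_template`.
#' @export
write_template <- function(tpl, path) {
  obj <- list(
    name = tpl$name, root_archetype = tpl$root_archetype,
    slot_fills = tpl$slot_fills, exclusions = tpl$exclusions,
    code_bindings = tpl$code_bindings,
    occurrence_overrides = lapply(tpl$occurrence_overrides, function(iv) {
      paste0(num_to_str(iv$lower), "..",
             if (is.finite(iv$upper)) num_to_str(iv$upper) else "*")
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_template
#' @export
load_template <- function(path, repo) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  tpl <- template_definition(
    name = obj$name, root_archetype = obj$root_archetype,
    slot_fills = lapply(obj$slot_fills %||% list(), function(x) as.character(unlist(x))),
    exclusions = as.character(unlist(obj$exclusions %||% list())),
    code_bindings = lapply(obj$code_bindings %||% list(), function(b) {
      list(terminology_id = b$terminology_id, codes = as.character(unlist(b$codes)))
    }),
    occurrence_overrides = obj$occurrence_overrides %||% list()
  )
  errs <- validate_template(tpl, repo)
  if (length(errs)) {
    stop_tiss(paste0("invalid template '", tpl$name, "':\n  ",
                     paste(errs, collapse = "\n  ")), "tiss_template_error",
              problems = errs)
  }
  tpl
}

#' @rdname write_template
#' @export
validate_template <- function(tpl, repo) {
  errs <- character()
  if (is.null(repo_get(repo, tpl$root_archetype))) {
    return(sprintf("root archetype '%s' is not in the repository", tpl$root_archetype))
  }
  for (ids in tpl$slot_fills) {
    for (id in ids) {
      if (is.null(repo_get(repo, id))) {
        errs <- c(errs, sprintf("slot filler '%s' is not in the repository", id))
      }
    }
  }
  res <- tryCatch(flatten_impl(tpl, repo, collect = TRUE),
                  tiss_template_error = function(e) e)
  if (inherits(res, "tiss_template_error")) {
    errs <- c(errs, conditionMessage(res))
  } else {
    errs <- c(errs, res$errors)
  }
  unique(errs)
}

# -- flattening --------------------------------------------------------------

flatten_impl <- function(tpl, repo, collect = FALSE) {
  root_def <- repo_get(repo, tpl$root_archetype)
  env <- new.env(parent = emptyenv())
  env$errors <- character()
  env$provenance <- list()
  env$used_fills <- character()
  env$used_paths <- character()
  note <- function(msg) {
    if (collect) env$errors <- c(env$errors, msg) else {
      stop_tiss(msg, "tiss_template_error")
    }
  }

  apply_mods <- function(node, path) {
    env$used_paths <- c(env$used_paths, path)
    if (path %in% tpl$exclusions) {
      if (node$occurrences$lower > 0) {
        note(sprintf("cannot exclude mandatory node at %s (occurrences {%s})",
                     path, format(node$occurrences)))
      } else {
        node$occurrences <- adl_interval(0, 0)
        node$excluded <- TRUE
      }
    }
    ov <- tpl$occurrence_overrides[[path]]
    if (!is.null(ov)) {
      if (!interval_contains(node$occurrences, ov)) {
        note(sprintf("override {%s} at %s widens {%s}", format(ov), path,
                     format(node$occurrences)))
      } else {
        node$occurrences <- ov
      }
    }
    bind <- tpl$code_bindings[[path]]
    if (!is.null(bind)) {
      if (!identical(node$rm_type, "ELEMENT")) {
        note(sprintf("code binding at %s does not target an ELEMENT", path))
      } else {
        node$binding <- bind
      }
    }
    node
  }

  expand <- function(node, path, arch_id, stack) {
    if (node$kind == "slot") {
      fills <- tpl$slot_fills[[path]]
      env$provenance[[path]] <- list(archetype = arch_id, node_id = node$node_id)
      if (is.null(fills) || length(fills) == 0L) {
        return(list(node))
      }
      env$used_fills <- c(env$used_fills, path)
      fillers <- list()
      for (fid in fills) {
        cid <- repo_resolve_id(repo, fid)
        if (cid %in% stack) {
          note(sprintf("circular slot fill: %s", paste(c(stack, cid), collapse = " -> ")))
          next
        }
        def <- repo_get(repo, fid)
        if (is.null(def)) next # already reported by validate_template
        inc_ok <- any(vapply(node$includes, function(i) same_archetype(repo, i, fid),
                             logical(1)))
        if (!inc_ok) {
          note(sprintf("fill '%s' at %s is not permitted by the slot include list", fid, path))
          next
        }
        sub_path <- sub(paste0("\\[", node$node_id, "\\]$"), paste0("[", fid, "]"), path)
        root <- def$root
        root$filler_id <- fid
        root$occurrences <- node$occurrences
        root$slot_origin <- node$node_id
        expanded <- expand_object(root, sub_path, format(def$id), c(stack, cid))
        fillers[[length(fillers) + 1L]] <- expanded
      }
      narrowed <- node
      narrowed$includes <- fills
      return(c(fillers, list(narrowed)))
    }
    list(expand_object(node, path, arch_id, stack))
  }

  expand_object <- function(node, path, arch_id, stack) {
    node <- apply_mods(node, path)
    env$provenance[[path]] <- list(archetype = arch_id, node_id = node$node_id)
    if (length(node$attributes)) {
      node$attributes <- lapply(node$attributes, function(attr) {
        kids <- list()
        for (ch in attr$children) {
          if (ch$kind == "primitive") {
            kids[[length(kids) + 1L]] <- ch
          } else {
            cpath <- path_append(path, attr$name, ch$node_id)
            kids <- c(kids, expand(ch, cpath, arch_id, stack))
          }
        }
        attr$children <- kids
        attr
      })
    }
    node
  }

  root <- expand_object(root_def$root, "", format(root_def$id),
                        repo_resolve_id(repo, tpl$root_archetype))

  for (p in names(tpl$slot_fills)) {
    if (!(p %in% env$used_fills)) {
      note(sprintf("slot fill path '%s' does not resolve to a slot", p))
    }
  }
  for (p in tpl$exclusions) {
    if (!(p %in% env$used_paths)) {
      note(sprintf("exclusion path '%s' does not resolve", p))
    }
  }
  for (p in names(tpl$occurrence_overrides)) {
    if (!(p %in% env$used_paths)) {
      note(sprintf("override path '%s' does not resolve", p))
    }
  }
  for (p in names(tpl$code_bindings)) {
    if (!(p %in% env$used_paths)) {
      note(sprintf("code binding path '%s' does not resolve", p))
    }
  }
  list(root = root, provenance = env$provenance, errors = env$errors)
}

#' Flatten a template to an operational template
#'
#' Replaces every filled slot with the filler archetypes' constraint trees
#' (retaining a narrowed slot so that foreign fillers are still recognized
#' and rejected), applies exclusions, occurrence overrides and code bindings,
#' and records the provenance (source archetype and node id) of every
#' flattened node. Filling is recursive, so fillers' own slots may be filled
#' in turn; circular fills are an error naming the cycle. Expanding an
#' already slot-free tree is the identity.
#'
#' @param template a [template_definition()].
#' @param repo an [archetype_repository()].
#' @return a `tiss_operational_template` with fields `name`, `root`
#'   (flattened constraint tree) and `provenance`.
#' @export
flatten <- function(template, repo) {
  res <- flatten_impl(template, repo, collect = FALSE)
  structure(list(name = template$name, root = res$root,
                 root_archetype = template$root_archetype,
                 provenance = res$provenance),
            class = "tiss_operational_template")
}

#' @export
print.tiss_operational_template <- function(x, ...) {
  cat(sprintf("<operational template> %s (%d node(s))\n", x$name,
              length(x$provenance)))
  invisible(x)
}

#' Validate a composition against an operational template
#'
#' Equivalent to validating against every source archetype plus the
#' template's restrictions: exclusions surface as occurrence findings, code
#' bindings as `CODE_BINDING_VIOLATION`, and foreign slot fillers as slot
#' findings.
#'
#' @param comp a [composition()].
#' @param opt a flattened [flatten()] result.
#' @param repo the repository the template was flattened against.
#' @return a [validation_report()].
#' @export
validate_against_template <- function(comp, opt, repo) {
  fake_def <- structure(list(id = NULL, root = opt$root, term_definitions = list()),
                        class = "tiss_archetype_definition")
  validate_instance(comp, fake_def, repo)
}

#' Derive a form schema from an operational template
#'
#' One field per (non-excluded) element constraint, in document order:
#' label, flattened path, value kind, whether the field is required
#' (occurrences lower bound >= 1) and the allowed codes of its binding, if
#' any. Field order is deterministic, so two runs are byte-identical.
#'
#' @param opt an operational template.
#' @return a data frame with columns `label`, `path`, `kind`, `required`,
#'   `codes`.
#' @export
form_schema <- function(opt) {
  rows <- list()
  walk <- function(node, path) {
    if (node$kind != "object") return()
    if (identical(node$rm_type, "ELEMENT")) {
      if (node$occurrences$upper < 1) return()
      kind <- "DV_TEXT"
      for (a in node$attributes) {
        for (ch in a$children) if (ch$kind == "primitive") kind <- ch$rm_type
      }
      rows[[length(rows) + 1L]] <<- data.frame(
        label = node$label %||% "", path = path, kind = kind,
        required = node$occurrences$lower >= 1,
        codes = if (!is.null(node$binding)) paste(node$binding$codes, collapse = "|") else "",
        stringsAsFactors = FALSE
      )
      return()
    }
    if (node$occurrences$upper < 1) return()
    for (a in node$attributes) {
      for (ch in a$children) {
        if (ch$kind %in% c("object")) {
          id <- ch$filler_id %||% ch$node_id
          walk(ch, path_append(path, a$name, id))
        }
      }
    }
  }
  walk(opt$root, "")
  if (length(rows) == 0L) {
    return(data.frame(label = character(), path = character(), kind = character(),
                      required = logical(), codes = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
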