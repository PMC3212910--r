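# Canonical nested-list form of every model object. This single function
# backs structural equality, JSON serialization and XML serialization, so the
# three agree by construction. Ordering discipline: marker key first, then
# scalar fields, then structured fields (the XML reader restores attributes
# before children). NULLs and empty lists are omitted.
as_rm_list <- function(x) {
  if (is_locatable(x)) return(locatable_to_list(x))
  if (is_dv(x)) return(dv_to_list(x))
  if (is_party(x)) return(party_to_list(x))
  if (inherits(x, "tiss_participation")) return(participation_to_list(x))
  if (inherits(x, "tiss_link")) return(link_to_list(x))
  if (inherits(x, "tiss_ism_transition")) return(ism_to_list(x))
  if (inherits(x, "tiss_extract")) return(extract_to_list(x))
  stop_tiss("cannot canonicalize this object", "tiss_type_error")
}

node_list <- function(xs) lapply(xs, as_rm_list)

dv_to_list <- function(v) {
  out <- list(`_dv` = v$dv_type)
  fields <- switch(v$dv_type,
    DV_TEXT = list(value = v$value),
    DV_CODED_TEXT = list(code = v$code, terminology_id = v$terminology_id,
                         display = v$display),
    DV_DATE_TIME = list(value = v$value),
    DV_DATE = list(value = v$value),
    DV_COUNT = list(value = as.numeric(v$value)),
    DV_QUANTITY = list(magnitude = as.numeric(v$magnitude), units = v$units),
    DV_MONEY = list(amount = round(as.numeric(v$amount), 2), currency = v$currency),
    DV_IDENTIFIER = list(id = v$id, issuer = v$issuer, type = v$type)
  )
  c(out, fields)
}

party_to_list <- function(p) {
  if (p$party_type == "PARTY_SELF") return(list(`_k` = "PARTY_SELF"))
  out <- list(`_k` = "PARTY_IDENTIFIED", name = p$name)
  if (length(p$identifiers)) out$identifiers <- node_list(p$identifiers)
  out
}

participation_to_list <- function(p) {
  out <- list(`_k` = "PARTICIPATION")
  out[["function"]] <- p[["function"]]
  if (!is.null(p$mode)) out$mode <- p$mode
  out$performer <- party_to_list(p$performer)
  out
}

link_to_list <- function(l) {
  list(`_k` = "LINK", meaning = l$meaning, type = l$type, target = l$target)
}

ism_to_list <- function(i) {
  out <- list(`_k` = "ISM_TRANSITION", current_state = i$current_state)
  if (!is.null(i$careflow_step)) out$careflow_step <- i$careflow_step
  out$timestamp <- i$timestamp
  out
}

locatable_to_list <- function(x) {
  out <- list(`_rm` = x$rm_type, name = x$name, archetype_node_id = x$node_id)
  if (!is.null(x$archetype_id)) out$archetype_id <- x$archetype_id
  t <- x$rm_type
  if (t == "ELEMENT") {
    if (!is.null(x$value)) out$value <- dv_to_list(x$value)
  } else if (t %in% c("CLUSTER", "ITEM_TREE", "ITEM_LIST", "SECTION")) {
    if (length(x$items)) out$items <- node_list(x$items)
  } else if (t == "ITEM_TABLE") {
    if (length(x$rows)) out$rows <- node_list(x$rows)
  } else if (t == "ITEM_SINGLE") {
    out$item <- locatable_to_list(x$item)
  } else if (t == "COMPOSITION") {
    if (!is.null(x$template)) out$template <- x$template
    out$context_start_time <- x$context_start_time
    out$composer <- party_to_list(x$composer)
    if (length(x$content)) out$content <- node_list(x$content)
    if (!is.null(x$ism_transition)) out$ism_transition <- ism_to_list(x$ism_transition)
    if (length(x$lifecycle)) out$lifecycle <- node_list(x$lifecycle)
  } else if (is_rm_subtype(t, "ENTRY")) {
    for (f in c("submission_id", "submission_date", "original_submission",
                "billing_date", "authorization_id", "validity_start",
                "validity_end", "complements")) {
      if (!is.null(x[[f]])) out[[f]] <- x[[f]]
    }
    if (!is.null(x$is_response)) out$is_response <- x$is_response
    out$subject <- party_to_list(x$subject)
    if (!is.null(x$provider)) out$provider <- party_to_list(x$provider)
    for (f in c("submitter", "submittee", "performer", "requester")) {
      if (!is.null(x[[f]])) out[[f]] <- party_to_list(x[[f]])
    }
    if (length(x$other_participations)) {
      out$other_participations <- node_list(x$other_participations)
    }
    if (!is.null(x$participants) && length(x$participants)) {
      out$participants <- node_list(x$participants)
    }
    out$data <- locatable_to_list(x$data)
  } else {
    stop_tiss(sprintf("cannot canonicalize rm type %s", t), "tiss_type_error")
  }
  if (length(x$links)) out$links <- node_list(x$links)
  out
}

extract_to_list <- function(e) {
  list(
    `_k` = "EXTRACT", extract_id = e$extract_id, created_at = e$created_at,
    source_org = party_to_list(e$source_org), target_org = party_to_list(e$target_org),
    items = lapply(e$items, function(it) {
      list(`_k` = "EXTRACT_ITEM", subject = party_to_list(it$subject),
           compositions = node_list(it$compositions))
    })
  )
}

#' Structural equality of instance trees
#'
#' Two trees are structurally equal iff they agree in reference-model type,
#' node ids, names, child order and data values, with values compared after
#' canonicalization: monetary amounts as parsed decimals (`"1,200.00"` equals
#' `"1200.00"`) and timestamps in canonical ISO-8601 form. This is an
#' equivalence relation over instance trees.
#'
#' @param a,b locatable nodes (or extracts).
#' @return logical scalar.
#' @export
structural_equals <- function(a, b) {
  identical(as_rm_list(a), as_rm_list(b))
}
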