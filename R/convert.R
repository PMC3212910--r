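# Fixed at-code layouts of the four plain-RM administrative archetypes.
# The institutional claim follows the published listing exactly (submission ID
# and original submission repeatable, slot at at0015); the others follow the
# archetype inventory with codes assigned in row order.
admin_layouts <- function() {
  list(
    professional_claim = c(
      at0002 = "original submission", at0003 = "submission ID",
      at0004 = "submission date", at0005 = "validity", at0006 = "billing date",
      at0007 = "type of claim", at0008 = "type of encounter",
      at0009 = "date of encounter", at0010 = "discharge reason",
      at0011 = "further action", at0012 = "status", at0013 = "comments"),
    institutional_claim = c(
      at0002 = "submission ID", at0003 = "original submission",
      at0004 = "submission Date", at0005 = "type of encounter",
      at0006 = "date of encounter", at0007 = "type of claim",
      at0008 = "billing date", at0009 = "status", at0010 = "discharge reason",
      at0011 = "further action", at0012 = "comments"),
    authorization = c(
      at0002 = "original submission", at0003 = "submission ID",
      at0004 = "submission date", at0005 = "validity",
      at0006 = "authorization date", at0007 = "authorization number",
      at0008 = "type of encounter", at0009 = "date of encounter",
      at0010 = "status", at0011 = "comments"),
    authorization_request = c(
      at0002 = "submission ID", at0003 = "submission date", at0004 = "status",
      at0005 = "type of encounter", at0006 = "date of encounter",
      at0007 = "comments")
  )
}

archetype_concept <- function(id) sub("^.*\\.([A-Za-z0-9_]+)\\.v[0-9]+$", "\\1", id)

admin_claim_concepts <- function() {
  c("professional_claim", "institutional_claim", "authorization", "authorization_request")
}

find_claim_entry <- function(comp, extended = FALSE) {
  for (i in seq_along(comp$content)) {
    e <- comp$content[[i]]
    if (extended && inherits(e, "tiss_submission")) return(i)
    if (!extended && identical(e$rm_type, "ADMIN_ENTRY") &&
        !is.null(e$archetype_id) &&
        archetype_concept(e$archetype_id) %in% admin_claim_concepts()) {
      return(i)
    }
  }
  NA_integer_
}

dv_string <- function(v) {
  if (is.null(v)) return(NA_character_)
  switch(dv_kind(v),
    DV_TEXT = v$value, DV_DATE = v$value, DV_DATE_TIME = v$value,
    DV_CODED_TEXT = v$code,
    format(v))
}

# Which element labels the extended RM absorbs, per source archetype.
conversion_mapped_labels <- function(concept) {
  base <- c("submission id", "original submission", "submission date",
            "billing date", "status")
  if (identical(concept, "authorization")) {
    base <- c(base, "validity", "authorization number")
  }
  base
}

take_participation <- function(parts, func) {
  idx <- which(vapply(parts, function(p) identical(p[["function"]], func), logical(1)))
  if (length(idx) == 0L) return(list(party = NULL, rest = parts))
  list(party = parts[[idx[1L]]]$performer, rest = parts[-idx[1L]])
}

#' Convert between plain-RM and extended-RM claim compositions
#'
#' The extended reference model absorbs into class attributes the header
#' elements every submission repeats — submission id and date, original
#' submission, billing date — and moves the status element into the
#' composition's ISM transition. `convert_base_to_extended()` performs that
#' move on a composition whose administrative entry conforms to one of the
#' four plain-RM claim archetypes, choosing the target class from the source
#' archetype (professional/institutional claim, authorization, authorization
#' request); for authorizations the validity and authorization-number
#' elements become the `validity` and `authorization_id` attributes and the
#' entry is marked as a response iff an authorization number is present.
#' Submitter and payer are taken from the entry's participations (functions
#' `"submitter"` and `"payer"`); the professional-claim performer and the
#' authorization requester come from the entry's `provider`; the remaining
#' `"professional"` participations of an institutional claim become its
#' participant list. All remaining elements are preserved verbatim, so
#' `convert_extended_to_base()` is an exact inverse and the round trip is the
#' identity under [structural_equals()] for generator-canonical claims.
#'
#' @param comp a [composition()].
#' @return the converted composition; inputs are never mutated.
#' @export
convert_base_to_extended <- function(comp) {
  i <- find_claim_entry(comp, extended = FALSE)
  if (is.na(i)) {
    stop_tiss("composition carries no admin entry of a known claim archetype",
              "tiss_conversion_error")
  }
  entry <- comp$content[[i]]
  concept <- archetype_concept(entry$archetype_id)
  mapped_labels <- conversion_mapped_labels(concept)

  taken <- list()
  residual <- list()
  for (it in entry$data$items) {
    lab <- tolower(it$name)
    if (identical(it$rm_type, "ELEMENT") && lab %in% mapped_labels &&
        is.null(taken[[lab]])) {
      taken[[lab]] <- it
    } else {
      residual[[length(residual) + 1L]] <- it
    }
  }
  val <- function(lab) {
    it <- taken[[lab]]
    if (is.null(it) || is.null(it$value)) NULL else dv_string(it$value)
  }

  p1 <- take_participation(entry$other_participations, "submitter")
  p2 <- take_participation(p1$rest, "payer")
  gaps <- character()
  if (is.null(val("submission id"))) gaps <- c(gaps, "submission ID element")
  if (is.null(val("submission date"))) gaps <- c(gaps, "submission date element")
  if (is.null(p1$party)) gaps <- c(gaps, "submitter participation")
  if (is.null(p2$party)) gaps <- c(gaps, "payer participation")
  if (concept %in% c("professional_claim", "institutional_claim") &&
      is.null(val("billing date"))) {
    gaps <- c(gaps, "billing date element")
  }
  if (concept %in% c("professional_claim", "authorization", "authorization_request") &&
      !inherits(entry$provider, "tiss_party_identified")) {
    gaps <- c(gaps, "identified provider")
  }
  if (length(gaps)) {
    stop_tiss(paste("cannot convert to the extended model; missing:",
                    paste(gaps, collapse = ", ")),
              "tiss_conversion_error", gaps = gaps)
  }

  data <- item_tree(entry$data$name, entry$data$node_id, residual,
                    entry$data$links, entry$data$archetype_id)
  common <- list(
    name = entry$name, node_id = entry$node_id, archetype_id = entry$archetype_id,
    subject = entry$subject, data = data, links = entry$links,
    submission_id = val("submission id"),
    submission_date = val("submission date"),
    original_submission = val("original submission"),
    submitter = p1$party, submittee = p2$party
  )

  rest <- p2$rest
  new_entry <- switch(concept,
    professional_claim = do.call(professional_claim, c(common, list(
      other_participations = rest, billing_date = val("billing date"),
      performer = entry$provider
    ))),
    institutional_claim = {
      pr <- list()
      keep <- list()
      for (p in rest) {
        if (identical(p[["function"]], "professional")) {
          pr[[length(pr) + 1L]] <- p$performer
        } else {
          keep[[length(keep) + 1L]] <- p
        }
      }
      do.call(institutional_claim, c(common, list(
        provider = entry$provider, other_participations = keep,
        billing_date = val("billing date"), participants = pr
      )))
    },
    {
      validity <- val("validity")
      vs <- ve <- NULL
      if (!is.null(validity)) {
        parts <- strsplit(validity, "/", fixed = TRUE)[[1]]
        if (length(parts) != 2L) {
          stop_tiss(sprintf("validity element must read 'start/end', got '%s'", validity),
                    "tiss_conversion_error")
        }
        vs <- parts[[1]]
        ve <- parts[[2]]
      }
      auth_id <- val("authorization number")
      do.call(authorization, c(common, list(
        other_participations = rest, requester = entry$provider,
        authorization_id = auth_id, validity_start = vs, validity_end = ve,
        is_response = !is.null(auth_id)
      )))
    }
  )

  content <- comp$content
  content[[i]] <- new_entry
  status <- val("status")
  composition(
    name = comp$name, node_id = comp$node_id, archetype_id = comp$archetype_id,
    composer = comp$composer, context_start_time = comp$context_start_time,
    content = content,
    ism_transition = if (!is.null(status)) {
      ism_transition(status_from_text(status), comp$context_start_time)
    } else NULL,
    lifecycle = comp$lifecycle, template = comp$template, links = comp$links
  )
}

#' @rdname convert_base_to_extended
#' @export
convert_extended_to_base <- function(comp) {
  i <- find_claim_entry(comp, extended = TRUE)
  if (is.na(i)) {
    stop_tiss("composition carries no extended-model submission entry",
              "tiss_conversion_error")
  }
  entry <- comp$content[[i]]
  if (is.null(entry$archetype_id)) {
    stop_tiss("submission entry lacks an archetype id", "tiss_conversion_error")
  }
  concept <- archetype_concept(entry$archetype_id)
  layout <- admin_layouts()[[concept]]
  if (is.null(layout)) {
    stop_tiss(sprintf("unknown source archetype concept '%s'", concept),
              "tiss_conversion_error")
  }
  code_of <- function(lab) {
    hit <- names(layout)[tolower(layout) == lab]
    if (length(hit) == 0L) {
      stop_tiss(sprintf("archetype %s has no '%s' element", concept, lab),
                "tiss_conversion_error")
    }
    hit[[1L]]
  }
  mk <- function(lab, value) {
    code <- code_of(lab)
    element(unname(layout[[code]]), code, dv_text(value))
  }

  mapped <- list()
  add <- function(lab, value) {
    if (!is.null(value)) mapped[[length(mapped) + 1L]] <<- mk(lab, value)
  }
  add("submission id", entry$submission_id)
  add("original submission", entry$original_submission)
  add("submission date", entry$submission_date)
  if (inherits(entry, "tiss_claim")) add("billing date", entry$billing_date)
  if (identical(entry$rm_type, "AUTHORIZATION") &&
      identical(concept, "authorization")) {
    if (!is.null(entry$validity_start)) {
      add("validity", paste0(entry$validity_start, "/", entry$validity_end))
    }
    add("authorization number", entry$authorization_id)
  }
  if (!is.null(comp$ism_transition)) {
    add("status", status_to_text(comp$ism_transition$current_state))
  }

  # merge the restored header elements into the residual elements by at-code;
  # slot-filler clusters (rooted at at0000) keep their position after them
  is_el <- vapply(entry$data$items, function(it) identical(it$rm_type, "ELEMENT"),
                  logical(1))
  els <- c(mapped, entry$data$items[is_el])
  ord <- order(vapply(els, function(it) it$node_id, character(1)), method = "radix")
  items <- c(els[ord], entry$data$items[!is_el])
  data <- item_tree(entry$data$name, entry$data$node_id, items,
                    entry$data$links, entry$data$archetype_id)

  parts <- list(participation(entry$submitter, "submitter"),
                participation(entry$submittee, "payer"))
  provider <- entry$provider
  if (identical(entry$rm_type, "PROFESSIONAL_CLAIM")) provider <- entry$performer
  if (identical(entry$rm_type, "AUTHORIZATION")) provider <- entry$requester
  if (identical(entry$rm_type, "INSTITUTIONAL_CLAIM")) {
    parts <- c(parts, lapply(entry$participants, participation, func = "professional"))
  }
  parts <- c(parts, entry$other_participations)

  new_entry <- admin_entry(entry$name, entry$node_id, entry$archetype_id,
                           entry$subject, data, provider, parts, entry$links)
  content <- comp$content
  content[[i]] <- new_entry
  composition(
    name = comp$name, node_id = comp$node_id, archetype_id = comp$archetype_id,
    composer = comp$composer, context_start_time = comp$context_start_time,
    content = content, ism_transition = NULL,
    lifecycle = comp$lifecycle, template = comp$template, links = comp$links
  )
}

#' Multiset of claim header values
#'
#' Collects the (label, value) pairs of a claim composition's administrative
#' entry across both representations — elements in the plain model, absorbed
#' attributes plus residual elements in the extended one — as a sorted
#' character vector. Conversion in either direction conserves this multiset.
#'
#' @param comp a claim composition in either representation.
#' @return sorted character vector of `"label=value"` strings.
#' @export
claim_value_multiset <- function(comp) {
  i <- find_claim_entry(comp, extended = TRUE)
  if (is.na(i)) i <- find_claim_entry(comp, extended = FALSE)
  if (is.na(i)) stop_tiss("no claim entry found", "tiss_conversion_error")
  entry <- comp$content[[i]]
  out <- character()
  for (it in entry$data$items) {
    if (identical(it$rm_type, "ELEMENT") && !is.null(it$value)) {
      out <- c(out, paste0(tolower(it$name), "=", dv_string(it$value)))
    }
  }
  pair <- function(lab, v) if (!is.null(v)) paste0(lab, "=", v) else character()
  out <- c(out,
    pair("submission id", entry$submission_id),
    pair("submission date", entry$submission_date),
    pair("original submission", entry$original_submission),
    pair("billing date", entry$billing_date),
    pair("authorization number", entry$authorization_id),
    if (!is.null(entry$validity_start)) {
      pair("validity", paste0(entry$validity_start, "/", entry$validity_end))
    },
    if (!is.null(comp$ism_transition)) {
      pair("status", status_to_text(comp$ism_transition$current_state))
    }
  )
  sort(out, method = "radix")
}
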