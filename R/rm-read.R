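# Inverse of as_rm_list(): rebuilds model objects from the canonical nested
# list form (as produced by the JSON and XML readers). Reconstruction goes
# through the public constructors, so invalid serialized content is rejected
# with the same errors as hand-built objects.
rm_from_list <- function(l) {
  if (!is.list(l)) stop_tiss("expected a canonical list", "tiss_parse_error")
  if (!is.null(l$`_dv`)) return(dv_from_list(l))
  if (!is.null(l$`_k`)) return(kind_from_list(l))
  if (!is.null(l$`_rm`)) return(node_from_list(l))
  stop_tiss("canonical list lacks a type marker", "tiss_parse_error")
}

dv_from_list <- function(l) {
  switch(l$`_dv`,
    DV_TEXT = dv_text(l$value),
    DV_CODED_TEXT = dv_coded_text(l$code, l$terminology_id, l$display),
    DV_DATE_TIME = dv_date_time(l$value),
    DV_DATE = dv_date(l$value),
    DV_COUNT = dv_count(as.numeric(l$value)),
    DV_QUANTITY = dv_quantity(as.numeric(l$magnitude), l$units),
    DV_MONEY = dv_money(as.numeric(l$amount), l$currency),
    DV_IDENTIFIER = dv_identifier(l$id, l$issuer, l$type %||% ""),
    stop_tiss(sprintf("unknown data value type %s", l$`_dv`), "tiss_parse_error")
  )
}

kind_from_list <- function(l) {
  switch(l$`_k`,
    PARTY_SELF = party_self(),
    PARTY_IDENTIFIED = party_identified(l$name, lapply(l$identifiers %||% list(), dv_from_list)),
    PARTICIPATION = participation(rm_from_list(l$performer), l[["function"]], l$mode),
    LINK = link_to(l$meaning, l$type, l$target),
    ISM_TRANSITION = ism_transition(l$current_state, l$timestamp, l$careflow_step),
    EXTRACT = extract_from_list(l),
    stop_tiss(sprintf("unknown kind %s", l$`_k`), "tiss_parse_error")
  )
}

extract_from_list <- function(l) {
  new_extract(
    extract_id = l$extract_id,
    source_org = rm_from_list(l$source_org),
    target_org = rm_from_list(l$target_org),
    created_at = l$created_at,
    items = lapply(l$items %||% list(), function(it) {
      list(subject = rm_from_list(it$subject),
           compositions = lapply(it$compositions %||% list(), node_from_list))
    })
  )
}

node_from_list <- function(l) {
  t <- l$`_rm`
  links <- lapply(l$links %||% list(), rm_from_list)
  aid <- l$archetype_id
  if (t == "ELEMENT") {
    return(element(l$name, l$archetype_node_id,
                   if (!is.null(l$value)) dv_from_list(l$value) else NULL,
                   links, aid))
  }
  if (t %in% c("CLUSTER", "ITEM_TREE", "ITEM_LIST", "SECTION")) {
    items <- lapply(l$items %||% list(), node_from_list)
    fn <- switch(t, CLUSTER = cluster, ITEM_TREE = item_tree,
                 ITEM_LIST = item_list, SECTION = section)
    return(fn(l$name, l$archetype_node_id, items, links, aid))
  }
  if (t == "ITEM_TABLE") {
    return(item_table(l$name, l$archetype_node_id,
                      lapply(l$rows %||% list(), node_from_list), links, aid))
  }
  if (t == "ITEM_SINGLE") {
    return(item_single(l$name, l$archetype_node_id, node_from_list(l$item), links, aid))
  }
  if (t == "COMPOSITION") {
    return(composition(
      name = l$name, node_id = l$archetype_node_id, archetype_id = aid,
      composer = rm_from_list(l$composer),
      context_start_time = l$context_start_time,
      content = lapply(l$content %||% list(), node_from_list),
      ism_transition = if (!is.null(l$ism_transition)) rm_from_list(l$ism_transition) else NULL,
      lifecycle = lapply(l$lifecycle %||% list(), rm_from_list),
      template = l$template, links = links
    ))
  }
  if (is_rm_subtype(t, "ENTRY")) return(entry_from_list(t, l, links, aid))
  stop_tiss(sprintf("unknown rm type %s", t), "tiss_parse_error")
}

entry_from_list <- function(t, l, links, aid) {
  subject <- rm_from_list(l$subject)
  provider <- if (!is.null(l$provider)) rm_from_list(l$provider) else NULL
  parts <- lapply(l$other_participations %||% list(), rm_from_list)
  data <- node_from_list(l$data)
  base <- c("ADMIN_ENTRY", "OBSERVATION", "EVALUATION", "INSTRUCTION", "ACTION")
  if (t %in% base) {
    fn <- switch(t, ADMIN_ENTRY = admin_entry, OBSERVATION = observation,
                 EVALUATION = evaluation, INSTRUCTION = instruction, ACTION = action)
    return(fn(l$name, l$archetype_node_id, aid, subject, data, provider, parts, links))
  }
  common <- list(
    name = l$name, node_id = l$archetype_node_id, archetype_id = aid,
    subject = subject, data = data, provider = provider,
    other_participations = parts, links = links,
    submission_id = l$submission_id, submission_date = l$submission_date,
    original_submission = l$original_submission,
    submitter = rm_from_list(l$submitter), submittee = rm_from_list(l$submittee)
  )
  if (t == "PROFESSIONAL_CLAIM") {
    return(do.call(professional_claim, c(common, list(
      billing_date = l$billing_date, performer = rm_from_list(l$performer)
    ))))
  }
  if (t == "INSTITUTIONAL_CLAIM") {
    return(do.call(institutional_claim, c(common, list(
      billing_date = l$billing_date,
      participants = lapply(l$participants %||% list(), rm_from_list)
    ))))
  }
  if (t == "AUTHORIZATION") {
    return(do.call(authorization, c(common, list(
      requester = if (!is.null(l$requester)) rm_from_list(l$requester) else NULL,
      authorization_id = l$authorization_id,
      validity_start = l$validity_start, validity_end = l$validity_end,
      is_response = isTRUE(l$is_response)
    ))))
  }
  if (t == "ANNEX") {
    return(do.call(annex, c(common, list(complements = l$complements))))
  }
  stop_tiss(sprintf("unknown entry type %s", t), "tiss_parse_error")
}
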