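# Extract packaging and the simulated provider<->payer exchange: an
# in-process transport contract with REST-resource semantics (resources live
# at /organizationID/{resource_id}, verbs GET/POST/PUT/DELETE), and payer
# adjudication producing a response extract per request extract.

new_extract <- function(extract_id, source_org, target_org, created_at, items) {
  assert_string(extract_id, "extract_id")
  assert_identified(source_org, "source_org")
  assert_identified(target_org, "target_org")
  if (length(items) < 1L) {
    stop_tiss("an extract must carry at least one item", "tiss_value_error")
  }
  structure(list(extract_id = extract_id, source_org = source_org,
                 target_org = target_org, created_at = canonical_datetime(created_at),
                 items = items),
            class = "tiss_extract")
}

#' @export
print.tiss_extract <- function(x, ...) {
  n <- sum(vapply(x$items, function(it) length(it$compositions), integer(1)))
  cat(sprintf("<extract> %s: %s -> %s, %d subject(s), %d composition(s)\n",
              x$extract_id, x$source_org$name, x$target_org$name,
              length(x$items), n))
  invisible(x)
}

party_key <- function(p) {
  if (length(p$identifiers)) p$identifiers[[1]]$id else p$name
}

#' Package compositions into an extract
#'
#' Groups the compositions by record subject (in order of first appearance)
#' and wraps them in a transferable extract from a source organization to a
#' target organization. Inputs are not mutated.
#'
#' @param comps non-empty list of compositions, each carrying a claim entry.
#' @param source,target identified source and target organizations.
#' @param id_source an [id_source()] used for the extract id.
#' @param created_at ISO timestamp of packaging.
#' @return a `tiss_extract`.
#' @export
package_extract <- function(comps, source, target, id_source,
                            created_at = "2011-11-01T08:00:00") {
  if (!is.list(comps) || length(comps) == 0L) {
    stop_tiss("comps must be a non-empty list of compositions", "tiss_value_error")
  }
  keys <- character()
  items <- list()
  for (comp in comps) {
    subject <- NULL
    for (e in comp$content) {
      if (!is.null(e$subject)) {
        subject <- e$subject
        break
      }
    }
    if (is.null(subject)) {
      stop_tiss("composition carries no entry with a subject", "tiss_value_error")
    }
    k <- party_key(subject)
    i <- match(k, keys)
    if (is.na(i)) {
      keys <- c(keys, k)
      items[[length(items) + 1L]] <- list(subject = subject, compositions = list(comp))
    } else {
      items[[i]]$compositions <- c(items[[i]]$compositions, list(comp))
    }
  }
  new_extract(id_source("EXT"), source, target, created_at, items)
}

#' Deterministic id sources and clocks
#'
#' `id_source()` returns a closure yielding `PREFIX-000001`, `PREFIX-000002`,
#' ... per prefix; `make_clock()` a closure yielding ISO timestamps advancing
#' by a fixed step. Both make exchange runs reproducible.
#'
#' @param start ISO timestamp the clock starts at.
#' @param step_seconds seconds between successive ticks.
#' @return a closure.
#' @export
id_source <- function() {
  counters <- new.env(parent = emptyenv())
  function(prefix) {
    n <- (get0(prefix, counters) %||% 0L) + 1L
    assign(prefix, n, counters)
    sprintf("%s-%06d", prefix, n)
  }
}

#' @rdname id_source
#' @export
make_clock <- function(start = "2011-11-01T08:00:00", step_seconds = 60) {
  t <- as.POSIXct(canonical_datetime(start), format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  n <- 0L
  function() {
    out <- format(t + n * step_seconds, "%Y-%m-%dT%H:%M:%S")
    n <<- n + 1L
    out
  }
}

# -- resource store ----------------------------------------------------------

#' In-process REST resource store
#'
#' Resources (serialized extracts) are stored under
#' `/organizationID/{resource_id}`. POST creates with a server-assigned id,
#' PUT upserts at the given id (idempotent), GET retrieves and DELETE
#' removes; missing resources yield a not-found response, not an exception.
#' All operations are appended to the store's log.
#'
#' @param store a `resource_store()`.
#' @param org_id organization id (registered with [register_org()]).
#' @param res_id resource id.
#' @param payload serialized payload (a string).
#' @return transport responses: `list(status =, resource_id =, payload =)`.
#' @export
resource_store <- function() {
  env <- new.env(parent = emptyenv())
  env$orgs <- character()
  env$data <- list()
  env$counters <- list()
  env$log <- list()
  structure(env, class = "tiss_resource_store")
}

#' @rdname resource_store
#' @export
register_org <- function(store, org_id) {
  if (!(org_id %in% store$orgs)) store$orgs <- c(store$orgs, org_id)
  invisible(store)
}

check_org <- function(store, org_id) {
  if (!(org_id %in% store$orgs)) {
    stop_tiss(sprintf("organization '%s' is not registered", org_id), "tiss_value_error")
  }
}

log_op <- function(store, verb, org_id, res_id, status) {
  store$log[[length(store$log) + 1L]] <-
    list(verb = verb, org = org_id, resource = res_id, status = status)
}

res_key <- function(org_id, res_id) paste0("/", org_id, "/", res_id)

#' @rdname resource_store
#' @export
transport_post <- function(store, org_id, payload) {
  check_org(store, org_id)
  n <- (store$counters[[org_id]] %||% 0L) + 1L
  store$counters[[org_id]] <- n
  res_id <- sprintf("r%04d", n)
  store$data[[res_key(org_id, res_id)]] <- payload
  log_op(store, "POST", org_id, res_id, 201L)
  list(status = 201L, resource_id = res_id)
}

#' @rdname resource_store
#' @export
transport_put <- function(store, org_id, res_id, payload) {
  check_org(store, org_id)
  key <- res_key(org_id, res_id)
  status <- if (is.null(store$data[[key]])) 201L else 200L
  store$data[[key]] <- payload
  log_op(store, "PUT", org_id, res_id, status)
  list(status = status, resource_id = res_id)
}

#' @rdname resource_store
#' @export
transport_get <- function(store, org_id, res_id) {
  check_org(store, org_id)
  payload <- store$data[[res_key(org_id, res_id)]]
  status <- if (is.null(payload)) 404L else 200L
  log_op(store, "GET", org_id, res_id, status)
  list(status = status, resource_id = res_id, payload = payload)
}

#' @rdname resource_store
#' @export
transport_delete <- function(store, org_id, res_id) {
  check_org(store, org_id)
  key <- res_key(org_id, res_id)
  status <- if (is.null(store$data[[key]])) 404L else 204L
  store$data[[key]] <- NULL
  log_op(store, "DELETE", org_id, res_id, status)
  list(status = status, resource_id = res_id)
}

# -- adjudication ------------------------------------------------------------

#' Adjudication policies
#'
#' A policy decides, per valid composition, one of `"approve"`, `"deny"`,
#' `"pend"` or `"return_for_correction"`, and configures the validity length
#' of granted authorizations. The decision logic of a payer is user-supplied;
#' `policy_approve_all()`, `policy_deny_all()` and `policy_deny_then_approve()`
#' (deny on first sight of a submission id, approve on resubmission) cover
#' the simulated scenarios.
#'
#' @param decide `function(comp, report) -> decision`.
#' @param validity_days length in days of granted authorization validity.
#' @return an `adjudication_policy`.
#' @export
adjudication_policy <- function(decide, validity_days = 30L) {
  structure(list(decide = decide, validity_days = as.integer(validity_days)),
            class = "tiss_adjudication_policy")
}

#' @rdname adjudication_policy
#' @export
policy_approve_all <- function(validity_days = 30L) {
  adjudication_policy(function(comp, report) "approve", validity_days)
}

#' @rdname adjudication_policy
#' @export
policy_deny_all <- function() {
  adjudication_policy(function(comp, report) "deny")
}

#' @rdname adjudication_policy
#' @export
policy_deny_then_approve <- function(validity_days = 30L) {
  seen <- new.env(parent = emptyenv())
  adjudication_policy(function(comp, report) {
    sid <- composition_submission_id(comp) %||% "?"
    if (is.null(get0(sid, seen))) {
      assign(sid, TRUE, seen)
      "deny"
    } else {
      "approve"
    }
  }, validity_days)
}

composition_submission_id <- function(comp) {
  i <- find_claim_entry(comp, extended = TRUE)
  if (!is.na(i)) return(comp$content[[i]]$submission_id)
  i <- find_claim_entry(comp, extended = FALSE)
  if (is.na(i)) return(NULL)
  entry <- comp$content[[i]]
  for (it in entry$data$items) {
    if (identical(it$rm_type, "ELEMENT") && tolower(it$name) == "submission id" &&
        !is.null(it$value)) {
      return(dv_string(it$value))
    }
  }
  NULL
}

decision_state <- function(decision) {
  switch(decision, approve = "COMPLETED", deny = "DENIED", pend = "PENDING",
         return_for_correction = "RETURNED_FOR_CORRECTION",
         stop_tiss(sprintf("unknown decision '%s'", decision), "tiss_value_error"))
}

annex_items <- function(decision, report) {
  items <- list(element("decision", "at0001", dv_text(decision)))
  k <- 1L
  for (f in report$findings) {
    k <- k + 1L
    items[[length(items) + 1L]] <- element(
      "finding", sprintf("at%04d", k),
      dv_text(sprintf("[%s] %s at %s: %s", f$severity, f$rule, f$path, f$detail)))
  }
  items
}

response_composition <- function(comp, decision, report, policy, clock, ids) {
  now <- clock()
  req_entry <- comp$content[[find_claim_entry(comp, extended = FALSE)]]
  subject <- req_entry$subject
  sid <- composition_submission_id(comp)
  p1 <- take_participation(req_entry$other_participations, "submitter")
  p2 <- take_participation(p1$rest, "payer")
  provider_org <- p1$party
  payer_org <- p2$party
  state <- decision_state(decision)
  history <- apply_transition(comp$lifecycle, state, now)
  concept <- archetype_concept(req_entry$archetype_id)
  link <- link_to("responds to", "CLAIM_STATUS",
                  paste0("submission:", sid %||% "unknown"))

  if (concept == "authorization_request" && decision == "approve") {
    today <- substr(now, 1, 10)
    entry <- authorization(
      "authorization response", "at0000",
      "openEHR-EHR-AUTHORIZATION.authorization.v1",
      subject = subject,
      data = item_tree("components", "at0001", list()),
      provider = req_entry$provider,
      other_participations = list(),
      links = list(link),
      submission_id = ids("RSP"), submission_date = today,
      submitter = payer_org, submittee = provider_org,
      original_submission = sid,
      requester = if (inherits(req_entry$provider, "tiss_party_identified")) {
        req_entry$provider
      } else NULL,
      authorization_id = ids("AUTH"),
      validity_start = today,
      validity_end = format(as.Date(today) + policy$validity_days, "%Y-%m-%d"),
      is_response = TRUE
    )
  } else {
    today <- substr(now, 1, 10)
    # synthetic annex archetype id: no annex archetype ships in the fixtures
    entry <- annex(
      "adjudication note", "at0000", "openEHR-EHR-ANNEX.adjudication_note.v1",
      subject = subject,
      data = item_tree("components", "at0001", annex_items(decision, report)),
      links = list(link),
      submission_id = ids("RSP"), submission_date = today,
      submitter = payer_org, submittee = provider_org,
      original_submission = sid,
      complements = sid %||% "unknown"
    )
  }
  composition(
    name = paste0(comp$name, " (response)"), node_id = "at0000",
    archetype_id = comp$archetype_id,
    composer = payer_org, context_start_time = now,
    content = list(entry),
    ism_transition = history[[length(history)]],
    lifecycle = history, template = comp$template
  )
}

#' Adjudicate a request extract
#'
#' Validates every composition in the extract against its form template; an
#' invalid composition is returned for correction with the validation report
#' attached as an annex entry. Valid compositions are decided by the policy:
#' approved authorization requests yield an authorization response carrying
#' an authorization id and a validity period of the configured length, other
#' outcomes yield an adjudication annex. Every processed composition's
#' lifecycle is extended by one legal transition, exactly one response
#' composition is emitted per request composition, and the response
#' extract's source and target organizations are swapped.
#'
#' @param extract the request extract.
#' @param policy an [adjudication_policy()].
#' @param repo,templates the archetype repository and template set.
#' @param clock a [make_clock()] closure.
#' @param ids an [id_source()] closure.
#' @return the response extract.
#' @export
adjudicate <- function(extract, policy, repo = tiss_repository(1L),
                       templates = tiss_templates(),
                       clock = make_clock(), ids = id_source()) {
  opt_cache <- list()
  items <- lapply(extract$items, function(it) {
    responses <- lapply(it$compositions, function(comp) {
      tpl_name <- comp$template
      if (is.null(tpl_name) || is.null(templates[[tpl_name]])) {
        report <- validation_report(list(validation_finding(
          "", "NODE_ID_UNKNOWN", "composition names no known template")))
        decision <- "return_for_correction"
      } else {
        if (is.null(opt_cache[[tpl_name]])) {
          opt_cache[[tpl_name]] <<- flatten(templates[[tpl_name]], repo)
        }
        report <- validate_against_template(comp, opt_cache[[tpl_name]], repo)
        decision <- if (!report$valid) {
          "return_for_correction"
        } else {
          policy$decide(comp, report)
        }
      }
      response_composition(comp, decision, report, policy, clock, ids)
    })
    list(subject = it$subject, compositions = responses)
  })
  new_extract(ids("EXT"), extract$target_org, extract$source_org, clock(), items)
}

# -- scenarios and the full round trip --------------------------------------

#' Generate an exchange scenario
#'
#' Builds the provider-side materials of a simulated exchange: an extract of
#' authorization-request compositions (instantiating the admission-request
#' form, whose admission cluster mirrors the simulated exchange of admission
#' documents) and optionally claim compositions. Deterministic under the
#' seed.
#'
#' @param seed integer seed.
#' @param n_requests number of authorization-request compositions.
#' @param n_claims number of individual-claim compositions.
#' @param repo,templates repository and template set.
#' @return a `tiss_scenario`: provider/payer organizations and a list of
#'   steps `list(actor =, extract =)`.
#' @export
generate_scenario <- function(seed, n_requests = 2L, n_claims = 0L,
                              repo = tiss_repository(1L),
                              templates = tiss_templates()) {
  comps <- list()
  if (n_requests > 0L) {
    comps <- c(comps, generate_claims(n_requests, seed, "admission request",
                                      repo, templates))
  }
  if (n_claims > 0L) {
    comps <- c(comps, lapply(seq_len(n_claims), function(i) {
      generate_composition(generator_config(seed, "individual claim",
                                            index = 1000L + i), repo, templates)
    }))
  }
  ids <- id_source()
  provider <- party_identified("Hospital Santa Clara", list(
    dv_identifier("PRV-0001", "national provider registry", "provider id")))
  payer <- party_identified("Vida Plena Health Plan", list(
    dv_identifier("PAY-001", "supplementary health registry", "payer id")))
  # submissions must be unique per scenario: re-key the submission ids
  comps <- lapply(seq_along(comps), function(i) {
    rekey_submission_id(comps[[i]], sprintf("S-%06d", i))
  })
  steps <- if (length(comps)) {
    list(list(actor = "provider",
              extract = package_extract(comps, provider, payer, ids)))
  } else {
    list()
  }
  structure(list(provider = provider, payer = payer, steps = steps,
                 provider_org = "PRV-0001", payer_org = "PAY-001"),
            class = "tiss_scenario")
}

rekey_submission_id <- function(comp, sid) {
  i <- find_claim_entry(comp, extended = FALSE)
  if (is.na(i)) return(comp)
  entry <- comp$content[[i]]
  entry$data$items <- lapply(entry$data$items, function(it) {
    if (identical(it$rm_type, "ELEMENT") && tolower(it$name) == "submission id") {
      it$value <- dv_text(sid)
    }
    it
  })
  comp$content[[i]] <- entry
  comp
}

#' Run the provider-payer round trip
#'
#' The provider POSTs its request extract to the payer's resource space, the
#' payer GETs and adjudicates it and POSTs the response extract to the
#' provider's space, and the provider GETs it back. With `resubmit = TRUE`,
#' denied submissions are resubmitted once (lifecycle DENIED -> SUBMITTED)
#' and re-adjudicated. Every lifecycle history in the final extracts
#' validates; the whole run is deterministic under the scenario seed and the
#' clock, and the log serializes to JSON lines byte-reproducibly.
#'
#' @param scenario a [generate_scenario()] result.
#' @param policy an [adjudication_policy()].
#' @param repo,templates repository and template set.
#' @param clock a [make_clock()] closure.
#' @param resubmit resubmit denied submissions once.
#' @return a `tiss_exchange_log` with fields `entries`, `responses` (final
#'   response compositions), `store`.
#' @export
run_roundtrip <- function(scenario, policy, repo = tiss_repository(1L),
                          templates = tiss_templates(), clock = make_clock(),
                          resubmit = FALSE) {
  store <- resource_store()
  register_org(store, scenario$provider_org)
  register_org(store, scenario$payer_org)
  ids <- id_source()
  entries <- list()
  responses <- list()
  note <- function(step, detail) {
    entries[[length(entries) + 1L]] <<- list(step = step, detail = detail)
  }

  for (step in scenario$steps) {
    extract <- step$extract
    round <- 1L
    repeat {
      posted <- transport_post(store, scenario$payer_org, to_tiss_json(extract))
      note("submit", sprintf("provider POST %s at /%s/%s", extract$extract_id,
                             scenario$payer_org, posted$resource_id))
      got <- transport_get(store, scenario$payer_org, posted$resource_id)
      inbound <- from_tiss_json(got$payload)
      response <- adjudicate(inbound, policy, repo, templates, clock, ids)
      rposted <- transport_post(store, scenario$provider_org, to_tiss_json(response))
      note("respond", sprintf("payer POST %s at /%s/%s", response$extract_id,
                              scenario$provider_org, rposted$resource_id))
      rgot <- transport_get(store, scenario$provider_org, rposted$resource_id)
      final <- from_tiss_json(rgot$payload)
      comps <- unlist(lapply(final$items, `[[`, "compositions"), recursive = FALSE)
      denied_src <- list()
      for (k in seq_along(comps)) {
        resp <- comps[[k]]
        state <- resp$ism_transition$current_state
        note("state", sprintf("%s -> %s", resp$name, state))
        if (identical(state, "DENIED") && resubmit && round == 1L) {
          denied_src[[length(denied_src) + 1L]] <- k
        } else {
          responses[[length(responses) + 1L]] <- resp
        }
      }
      if (length(denied_src) == 0L || !resubmit || round > 1L) break
      # resubmission: reopen the denied submissions' lifecycles and resend
      originals <- unlist(lapply(extract$items, `[[`, "compositions"),
                          recursive = FALSE)
      keep <- list()
      for (k in denied_src) {
        orig <- originals[[k]]
        hist <- apply_transition(comps[[k]]$lifecycle, "SUBMITTED", clock())
        orig$lifecycle <- hist
        keep[[length(keep) + 1L]] <- orig
        note("resubmit", sprintf("%s resubmitted after denial", orig$name))
      }
      extract <- package_extract(keep, scenario$provider, scenario$payer, ids,
                                 created_at = clock())
      round <- round + 1L
    }
  }
  structure(list(entries = entries, responses = responses, store = store),
            class = "tiss_exchange_log")
}

#' @rdname run_roundtrip
#' @param log an exchange log.
#' @export
exchange_log_json <- function(log) {
  lines <- vapply(log$entries, function(e) {
    as.character(jsonlite::toJSON(e, auto_unbox = TRUE))
  }, character(1))
  paste(lines, collapse = "\n")
}

#' @export
print.tiss_exchange_log <- function(x, ...) {
  cat(sprintf("<exchange log> %d entr(ies), %d response composition(s)\n",
              length(x$entries), length(x$responses)))
  invisible(x)
}
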