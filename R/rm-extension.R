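assert_identified <- function(p, what) {
  if (!inherits(p, "tiss_party_identified") || length(p$identifiers) < 1L) {
    stop_tiss(sprintf("%s must be a PARTY_IDENTIFIED with at least one identifier", what),
              "tiss_type_error")
  }
  p
}

make_submission <- function(rm_type, name, node_id, archetype_id, subject, data,
                            provider, other_participations, links,
                            submission_id, submission_date, submitter, submittee,
                            original_submission = NULL, extra = list()) {
  if (!is_string(submission_id) || !nzchar(submission_id)) {
    stop_tiss("submission_id must be a non-empty string", "tiss_value_error")
  }
  assert_identified(submitter, "submitter")
  assert_identified(submittee, "submittee")
  if (!is.null(original_submission)) assert_string(original_submission, "original_submission")
  make_entry(rm_type, name, node_id, archetype_id, subject, data, provider,
             other_participations, links,
             c(list(submission_id = submission_id,
                    submission_date = canonical_date(submission_date),
                    original_submission = original_submission,
                    submitter = submitter, submittee = submittee),
               extra))
}

#' Extended reference-model submission entries
#'
#' In the extended reference model the generic administrative entry is
#' specialized for billing: a SUBMISSION carries the fixed attributes common
#' to every authorization and claim (submission id and date, the submitting
#' provider, the receiving payer, and an optional reference to the submission
#' it re-issues). A claim adds a billing date; a professional claim names its
#' performer, an institutional claim lists the professionals involved. An
#' authorization covers both the request and the response: responses carry an
#' authorization id and a validity period. An annex supplements another
#' submission, e.g. a clinical report requested by the payer.
#'
#' @inheritParams admin_entry
#' @param submission_id non-empty submission identifier.
#' @param submission_date ISO date the submission was made.
#' @param submitter,submittee identified provider and payer organizations,
#'   each with at least one identifier.
#' @param original_submission optional id of the submission this one re-issues.
#' @param billing_date ISO billing date (claims).
#' @param performer the identified professional who performed the services.
#' @param participants identified professionals involved (institutional).
#' @param requester the requesting professional (authorizations).
#' @param authorization_id authorization number; required when `is_response`.
#' @param validity_start,validity_end optional validity interval (responses),
#'   `validity_start <= validity_end`.
#' @param is_response whether this authorization is a payer response.
#' @param complements submission id this annex supplements.
#' @return an entry of the requested extended type.
#' @export
professional_claim <- function(name, node_id = "at0000", archetype_id = NULL,
                               subject, data, provider = NULL,
                               other_participations = list(), links = list(),
                               submission_id, submission_date, submitter, submittee,
                               original_submission = NULL, billing_date, performer) {
  make_submission("PROFESSIONAL_CLAIM", name, node_id, archetype_id, subject, data,
                  provider, other_participations, links, submission_id,
                  submission_date, submitter, submittee, original_submission,
                  list(billing_date = canonical_date(billing_date),
                       performer = assert_identified(performer, "performer")))
}

#' @rdname professional_claim
#' @export
institutional_claim <- function(name, node_id = "at0000", archetype_id = NULL,
                                subject, data, provider = NULL,
                                other_participations = list(), links = list(),
                                submission_id, submission_date, submitter, submittee,
                                original_submission = NULL, billing_date,
                                participants = list()) {
  for (p in participants) assert_identified(p, "participant")
  make_submission("INSTITUTIONAL_CLAIM", name, node_id, archetype_id, subject, data,
                  provider, other_participations, links, submission_id,
                  submission_date, submitter, submittee, original_submission,
                  list(billing_date = canonical_date(billing_date),
                       participants = participants))
}

#' @rdname professional_claim
#' @export
authorization <- function(name, node_id = "at0000", archetype_id = NULL,
                          subject, data, provider = NULL,
                          other_participations = list(), links = list(),
                          submission_id, submission_date, submitter, submittee,
                          original_submission = NULL, requester = NULL,
                          authorization_id = NULL, validity_start = NULL,
                          validity_end = NULL, is_response = FALSE) {
  if (!is.null(requester)) assert_identified(requester, "requester")
  if (!is.null(authorization_id)) assert_string(authorization_id, "authorization_id")
  if (isTRUE(is_response) && is.null(authorization_id)) {
    stop_tiss("an authorization response requires an authorization_id", "tiss_value_error")
  }
  if (xor(is.null(validity_start), is.null(validity_end))) {
    stop_tiss("validity requires both start and end", "tiss_value_error")
  }
  if (!is.null(validity_start)) {
    validity_start <- canonical_date(validity_start)
    validity_end <- canonical_date(validity_end)
    if (validity_start > validity_end) {
      stop_tiss("validity start must not follow its end", "tiss_value_error")
    }
  }
  make_submission("AUTHORIZATION", name, node_id, archetype_id, subject, data,
                  provider, other_participations, links, submission_id,
                  submission_date, submitter, submittee, original_submission,
                  list(requester = requester, authorization_id = authorization_id,
                       validity_start = validity_start, validity_end = validity_end,
                       is_response = isTRUE(is_response)))
}

#' @rdname professional_claim
#' @export
annex <- function(name, node_id = "at0000", archetype_id = NULL,
                  subject, data, provider = NULL,
                  other_participations = list(), links = list(),
                  submission_id, submission_date, submitter, submittee,
                  original_submission = NULL, complements) {
  make_submission("ANNEX", name, node_id, archetype_id, subject, data,
                  provider, other_participations, links, submission_id,
                  submission_date, submitter, submittee, original_submission,
                  list(complements = assert_string(complements, "complements")))
}
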