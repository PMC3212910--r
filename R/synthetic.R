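# Seedable generator of template-conformant claim and authorization
# compositions. Values emulate the Brazilian claims context abstractly:
# opaque patient/provider/payer identifier strings with issuer labels, TUSS-
# and ICD-like codes as opaque strings, amounts in BRL. One derived RNG seed
# per composition, so adding templates does not shift existing outputs.

#' Generator configuration
#'
#' @param seed integer master seed; the same configuration produces a
#'   byte-identical composition.
#' @param template name of the form template to instantiate.
#' @param index stream index: compositions with different indices come from
#'   independently seeded streams of the same master seed.
#' @param fill `"random"` includes optional elements with `include_prob`;
#'   `"all"` populates every element the template admits.
#' @param include_prob inclusion probability for optional elements.
#' @return a `tiss_generator_config`.
#' @export
generator_config <- function(seed, template, index = 1L, fill = c("random", "all"),
                             include_prob = 0.9) {
  fill <- match.arg(fill)
  structure(list(seed = as.integer(seed), template = template,
                 index = as.integer(index), fill = fill,
                 include_prob = include_prob),
            class = "tiss_generator_config")
}

derive_seed <- function(seed, key, index) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((abs(seed) %% 1021001 * 1009 + index * 97003 + h * 131) %% 2147483587L)
}

word_pool <- function(label) {
  pools <- list(
    "type of encounter" = c("consultation", "exam", "hospitalization", "therapy"),
    "type of claim" = c("initial", "complementary", "final"),
    "type of procedure" = c("clinical", "surgical", "diagnostic"),
    "procedure" = c("10101012", "20103301", "31309054", "40304361"),
    "main diagnosis" = c("A09.0", "J18.9", "S52.5", "I10"),
    "secondary diagnoses" = c("E11.9", "N39.0", "R51"),
    "clinical indication" = c("acute abdominal pain", "persistent fever",
                              "post-operative follow-up"),
    "type of disease" = c("acute", "chronic"),
    "discharge reason" = c("cured", "improved", "transferred"),
    "further action" = c("none", "return visit", "referral"),
    "comments" = c("no remarks", "see annex", "urgent"),
    "type of admission" = c("elective", "emergency"),
    "admission regime" = c("hospital", "day hospital", "home care"),
    "hospital service" = c("clinical", "surgical", "obstetric"),
    "type of accommodation" = c("ward", "private room", "ICU"),
    "access" = c("open", "videolaparoscopic"),
    "technique" = c("conventional", "robotic"),
    "vendor" = c("OrthoMed", "BioSupply", "MedParts"),
    "tooth" = c("11", "24", "36", "47"),
    "face" = c("M", "D", "V", "L", "O"),
    "status" = "submitted"
  )
  pools[[label]] %||% c("recorded", "not informed", "see notes")
}

person_name <- function() {
  first <- c("Ana", "Bruno", "Carla", "Diego", "Elisa", "Fabio", "Gilda", "Hugo")
  last <- c("Silva", "Souza", "Oliveira", "Costa", "Pereira", "Almeida")
  paste(sample(first, 1), sample(last, 1))
}

gen_parties <- function() {
  patient <- party_identified(person_name(), list(
    dv_identifier(sprintf("PAT-%06d", sample.int(999999L, 1)), "health plan",
                  "patient number")
  ))
  clinician <- party_identified(person_name(), list(
    dv_identifier(sprintf("CRM-%05d", sample.int(99999L, 1)), "professional council",
                  "professional id")
  ))
  provider_org <- party_identified("Hospital Santa Clara", list(
    dv_identifier(sprintf("PRV-%04d", sample.int(9999L, 1)), "national provider registry",
                  "provider id")
  ))
  payer_org <- party_identified("Vida Plena Health Plan", list(
    dv_identifier(sprintf("PAY-%03d", sample.int(999L, 1)), "supplementary health registry",
                  "payer id")
  ))
  list(patient = patient, clinician = clinician,
       provider_org = provider_org, payer_org = payer_org)
}

base_date <- function() {
  as.Date("2011-10-01") + sample.int(20L, 1)
}

iso <- function(d) format(d, "%Y-%m-%d")

# Elements without which a claim header is not convertible or adjudicable.
always_labels <- function() {
  c("submission ID", "submission Date", "submission date", "billing date",
    "status", "authorization number", "authorization date", "date of encounter")
}

gen_element_value <- function(cons, ctx) {
  label <- cons$label %||% ""
  kind <- "DV_TEXT"
  for (a in cons$attributes) {
    for (ch in a$children) if (ch$kind == "primitive") kind <- ch$rm_type
  }
  if (!is.null(cons$binding)) {
    code <- sample(cons$binding$codes, 1)
    return(dv_coded_text(code, cons$binding$terminology_id))
  }
  if (kind == "DV_DATE_TIME") return(dv_date_time(paste0(iso(ctx$date), "T10:30:00")))
  if (kind == "DV_COUNT") return(dv_count(sample(0:9, 1)))
  if (kind == "DV_MONEY") return(dv_money(round(stats::runif(1, 10, 5000), 2)))
  value <- switch(label,
    "submission ID" = ,
    "submission date" = ,
    "submission Date" = iso(ctx$date),
    "billing date" = iso(ctx$date + 2),
    "authorization date" = iso(ctx$date - 1),
    "probable date of admission" = iso(ctx$date + 1),
    "date of admission" = iso(ctx$date + 1),
    "discharge date" = iso(ctx$date + 1 + sample(0:14, 1)),
    "validity" = paste0(iso(ctx$date), "/", iso(ctx$date + 30)),
    "original submission" = sprintf("S-%06d", sample.int(999999L, 1)),
    "authorization number" = sprintf("A-%05d", sample.int(99999L, 1)),
    "death certificate number" = sprintf("DC-%06d", sample.int(999999L, 1)),
    "duration of disease" = sprintf("%d days", sample.int(60L, 1)),
    "accident indication" = sample(c("no accident", "work accident", "traffic accident"), 1),
    sample(word_pool(label), 1)
  )
  if (identical(label, "submission ID")) value <- ctx$submission_id
  dv_text(value)
}

gen_items <- function(children, ctx) {
  out <- list()
  for (ch in children) {
    if (ch$kind == "primitive") next
    if (ch$kind == "slot") next # unfilled slot: nothing to instantiate
    if (ch$occurrences$upper < 1) next # excluded
    label <- ch$label %||% ""
    include <- if (!is.null(ch$filler_id)) {
      TRUE
    } else if (ch$occurrences$lower >= 1 || ctx$fill == "all") {
      TRUE
    } else if (label %in% always_labels()) {
      TRUE
    } else {
      stats::runif(1) < ctx$include_prob
    }
    if (!include) next
    if (identical(ch$rm_type, "ELEMENT")) {
      n <- 1L
      if (is.infinite(ch$occurrences$upper) && identical(label, "secondary diagnoses")) {
        n <- sample(1:2, 1)
      }
      for (k in seq_len(n)) {
        out[[length(out) + 1L]] <- element(label, ch$node_id, gen_element_value(ch, ctx))
      }
    } else if (identical(ch$rm_type, "CLUSTER")) {
      kids <- list()
      for (a in ch$attributes) kids <- c(kids, gen_items(a$children, ctx))
      if (length(kids) == 0L) {
        # a cluster instance must hold at least one item
        first_el <- NULL
        for (a in ch$attributes) {
          for (cc in a$children) {
            if (cc$kind == "object" && identical(cc$rm_type, "ELEMENT")) {
              first_el <- cc
              break
            }
          }
          if (!is.null(first_el)) break
        }
        if (is.null(first_el)) next
        kids <- list(element(first_el$label %||% "", first_el$node_id,
                             gen_element_value(first_el, ctx)))
      }
      out[[length(out) + 1L]] <- cluster(label, ch$node_id, kids,
                                         archetype_id = ch$filler_id)
    }
  }
  out
}

fix_coherence <- function(items) {
  by_label <- function(lab) {
    which(vapply(items, function(i) {
      identical(i$rm_type, "ELEMENT") && identical(i$name, lab)
    }, logical(1)))
  }
  req <- by_label("requested number of days")
  auth <- by_label("authorized number of days")
  if (length(req) && length(auth)) {
    r <- items[[req[1]]]$value$value
    a <- items[[auth[1]]]$value$value
    if (r > a) items[[req[1]]]$value <- dv_count(a)
  }
  adm <- by_label("date of admission")
  dis <- by_label("discharge date")
  if (length(adm) && length(dis)) {
    if (items[[dis[1]]]$value$value < items[[adm[1]]]$value$value) {
      items[[dis[1]]]$value <- dv_text(items[[adm[1]]]$value$value)
    }
  }
  items
}

gen_entry <- function(cons, ctx) {
  concept <- archetype_concept(cons$filler_id)
  data_items <- list()
  for (a in cons$attributes) {
    if (identical(a$name, "data")) {
      tree_cons <- a$children[[1]]
      for (ta in tree_cons$attributes) {
        data_items <- c(data_items, gen_items(ta$children, ctx))
      }
    }
  }
  data_items <- fix_coherence_deep(data_items)
  data <- item_tree("components", "at0001", data_items)
  parts <- list(participation(ctx$parties$provider_org, "submitter"),
                participation(ctx$parties$payer_org, "payer"))
  if (identical(concept, "institutional_claim")) {
    n <- sample(1:2, 1)
    for (k in seq_len(n)) {
      parts[[length(parts) + 1L]] <- participation(
        party_identified(person_name(), list(
          dv_identifier(sprintf("CRM-%05d", sample.int(99999L, 1)),
                        "professional council", "professional id")
        )), "professional")
    }
  }
  fn <- switch(cons$rm_type, EVALUATION = evaluation, ACTION = action,
               OBSERVATION = observation, INSTRUCTION = instruction, admin_entry)
  fn(cons$label %||% concept, "at0000", cons$filler_id, ctx$parties$patient,
     data, ctx$parties$clinician, parts)
}

fix_coherence_deep <- function(items) {
  items <- fix_coherence(items)
  lapply(items, function(it) {
    if (identical(it$rm_type, "CLUSTER")) {
      fixed <- fix_coherence_deep(it$items)
      cluster(it$name, it$node_id, fixed, it$links, it$archetype_id)
    } else {
      it
    }
  })
}

#' Generate a template-conformant composition
#'
#' Instantiates the flattened form of the configured template with pooled
#' synthetic values: identified patient, clinician, provider and payer
#' parties; coherent dates (admission precedes discharge, requested days
#' never exceed authorized days); non-negative costs; coded values drawn from
#' the template's code bindings; a status element reading "submitted"; and an
#' opened lifecycle. Output is deterministic under the configuration and
#' valid against the template by construction.
#'
#' @param cfg a [generator_config()].
#' @param repo an [archetype_repository()] (approach-1 fixtures by default).
#' @param templates named list of templates, as from [tiss_templates()].
#' @param opt optional pre-flattened operational template for `cfg$template`,
#'   to avoid re-flattening in bulk generation.
#' @return a [composition()].
#' @export
generate_composition <- function(cfg, repo = tiss_repository(1L),
                                 templates = tiss_templates(), opt = NULL) {
  tpl <- templates[[cfg$template]]
  if (is.null(tpl)) {
    stop_tiss(sprintf("unknown template '%s'", cfg$template), "tiss_value_error")
  }
  if (is.null(opt)) opt <- flatten(tpl, repo)
  seed <- derive_seed(cfg$seed, cfg$template, cfg$index)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  parties <- gen_parties()
  date <- base_date()
  ctx <- list(parties = parties, date = date, fill = cfg$fill,
              include_prob = cfg$include_prob,
              submission_id = sprintf("S-%06d", sample.int(999999L, 1)))

  entries <- list()
  for (a in opt$root$attributes) {
    if (!identical(a$name, "content")) next
    for (ch in a$children) {
      if (ch$kind == "object" && !is.null(ch$filler_id)) {
        entries[[length(entries) + 1L]] <- gen_entry(ch, ctx)
      }
    }
  }
  start <- paste0(iso(date), "T09:00:00")
  composition(
    name = cfg$template, node_id = "at0000",
    archetype_id = repo_resolve_id(repo, tpl$root_archetype),
    composer = parties$clinician, context_start_time = start,
    content = entries, lifecycle = list(ism_transition("SUBMITTED", start)),
    template = cfg$template
  )
}

#' @rdname generate_composition
#' @param n number of compositions.
#' @param seed master seed.
#' @param template template name.
#' @param ... passed to [generator_config()].
#' @export
generate_claims <- function(n, seed, template, repo = tiss_repository(1L),
                            templates = tiss_templates(), ...) {
  opt <- flatten(templates[[template]], repo)
  lapply(seq_len(n), function(i) {
    generate_composition(generator_config(seed, template, index = i, ...),
                         repo, templates, opt = opt)
  })
}
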