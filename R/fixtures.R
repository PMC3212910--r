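# Programmatic builders for the three TISS archetype sets and the eleven form
# templates. Everything is constructed in code; build_fixtures() serializes
# the set to .adl files, tiss_repository() loads it in memory.

# Value types deviate from plain text only where the domain demands it:
# encounter dates are DV_DATE_TIME (as in the published listings), monetary
# fields DV_MONEY, day/quantity fields DV_COUNT. The manifest records these.
element_kind <- function(label) {
  money <- c("unit cost", "total cost", "deduction", "total costs", "total rent",
             "total drugs", "total materials", "total hospital stay", "total gases",
             "total other rates", "total procedures", "total medicinal gases",
             "Total deduction")
  count <- c("quantity requested", "quantity authorized", "quantity performed",
             "requested number of days", "authorized number of days",
             "living term births", "premature living births", "still births",
             "early neonatal deaths", "late neonatal deaths")
  if (label %in% money) return("DV_MONEY")
  if (label %in% count) return("DV_COUNT")
  if (identical(label, "date of encounter")) return("DV_DATE_TIME")
  "DV_TEXT"
}

el_constraint <- function(node_id, label, occ = adl_interval(0, 1)) {
  c_object("ELEMENT", node_id, occ, label, attributes = list(
    c_attribute("value", children = list(c_primitive(element_kind(label))))
  ))
}

els_seq <- function(labels, first_code, occs = NULL) {
  codes <- sprintf("at%04d", seq(first_code, length.out = length(labels)))
  lapply(seq_along(labels), function(i) {
    occ <- if (!is.null(occs) && !is.null(occs[[labels[[i]]]])) {
      occs[[labels[[i]]]]
    } else {
      adl_interval(0, 1)
    }
    el_constraint(codes[[i]], labels[[i]], occ)
  })
}

cl_constraint <- function(node_id, label, children, occ = adl_interval(0, 1)) {
  c_object("CLUSTER", node_id, occ, label, attributes = list(
    c_attribute("items", adl_interval(0, Inf, ordered = FALSE), children)
  ))
}

items_attr <- function(children) {
  c_attribute("items", adl_interval(0, Inf, ordered = FALSE), children)
}

data_tree <- function(children) {
  c_attribute("data", children = list(
    c_object("ITEM_TREE", "at0001", adl_interval(1, 1), "components",
             attributes = list(items_attr(children)))
  ))
}

# -- care-entry and cluster archetype bodies --------------------------------

patient_evaluation_items <- function() {
  obstetrics <- cl_constraint("at0010", "obstetrics", c(
    els_seq(c("gestation", "abortion", "pregnancy-related problems",
              "puerperium complications", "neonatal assistance",
              "neonatal complication", "low birthweight", "cesarean section",
              "normal delivery", "maternal death"), 11),
    list(cl_constraint("at0021", "number of living births",
                       els_seq(c("living term births", "premature living births",
                                 "still births", "early neonatal deaths",
                                 "late neonatal deaths"), 22)))
  ))
  planned <- cl_constraint("at0030", "planned services", c(
    els_seq(c("type of procedure", "procedure", "quantity requested",
              "quantity authorized"), 31),
    list(cl_constraint("at0035", "orthoses and prostheses",
                       els_seq(c("vendor", "unit cost"), 36)))
  ), occ = adl_interval(0, Inf))
  c(
    els_seq(c("clinical indication", "type of disease", "duration of disease",
              "accident indication", "main diagnosis", "secondary diagnoses",
              "cause of death", "death certificate number"), 2,
            occs = list("secondary diagnoses" = adl_interval(0, Inf))),
    list(obstetrics, planned)
  )
}

odontologic_items <- function() {
  c(
    els_seq(c("periodontal disease", "alterations in soft tissues"), 2),
    list(cl_constraint("at0004", "initial status",
                       els_seq(c("tooth", "status"), 5),
                       occ = adl_interval(0, Inf)))
  )
}

claim_services_items <- function() {
  els_seq(c("type of procedure", "procedure", "quantity authorized",
            "quantity performed", "access", "technique", "vendor", "unit cost",
            "total cost", "percent of reduction/addition", "deduction",
            "tooth", "face"), 2)
}

admission_labels <- function() {
  c("type of admission", "probable date of admission", "hospital service",
    "admission regime", "requested number of days", "authorized number of days",
    "type of accommodation", "date of admission", "discharge date")
}

total_costs_labels <- function() {
  c("total costs", "total rent", "total drugs", "total materials",
    "total hospital stay", "total gases", "total other rates",
    "total procedures", "total medicinal gases", "Total deduction")
}

care_root <- function(rm_type, concept, label, items) {
  archetype_definition(
    archetype_id(rm_type, concept),
    c_object(rm_type, "at0000", adl_interval(1, 1), label,
             attributes = list(data_tree(items)))
  )
}

cluster_root <- function(concept, label, items) {
  archetype_definition(
    archetype_id("CLUSTER", concept),
    c_object("CLUSTER", "at0000", adl_interval(1, 1), label,
             attributes = list(items_attr(items)))
  )
}

# -- administrative archetypes ----------------------------------------------

admin_slot_includes <- function(concept, approach) {
  if (approach == 2L) {
    return(c("openEHR-EHR-CLUSTER.admission.v1", "openEHR-EHR-CLUSTER.total_costs.v1",
             "openEHR-EHR-CLUSTER.patient_evaluation.v1",
             "openEHR-EHR-CLUSTER.odontologic_evaluation.v1",
             "openEHR-EHR-CLUSTER.claim_services.v1"))
  }
  switch(concept,
    professional_claim = "openEHR-EHR-CLUSTER.total_costs.v1",
    # the published institutional-claim listings name the cost cluster
    # "costs"; the inventory calls it "total_costs" (aliased in the repo)
    institutional_claim = c("openEHR-EHR-CLUSTER.admission.v1",
                            "openEHR-EHR-CLUSTER.costs.v1"),
    authorization = "openEHR-EHR-CLUSTER.admission.v1",
    authorization_request = "openEHR-EHR-CLUSTER.admission.v1"
  )
}

admin_archetype <- function(concept, approach = 1L) {
  layout <- admin_layouts()[[concept]]
  occs <- NULL
  if (identical(concept, "institutional_claim")) {
    occs <- list("submission ID" = adl_interval(0, Inf),
                 "original submission" = adl_interval(0, Inf))
  }
  els <- lapply(seq_along(layout), function(i) {
    lab <- unname(layout[[i]])
    occ <- if (!is.null(occs) && !is.null(occs[[lab]])) occs[[lab]] else adl_interval(0, 1)
    el_constraint(names(layout)[[i]], lab, occ)
  })
  slot <- c_slot("CLUSTER", "at0015", adl_interval(0, Inf),
                 admin_slot_includes(concept, approach))
  archetype_definition(
    archetype_id("ADMIN_ENTRY", concept),
    c_object("ADMIN_ENTRY", "at0000", adl_interval(1, 1), "claim header",
             attributes = list(data_tree(c(els, list(slot)))))
  )
}

# Extended-model administrative archetypes. The institutional claim matches
# the published extended listing (status element retained at at0005, slot at
# at0010); the other element sets follow the extended-model inventory.
extended_admin_layouts <- function() {
  list(
    professional_claim = c(at0002 = "type of encounter",
                           at0003 = "date of encounter",
                           at0004 = "discharge reason", at0005 = "further action",
                           at0006 = "comments"),
    institutional_claim = c(at0002 = "type of encounter",
                            at0003 = "date of encounter", at0004 = "type of claim",
                            at0005 = "status", at0006 = "discharge reason",
                            at0007 = "further action", at0008 = "comments"),
    authorization = c(at0002 = "type of encounter", at0003 = "date of encounter",
                      at0004 = "comments"),
    authorization_request = c(at0002 = "type of encounter",
                              at0003 = "date of encounter", at0004 = "comments")
  )
}

extended_admin_archetype <- function(concept) {
  rm_type <- switch(concept,
    professional_claim = "PROFESSIONAL_CLAIM",
    institutional_claim = "INSTITUTIONAL_CLAIM",
    "AUTHORIZATION")
  layout <- extended_admin_layouts()[[concept]]
  els <- lapply(seq_along(layout), function(i) {
    el_constraint(names(layout)[[i]], unname(layout[[i]]))
  })
  slot <- c_slot("CLUSTER", "at0010", adl_interval(0, Inf),
                 admin_slot_includes(concept, 1L))
  archetype_definition(
    archetype_id(rm_type, concept),
    c_object(rm_type, "at0000", adl_interval(1, 1), "claim header",
             attributes = list(data_tree(c(els, list(slot)))))
  )
}

composition_archetype <- function(entry_ids) {
  archetype_definition(
    archetype_id("COMPOSITION", "tiss_claim"),
    c_object("COMPOSITION", "at0000", adl_interval(1, 1), "TISS claim",
             attributes = list(
               c_attribute("content", adl_interval(1, Inf, ordered = TRUE), list(
                 c_slot("ENTRY", "at0001", adl_interval(0, Inf), entry_ids)
               ))
             ))
  )
}

#' Build the archetype fixture sets
#'
#' `fixture_archetypes()` constructs in memory the ten archetypes of the
#' requested modelling approach: (1) rooted in the clinical ENTRY subtypes
#' plus four ADMIN_ENTRY claim archetypes and a composition archetype with a
#' slot for all of them; (2) the same content rooted exclusively in CLUSTER,
#' with the ADMIN_ENTRY archetypes accepting every cluster archetype in their
#' slot; (3) rooted in the extended-model claim classes
#' (PROFESSIONAL_CLAIM, INSTITUTIONAL_CLAIM, AUTHORIZATION), with the header
#' elements absorbed by the reference model removed. `build_fixtures()`
#' serializes the set to one UTF-8 `.adl` file per archetype plus a
#' `manifest.json` recording root classes and non-text value types, and
#' returns the ADL paths; every emitted file parses with [read_archetype()].
#' `tiss_repository()` wraps a set in an alias-aware repository.
#'
#' @param approach 1, 2 or 3.
#' @param outdir output directory (created if missing).
#' @return `fixture_archetypes()`: named list of definitions;
#'   `build_fixtures()`: character vector of `.adl` paths;
#'   `tiss_repository()`: an [archetype_repository()].
#' @export
fixture_archetypes <- function(approach = 1L) {
  approach <- as.integer(approach)
  if (!approach %in% 1:3) stop_tiss("approach must be 1, 2 or 3", "tiss_value_error")
  shared_clusters <- list(
    admission = cluster_root("admission", "admission", {
      labs <- admission_labels()
      els_seq(labs, 1)
    }),
    total_costs = cluster_root("total_costs", "total costs",
                               els_seq(total_costs_labels(), 1))
  )
  if (approach == 1L || approach == 3L) {
    care <- list(
      patient_evaluation = care_root("EVALUATION", "patient_evaluation",
                                     "patient evaluation", patient_evaluation_items()),
      odontologic_evaluation = care_root("EVALUATION", "odontologic_evaluation",
                                         "odontologic evaluation", odontologic_items()),
      claim_services = care_root("ACTION", "claim_services", "claim services",
                                 claim_services_items())
    )
  } else {
    care <- list(
      patient_evaluation = cluster_root("patient_evaluation", "patient evaluation",
                                        patient_evaluation_items()),
      odontologic_evaluation = cluster_root("odontologic_evaluation",
                                            "odontologic evaluation",
                                            odontologic_items()),
      claim_services = cluster_root("claim_services", "claim services",
                                    claim_services_items())
    )
  }
  admins <- if (approach == 3L) {
    lapply(stats::setNames(nm = admin_claim_concepts()), extended_admin_archetype)
  } else {
    lapply(stats::setNames(nm = admin_claim_concepts()), admin_archetype,
           approach = approach)
  }
  comp_ids <- if (approach == 2L) {
    vapply(admins, function(d) format(d$id), character(1))
  } else {
    vapply(c(care, admins), function(d) format(d$id), character(1))
  }
  out <- c(care, shared_clusters, admins,
           list(tiss_claim = composition_archetype(unname(comp_ids))))
  out
}

#' @rdname fixture_archetypes
#' @export
build_fixtures <- function(approach = 1L, outdir) {
  defs <- fixture_archetypes(approach)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- character()
  for (nm in names(defs)) {
    p <- file.path(outdir, paste0(nm, ".adl"))
    write_archetype(defs[[nm]], p)
    paths <- c(paths, p)
  }
  manifest <- lapply(defs, function(d) {
    kinds <- list()
    walk <- function(n) {
      if (n$kind == "object") {
        if (identical(n$rm_type, "ELEMENT")) {
          k <- element_kind(n$label %||% "")
          if (!identical(k, "DV_TEXT")) kinds[[n$label]] <<- k
        }
        for (a in n$attributes) for (ch in a$children) walk(ch)
      }
    }
    walk(d$root)
    list(id = format(d$id), root = d$root$rm_type, approach = approach,
         non_text_elements = kinds)
  })
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' @rdname fixture_archetypes
#' @export
tiss_repository <- function(approach = 1L) {
  archetype_repository(unname(fixture_archetypes(approach)))
}

# -- inventories -------------------------------------------------------------

#' Fixture inventories
#'
#' `inventory()` lists, per archetype of an approach, the top-level element
#' labels, the cluster labels and the slot includes, as a named list.
#' `rm_absorbed_labels()` gives, per administrative archetype, the header
#' element labels the extended reference model absorbs — into SUBMISSION /
#' CLAIM / AUTHORIZATION attributes, into the composition's ISM transition
#' (status), or into the class itself (a professional claim's type of claim).
#' The approach-1 and approach-3 inventories differ exactly by these sets.
#'
#' @param approach 1, 2 or 3.
#' @param concept an administrative archetype concept name.
#' @return named list / character vector of labels.
#' @export
inventory <- function(approach = 1L) {
  defs <- fixture_archetypes(approach)
  entries <- lapply(defs, function(d) {
    elements <- character()
    clusters <- character()
    includes <- character()
    walk <- function(n, top) {
      if (n$kind == "slot") {
        includes <<- c(includes, n$includes)
        return()
      }
      if (n$kind != "object") return()
      if (identical(n$rm_type, "ELEMENT")) {
        if (top) elements <<- c(elements, n$label)
        return()
      }
      if (identical(n$rm_type, "CLUSTER") && !identical(n$node_id, "at0000")) {
        clusters <<- c(clusters, n$label)
        for (a in n$attributes) for (ch in a$children) walk(ch, top = FALSE)
        return()
      }
      for (a in n$attributes) for (ch in a$children) walk(ch, top)
    }
    walk(d$root, top = TRUE)
    list(id = format(d$id), rm_type = d$root$rm_type,
         elements = elements, clusters = clusters, slot_includes = includes)
  })
  structure(list(approach = as.integer(approach), entries = entries),
            class = "tiss_inventory")
}

#' @rdname inventory
#' @export
rm_absorbed_labels <- function(concept) {
  switch(concept,
    professional_claim = c("original submission", "submission ID",
                           "submission date", "validity", "billing date",
                           "type of claim", "status"),
    institutional_claim = c("submission ID", "original submission",
                            "submission Date", "billing date"),
    authorization = c("original submission", "submission ID", "submission date",
                      "validity", "authorization date", "authorization number",
                      "status"),
    authorization_request = c("submission ID", "submission date", "status"),
    character()
  )
}

#' @export
print.tiss_inventory <- function(x, ...) {
  cat(sprintf("<fixture inventory> approach %d, %d archetype(s)\n",
              x$approach, length(x$entries)))
  for (e in x$entries) {
    cat(sprintf("  %s: %d element(s), %d cluster(s)\n", e$id,
                length(e$elements), length(e$clusters)))
  }
  invisible(x)
}
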