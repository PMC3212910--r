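# The eleven TISS form templates, reconstructed from the forms the standard
# defines: which archetypes each form selects follows the form semantics
# (consultations carry no obstetric data, admission forms carry the admission
# cluster, claim forms carry performed services and totals).

A1 <- function(concept) sprintf("openEHR-EHR-ADMIN_ENTRY.%s.v1", concept)
EV <- function(concept) sprintf("openEHR-EHR-EVALUATION.%s.v1", concept)
CL <- function(concept) sprintf("openEHR-EHR-CLUSTER.%s.v1", concept)
AC <- "openEHR-EHR-ACTION.claim_services.v1"
COMP <- "openEHR-EHR-COMPOSITION.tiss_claim.v1"

content_slot <- "/content[at0001]"
admin_cluster_slot <- function(id) sprintf("/content[%s]/data[at0001]/items[at0015]", id)
in_archetype <- function(id, rest) sprintf("/content[%s]%s", id, rest)

#' The eleven TISS form templates
#'
#' `tiss_form_names()` enumerates the forms; `tiss_templates()` builds the
#' corresponding template definitions over the approach-1 archetype set;
#' `build_templates()` writes them as `*.tpl.json` config files and returns
#' the paths.
#'
#' @param outdir output directory for the config files.
#' @return `tiss_templates()`: named list of [template_definition()] objects.
#' @export
tiss_form_names <- function() {
  c("individual claim", "consultation claim", "admission request",
    "admission authorization", "admission claim", "tests and procedures request",
    "tests and procedures authorization", "tests and procedures claim",
    "dental evaluation", "dental claim", "other charges")
}

#' @rdname tiss_form_names
#' @export
tiss_templates <- function() {
  prof <- A1("professional_claim")
  inst <- A1("institutional_claim")
  auth <- A1("authorization")
  req <- A1("authorization_request")
  pev <- EV("patient_evaluation")
  oev <- EV("odontologic_evaluation")

  tpls <- list(
    template_definition(
      "individual claim", COMP,
      slot_fills = stats::setNames(
        list(c(prof, pev, AC), CL("total_costs")),
        c(content_slot, admin_cluster_slot(prof))),
      code_bindings = stats::setNames(
        list(list(terminology_id = "local", codes = c("01", "02", "03"))),
        in_archetype(prof, "/data[at0001]/items[at0007]")),
      occurrence_overrides = stats::setNames(
        list("0..2"), in_archetype(pev, "/data[at0001]/items[at0007]"))
    ),
    template_definition(
      "consultation claim", COMP,
      slot_fills = stats::setNames(list(c(prof, pev)), content_slot),
      exclusions = c(
        in_archetype(pev, "/data[at0001]/items[at0008]"),
        in_archetype(pev, "/data[at0001]/items[at0009]"),
        in_archetype(pev, "/data[at0001]/items[at0010]")
      ),
      code_bindings = stats::setNames(
        list(list(terminology_id = "local", codes = c("01", "02", "03", "04"))),
        in_archetype(prof, "/data[at0001]/items[at0008]"))
    ),
    template_definition(
      "admission request", COMP,
      slot_fills = stats::setNames(
        list(c(req, pev), CL("admission")),
        c(content_slot, admin_cluster_slot(req)))
    ),
    template_definition(
      "admission authorization", COMP,
      slot_fills = stats::setNames(
        list(auth, CL("admission")),
        c(content_slot, admin_cluster_slot(auth)))
    ),
    template_definition(
      "admission claim", COMP,
      slot_fills = stats::setNames(
        list(c(inst, pev, AC), c(CL("admission"), CL("total_costs"))),
        c(content_slot, admin_cluster_slot(inst)))
    ),
    template_definition(
      "tests and procedures request", COMP,
      slot_fills = stats::setNames(list(c(req, pev)), content_slot),
      exclusions = in_archetype(pev, "/data[at0001]/items[at0010]")
    ),
    template_definition(
      "tests and procedures authorization", COMP,
      slot_fills = stats::setNames(list(auth), content_slot)
    ),
    template_definition(
      "tests and procedures claim", COMP,
      slot_fills = stats::setNames(
        list(c(prof, AC), CL("total_costs")),
        c(content_slot, admin_cluster_slot(prof)))
    ),
    template_definition(
      "dental evaluation", COMP,
      slot_fills = stats::setNames(list(c(req, oev)), content_slot)
    ),
    template_definition(
      "dental claim", COMP,
      slot_fills = stats::setNames(
        list(c(prof, oev, AC), CL("total_costs")),
        c(content_slot, admin_cluster_slot(prof))),
      code_bindings = stats::setNames(
        list(list(terminology_id = "local", codes = c("M", "D", "V", "L", "O"))),
        in_archetype(AC, "/data[at0001]/items[at0014]"))
    ),
    template_definition(
      "other charges", COMP,
      slot_fills = stats::setNames(
        list(c(inst, AC), CL("total_costs")),
        c(content_slot, admin_cluster_slot(inst)))
    )
  )
  stats::setNames(tpls, tiss_form_names())
}

#' @rdname tiss_form_names
#' @export
build_templates <- function(outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  tpls <- tiss_templates()
  paths <- character()
  for (nm in names(tpls)) {
    p <- file.path(outdir, paste0(gsub(" ", "_", nm), ".tpl.json"))
    write_template(tpls[[nm]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
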