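#' Archetype repositories
#'
#' A repository maps archetype identifiers to parsed definitions and carries
#' an alias table for identifiers that name the same archetype under two
#' spellings (the claim archetypes' cost-cluster slot includes
#' `openEHR-EHR-CLUSTER.costs.v1`, which the inventory lists as
#' `total_costs`). Lookup and include matching honor aliases; identifiers are
#' unique.
#'
#' @param defs list of [archetype_definition()] objects (ids required).
#' @param aliases named character vector, alias id -> canonical id.
#' @param repo a repository.
#' @param id an archetype id string (alias or short form accepted).
#' @param def an [archetype_definition()] to add.
#' @return `archetype_repository()` and `repo_add()` return the repository;
#'   `repo_get()` a definition or `NULL`; `repo_ids()` the canonical ids.
#' @export
archetype_repository <- function(defs = list(), aliases = tiss_aliases()) {
  repo <- structure(list(defs = list(), aliases = aliases),
                    class = "tiss_archetype_repository")
  for (d in defs) repo <- repo_add(repo, d)
  repo
}

#' @rdname archetype_repository
#' @export
tiss_aliases <- function() {
  c("openEHR-EHR-CLUSTER.costs.v1" = "openEHR-EHR-CLUSTER.total_costs.v1")
}

#' @rdname archetype_repository
#' @export
repo_add <- function(repo, def) {
  if (is.null(def$id)) {
    stop_tiss("cannot add an anonymous definition to a repository", "tiss_value_error")
  }
  id <- format(def$id)
  if (!is.null(repo$defs[[id]])) {
    stop_tiss(sprintf("duplicate archetype id '%s'", id), "tiss_value_error")
  }
  repo$defs[[id]] <- def
  repo
}

#' @rdname archetype_repository
#' @export
repo_resolve_id <- function(repo, id) {
  id <- normalize_archetype_id(id)
  hit <- repo$aliases[id]
  if (length(hit) == 1L && !is.na(hit)) unname(hit) else id
}

#' @rdname archetype_repository
#' @export
repo_get <- function(repo, id) {
  repo$defs[[repo_resolve_id(repo, id)]]
}

#' @rdname archetype_repository
#' @export
repo_ids <- function(repo) names(repo$defs)

#' @export
print.tiss_archetype_repository <- function(x, ...) {
  cat(sprintf("<archetype repository> %d archetype(s)\n", length(x$defs)))
  for (id in names(x$defs)) cat(" ", id, "\n")
  invisible(x)
}

# Same-archetype test under aliasing.
same_archetype <- function(repo, a, b) {
  identical(repo_resolve_id(repo, a), repo_resolve_id(repo, b))
}
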