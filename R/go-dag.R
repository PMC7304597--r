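#' Read a GO ontology from an OBO file
#'
#' Minimal OBO 1.2/1.4 reader keeping, per `[Term]` stanza, the id, name,
#' `is_a` parents and `relationship: part_of` parents. Obsolete terms are
#' dropped. Only the structure needed for ancestor propagation is retained.
#'
#' @param path Path to an OBO file.
#' @return An object of class `go_dag`: list with `terms` (character),
#'   `parents` (named list of character vectors) and `names` (named
#'   character vector of term labels).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "[Term]")
  if (!length(starts)) stop("no [Term] stanzas in ", path)
  bounds <- c(starts, length(lines) + 1L)
  terms <- character(); parents <- list(); labels <- character()
  for (i in seq_along(starts)) {
    blk <- lines[(bounds[[i]] + 1L):(bounds[[i + 1L]] - 1L)]
    blk <- blk[nzchar(blk) & !startsWith(blk, "[")]
    val <- function(key) sub(paste0("^", key, ": *"), "",
                             blk[startsWith(blk, paste0(key, ":"))])
    if (any(val("is_obsolete") == "true")) next
    id <- val("id")[1]
    if (is.na(id)) next
    isa <- sub(" *!.*$", "", val("is_a"))
    rel <- val("relationship")
    po <- sub(" *!.*$", "", sub("^part_of +", "", rel[startsWith(rel, "part_of")]))
    terms <- c(terms, id)
    parents[[id]] <- unique(c(isa, po))
    nm <- val("name")[1]
    labels[[id]] <- if (is.na(nm)) id else nm
  }
  missing <- setdiff(unlist(parents), terms)
  if (length(missing))
    stop("parent term(s) not defined in ontology: ",
         paste(utils::head(missing, 3), collapse = ", "))
  dag <- structure(list(terms = terms, parents = parents, names = labels),
                   class = "go_dag")
  .check_acyclic(dag)
  dag
}

.check_acyclic <- function(dag) {
  # Kahn-style peeling: repeatedly resolve terms all of whose parents are
  # resolved; leftovers imply a cycle.
  unresolved <- setNames(lengths(dag$parents[dag$terms]), dag$terms)
  children <- split(rep(dag$terms, lengths(dag$parents[dag$terms])),
                    unlist(dag$parents[dag$terms], use.names = FALSE))
  queue <- names(unresolved)[unresolved == 0L]
  done <- 0L
  while (length(queue)) {
    t <- queue[[length(queue)]]; queue <- queue[-length(queue)]
    done <- done + 1L
    for (ch in children[[t]]) {
      unresolved[[ch]] <- unresolved[[ch]] - 1L
      if (unresolved[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (done < length(dag$terms)) stop("cycle detected in GO DAG")
  invisible(TRUE)
}

#' Ancestors of GO terms in a DAG
#'
#' Transitive closure over `is_a`/`part_of` parents. Root terms (terms with
#' no parents) can be excluded, matching the convention that the ontology
#' root carries no information in enrichment testing.
#'
#' @param dag A `go_dag` from [read_obo()].
#' @param terms Character vector of term ids present in the DAG (ids absent
#'   from the DAG are ignored).
#' @param include_roots Keep root terms in the result.
#' @return Character vector of ancestor term ids (the input terms are not
#'   included).
#' @export
go_ancestors <- function(dag, terms, include_roots = TRUE) {
  seen <- character()
  frontier <- intersect(terms, dag$terms)
  while (length(frontier)) {
    up <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    up <- setdiff(up, seen)
    seen <- c(seen, up)
    frontier <- up
  }
  anc <- setdiff(seen, terms)
  if (!include_roots) {
    roots <- dag$terms[lengths(dag$parents[dag$terms]) == 0]
    anc <- setdiff(anc, roots)
  }
  anc
}
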