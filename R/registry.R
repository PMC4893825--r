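#' Load the consequence term registry
#'
#' The registry ships as a tabular data file (so_name, accession, parents,
#' rank, impact) curated from the Ensembl-era Sequence Ontology consequence
#' set; severity ranks follow the published ordering (1 = most severe).
#' Membership is data, not code: users may supply their own file with the same
#' columns.
#'
#' @param path optional path to an alternative registry file.
#' @return a \linkS4class{ConsequenceRegistry}.
#' @export
loadRegistry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "consequence_registry.tsv", package = "vcanno")
  tb <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "character",
                                         "integer", "character"))
  tb$parents[is.na(tb$parents)] <- ""
  new("ConsequenceRegistry", table = tb)
}

registryTable <- function(registry) registry@table

#' @export
termRank <- function(registry, terms) {
  r <- registry@table$rank[match(terms, registry@table$so_name)]
  if (anyNA(r)) stop("unknown consequence term: ",
                     paste(terms[is.na(r)], collapse = ", "))
  r
}

#' @export
termImpact <- function(registry, terms) {
  registry@table$impact[match(terms, registry@table$so_name)]
}

termAncestors <- function(registry, term) {
  tb <- registry@table
  par <- strsplit(tb$parents, ",", fixed = TRUE)
  names(par) <- tb$so_name
  out <- character(0)
  frontier <- par[[term]]
  frontier <- frontier[nzchar(frontier)]
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- unlist(par[frontier])
    frontier <- frontier[nzchar(frontier)]
  }
  out
}

#' Keep only the most specific term under any parent chain
#'
#' Removes every term that is an ancestor (through registry parent links) of
#' another term in the collection; terms on distinct ontology branches are all
#' retained.
#'
#' @param terms character vector of so_names (all must be in the registry).
#' @param registry a \linkS4class{ConsequenceRegistry}.
#' @export
mostSpecificTerms <- function(terms, registry) {
  if (length(terms) == 0L) return(character(0))
  terms <- unique(terms)
  if (!all(terms %in% registry@table$so_name))
    stop("unknown consequence term: ",
         paste(setdiff(terms, registry@table$so_name), collapse = ", "))
  anc <- unique(unlist(lapply(terms, termAncestors, registry = registry)))
  setdiff(terms, anc)
}

#' Most severe term (minimal severity rank)
#'
#' @param terms non-empty character vector of registry so_names.
#' @param registry a \linkS4class{ConsequenceRegistry}.
#' @export
mostSevere <- function(terms, registry) {
  if (length(terms) == 0L) stop("most severe term of an empty set is undefined")
  terms[which.min(termRank(registry, terms))]
}
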