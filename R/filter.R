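# Field-operator-value filter language over annotation results.
# Grammar: clause (AND|OR clause)*, AND binding tighter than OR; a clause is
# `field op value` (or `field exists`). No parentheses.

FILTER_OPS <- c("is", "eq", "=", "ne", "!=", "gt", ">", "lt", "<",
                "gte", ">=", "lte", "<=", "in", "matches", "exists")

filterTokens <- function(text) {
  # split on whitespace, honouring double quotes
  m <- regmatches(text, gregexpr('"[^"]*"|\\S+', text))[[1L]]
  gsub('^"|"$', "", m)
}

#' Parse a filter expression
#'
#' @param text e.g. \code{"AFR >0.1 AND EUR <0.05"} or
#'   \code{"Consequence is missense_variant"}; operators may be glued to
#'   their value (\code{">0.1"}). \code{in} accepts a filename (one value per
#'   line) or a comma-separated list; \code{matches} is a case-insensitive
#'   substring test; \code{exists} takes no value.
#' @return a FilterExpression: list of OR-groups, each a list of clauses.
#' @export
parseFilter <- function(text) {
  if (!nzchar(trimws(text))) stop("empty filter expression")
  toks <- filterTokens(text)
  # re-split tokens where a comparison operator is glued to its value
  expanded <- list()
  for (t in toks) {
    m <- regmatches(t, regexec("^(>=|<=|!=|>|<|=)(.+)$", t))[[1L]]
    if (length(m) && !t %in% FILTER_OPS)
      expanded <- c(expanded, m[2L], m[3L])
    else expanded <- c(expanded, t)
  }
  toks <- unlist(expanded)
  orGroups <- list(); andGroup <- list()
  i <- 1L
  n <- length(toks)
  while (i <= n) {
    field <- toks[i]
    if (toupper(field) %in% c("AND", "OR"))
      stop(sprintf("filter syntax error at token %d: unexpected '%s'", i, field))
    if (i + 1L > n) stop(sprintf("filter syntax error at token %d: operator expected", i + 1L))
    op <- tolower(toks[i + 1L])
    if (!op %in% FILTER_OPS)
      stop(sprintf("filter syntax error at token %d: unknown operator '%s'", i + 1L, toks[i + 1L]))
    if (op == "exists") {
      value <- NA_character_; i <- i + 2L
    } else {
      if (i + 2L > n) stop(sprintf("filter syntax error at token %d: value expected", i + 2L))
      value <- toks[i + 2L]; i <- i + 3L
    }
    andGroup[[length(andGroup) + 1L]] <- list(field = field, op = op, value = value)
    if (i <= n) {
      conj <- toupper(toks[i])
      if (conj == "AND") { i <- i + 1L }
      else if (conj == "OR") {
        orGroups[[length(orGroups) + 1L]] <- andGroup
        andGroup <- list(); i <- i + 1L
      } else stop(sprintf("filter syntax error at token %d: AND/OR expected, got '%s'", i, toks[i]))
    }
  }
  orGroups[[length(orGroups) + 1L]] <- andGroup
  structure(orGroups, class = "FilterExpression")
}

# Map a filter field name to a value within one result row (columns first,
# then extras keys); unresolvable fields evaluate false with a warning.
resolveField <- function(r, field) {
  alias <- c(consequence = "consequence", gene = "gene", feature = "feature",
             symbol = "gene_symbol", biotype = "biotype", allele = "allele",
             impact = "impact", location = "location", distance = "distance",
             hgvsc = "hgvsc", hgvsp = "hgvsp", hgvsg = "hgvsg",
             exon = "exon", intron = "intron",
             existing_variation = "existing_variation",
             uploaded_variation = "uploaded_variation",
             feature_type = "feature_type", strand = "strand",
             canonical = "canonical")
  key <- alias[tolower(field)]
  if (!is.na(key)) return(r[[key]])
  ex <- r$extras[[1L]]
  hit <- which(tolower(names(ex)) == tolower(field))
  if (length(hit)) return(ex[[hit[1L]]])
  NULL
}

evalClause <- function(r, cl) {
  v <- resolveField(r, cl$field)
  if (cl$op == "exists")
    return(!is.null(v) && !all(is.na(v)) && any(nzchar(as.character(v))))
  if (is.null(v)) {
    warning("filter field '", cl$field, "' does not resolve; clause is false",
            call. = FALSE)
    return(FALSE)
  }
  vs <- as.character(v)
  parts <- unlist(strsplit(vs, "[,&]"))
  # prediction fields print as "term(score)"; "is term" matches the term
  bare <- sub("\\([^)]*\\)$", "", parts)
  switch(cl$op,
    is = , eq = , `=` = any(parts == cl$value | bare == cl$value),
    ne = , `!=` = !any(parts == cl$value | bare == cl$value),
    matches = any(grepl(tolower(cl$value), tolower(parts), fixed = TRUE)),
    `in` = {
      vals <- if (file.exists(cl$value)) readLines(cl$value, warn = FALSE)
              else strsplit(cl$value, ",", fixed = TRUE)[[1L]]
      any(parts %in% vals)
    },
    {  # numeric comparators coerce; false on non-numeric fields
      num <- suppressWarnings(as.numeric(parts))
      num <- num[!is.na(num)]
      thr <- suppressWarnings(as.numeric(cl$value))
      if (!length(num) || is.na(thr)) return(FALSE)
      switch(cl$op,
        gt = , `>` = any(num > thr),
        lt = , `<` = any(num < thr),
        gte = , `>=` = any(num >= thr),
        lte = , `<=` = any(num <= thr),
        FALSE)
    })
}

#' Apply a parsed filter expression to results
#'
#' A row is kept when any OR-group has all its clauses true (AND binds
#' tighter than OR).
#' @export
applyFilter <- function(expr, results) {
  if (nrow(results) == 0L) return(results)
  keep <- vapply(seq_len(nrow(results)), function(i) {
    r <- results[i, , drop = FALSE]
    any(vapply(expr, function(grp)
      all(vapply(grp, function(cl) isTRUE(evalClause(r, cl)), logical(1))),
      logical(1)))
  }, logical(1))
  results[keep, , drop = FALSE]
}
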