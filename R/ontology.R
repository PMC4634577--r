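# OBO 1.2 ontology and GAF 2.x annotation readers.

GO_NAMESPACES <- c(MF = "molecular_function", BP = "biological_process",
                   CC = "cellular_component")

#' Load an OBO 1.2 ontology
#'
#' Parses `[Term]` stanzas into an [OntologyGraph-class]. Obsolete terms are
#' dropped (together with their edges); `alt_id`s are mapped to their
#' primary ids. Only `is_a` and `part_of` relationships are retained; a
#' cyclic graph is a fatal validation error.
#'
#' @param path Path to an OBO 1.2 file.
#' @return An [OntologyGraph-class].
#' @export
loadOBO <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "[Term]")
  if (!length(starts)) stop("no [Term] stanzas in '", path, "'")
  bounds <- c(starts, length(lines) + 1L)
  terms <- list(); edges <- list(); alt <- character(0)
  for (k in seq_along(starts)) {
    chunk <- lines[seq.int(starts[k] + 1L, bounds[k + 1L] - 1L)]
    chunk <- chunk[nzchar(chunk) & !startsWith(chunk, "[")]
    field <- function(tag) {
      v <- chunk[startsWith(chunk, paste0(tag, ":"))]
      trimws(sub("!.*$", "", sub(paste0("^", tag, ":"), "", v)))
    }
    id <- field("id")[1]
    if (is.na(id)) next
    if (any(field("is_obsolete") == "true")) next
    for (a in field("alt_id")) alt[a] <- id
    ns <- field("namespace")[1]
    nm <- field("name")[1]
    terms[[length(terms) + 1L]] <- data.frame(
      id = id, name = ifelse(is.na(nm), id, nm),
      namespace = ifelse(is.na(ns), NA_character_, ns),
      stringsAsFactors = FALSE)
    for (p in field("is_a")) {
      edges[[length(edges) + 1L]] <- data.frame(
        child = id, parent = p, relation = "is_a", stringsAsFactors = FALSE)
    }
    for (rel in field("relationship")) {
      parts <- strsplit(trimws(rel), "[[:space:]]+")[[1]]
      if (length(parts) >= 2L && parts[1] == "part_of") {
        edges[[length(edges) + 1L]] <- data.frame(
          child = id, parent = parts[2], relation = "part_of",
          stringsAsFactors = FALSE)
      }
    }
  }
  termDf <- do.call(rbind, terms)
  edgeDf <- if (length(edges)) do.call(rbind, edges) else
    data.frame(child = character(), parent = character(),
               relation = character(), stringsAsFactors = FALSE)
  # drop edges to obsolete/unknown terms
  edgeDf <- edgeDf[edgeDf$parent %in% termDf$id &
                   edgeDf$child %in% termDf$id, , drop = FALSE]
  new("OntologyGraph", terms = termDf, edges = edgeDf, altIds = alt)
}

# Resolve possibly-alternative ids to primary ids; unknown terms error.
.resolveTerms <- function(ids, graph) {
  out <- ids
  isAlt <- out %in% names(graph@altIds)
  out[isAlt] <- graph@altIds[out[isAlt]]
  bad <- !(out %in% graph@terms$id)
  if (any(bad)) stop("unknown ontology term(s): ",
                     paste(ids[bad], collapse = ", "))
  out
}

.termNamespace <- function(ids, graph) {
  graph@terms$namespace[match(ids, graph@terms$id)]
}

#' Load GO annotations from a GAF 2.x file
#'
#' Reads a tab-separated GAF 2.x annotation file (comment lines start with
#' `!`) and returns, per annotated object, the GO term sets split by
#' annotation domain. Alternative ids are resolved against the ontology and
#' terms missing from it are dropped with a warning.
#'
#' @param path Path to a GAF 2.x file.
#' @param graph An [OntologyGraph-class] from [loadOBO()].
#' @return Named list (by DB object id) of lists with `MF`, `BP`, `CC`
#'   character vectors.
#' @export
loadGAF <- function(path, graph) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (!length(lines)) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  obj <- vapply(fields, `[`, character(1), 2L)
  go <- vapply(fields, `[`, character(1), 5L)
  aspect <- vapply(fields, `[`, character(1), 9L)
  ns <- c(F = "MF", P = "BP", C = "CC")[aspect]
  known <- go %in% graph@terms$id | go %in% names(graph@altIds)
  if (any(!known)) {
    warning(sum(!known), " GAF term(s) absent from the ontology dropped")
  }
  keep <- known & !is.na(ns)
  obj <- obj[keep]; go <- .resolveTerms(go[keep], graph); ns <- ns[keep]
  out <- list()
  for (o in unique(obj)) {
    sel <- obj == o
    out[[o]] <- lapply(c(MF = "MF", BP = "BP", CC = "CC"), function(d) {
      unique(go[sel & ns == d])
    })
  }
  out
}
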