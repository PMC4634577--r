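# Reading residues from PDB-format coordinate files.

#' Read residues from a PDB file
#'
#' Parses a PDB-format coordinate file (first model only) into
#' [Residue-class] objects keyed by `"<chain>|<seqPos>"`, where `seqPos` is
#' the author residue number with any insertion code appended. Hydrogen (and
#' deuterium) atoms are dropped. When alternate locations are present, only
#' the highest-occupancy altloc of each atom is kept; occupancy ties break
#' toward altloc `"A"`. Non-standard residues are retained; use
#' [isCanonical()] to flag them. Residues without a C-alpha atom are kept
#' here and rejected later during curation.
#'
#' @param path Path to a PDB-format file.
#' @return Named list of [Residue-class] objects.
#' @export
readStructure <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  # drop hydrogens/deuteriums by element symbol (fall back to name prefix)
  elem <- toupper(trimws(at$elesy))
  noElem <- is.na(elem) | !nzchar(elem)
  elem[noElem] <- substr(gsub("[0-9]", "", trimws(at$elety[noElem])), 1, 1)
  at <- at[!(elem %in% c("H", "D")), , drop = FALSE]
  if (!nrow(at)) stop("no heavy atoms in '", path, "'")
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  rkey <- paste(at$chain, paste0(at$resno, at$insert), sep = "|")
  # altloc resolution per (residue, atom name): highest occupancy, tie -> 'A'
  akey <- paste(rkey, at$elety, sep = "|")
  ord <- order(akey, -at$o, at$alt != "A", at$alt)
  keep <- ord[!duplicated(akey[ord])]
  at <- at[sort(keep), , drop = FALSE]   # preserve file order of kept atoms
  rkey <- paste(at$chain, paste0(at$resno, at$insert), sep = "|")
  elem <- toupper(trimws(at$elesy))
  out <- list()
  for (key in unique(rkey)) {
    sel <- rkey == key
    sub <- at[sel, , drop = FALSE]
    out[[key]] <- residue(
      aa = sub$resid[1L], chainId = sub$chain[1L],
      seqPos = paste0(sub$resno[1L], sub$insert[1L]),
      atoms = data.frame(name = sub$elety, element = elem[sel],
                         x = sub$x, y = sub$y, z = sub$z,
                         stringsAsFactors = FALSE)
    )
  }
  out
}

#' Load catalytic-site definitions against structures
#'
#' Resolves a CSA-style site table (columns `site_id`, `struct_id`, `chain`,
#' `seq_pos`, `res_type`) against coordinates. Rows whose residue cannot be
#' found, lacks a C-alpha atom, or whose residue type disagrees with the
#' structure are recorded as inconsistencies for the curation stage (the
#' offending residue is dropped from the site).
#'
#' @param table Path to a tab-separated site table, or a data.frame with the
#'   columns above.
#' @param structures Either a named list of residue maps from
#'   [readStructure()] (names = structure ids) or a directory containing
#'   `<struct_id>.pdb` files.
#' @return List with `sites` (list of [CatalyticSite-class]) and
#'   `inconsistencies` (data.frame of `site_id`, `struct_id`, `chain`,
#'   `seq_pos`, `problem`).
#' @export
loadSiteDefinitions <- function(table, structures) {
  tab <- if (is.character(table)) {
    utils::read.table(table, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, colClasses = "character")
  } else {
    table
  }
  need <- c("site_id", "struct_id", "chain", "seq_pos", "res_type")
  if (!all(need %in% names(tab))) {
    stop("site table needs columns: ", paste(need, collapse = ", "))
  }
  getStructure <- local({
    cache <- list()
    function(id) {
      if (!is.null(cache[[id]])) return(cache[[id]])
      s <- if (is.list(structures)) {
        structures[[id]]
      } else {
        f <- file.path(structures, paste0(id, ".pdb"))
        if (file.exists(f)) readStructure(f) else NULL
      }
      cache[[id]] <<- s
      s
    }
  })
  sites <- list()
  inc <- list()
  note <- function(row, problem) {
    inc[[length(inc) + 1L]] <<- data.frame(
      site_id = row$site_id, struct_id = row$struct_id, chain = row$chain,
      seq_pos = row$seq_pos, problem = problem, stringsAsFactors = FALSE)
  }
  for (sid in unique(tab$site_id)) {
    rows <- tab[tab$site_id == sid, , drop = FALSE]
    resl <- list()
    for (r in seq_len(nrow(rows))) {
      row <- rows[r, , drop = FALSE]
      str <- getStructure(row$struct_id)
      if (is.null(str)) {
        note(row, "structure_not_found")
        next
      }
      key <- paste(row$chain, row$seq_pos, sep = "|")
      res <- str[[key]]
      if (is.null(res)) {
        note(row, "residue_not_found")
        next
      }
      if (!identical(toupper(res@aa), toupper(row$res_type))) {
        note(row, "residue_type_mismatch")
        next
      }
      if (!("CA" %in% res@atoms$name)) {
        note(row, "missing_ca")
        next
      }
      resl[[length(resl) + 1L]] <- res
    }
    sites[[length(sites) + 1L]] <- catalyticSite(
      siteId = sid, structId = rows$struct_id[1L], residues = resl)
  }
  inconsistencies <- if (length(inc)) {
    do.call(rbind, inc)
  } else {
    data.frame(site_id = character(), struct_id = character(),
               chain = character(), seq_pos = character(),
               problem = character(), stringsAsFactors = FALSE)
  }
  list(sites = sites, inconsistencies = inconsistencies)
}

#' Load a SCOP-style classification table
#'
#' Reads a tab-separated table with columns `struct_id`, `chain`, `sccs` and
#' extracts the superfamily as the first three dot-separated fields of the
#' sccs code (e.g. `"c.1.8.1"` gives `"c.1.8"`). Malformed sccs codes are
#' skipped with a warning.
#'
#' @param path Path to the table, or an equivalent data.frame.
#' @return Named character vector mapping `"<struct_id>|<chain>"` to
#'   superfamily id.
#' @export
loadScopTable <- function(path) {
  tab <- if (is.character(path)) {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, colClasses = "character")
  } else {
    path
  }
  if (!all(c("struct_id", "chain", "sccs") %in% names(tab))) {
    stop("SCOP table needs columns struct_id, chain, sccs")
  }
  ok <- grepl("^[a-z]\\.[0-9]+\\.[0-9]+(\\.[0-9]+)?$", tab$sccs)
  if (any(!ok)) {
    warning(sum(!ok), " SCOP record(s) with malformed sccs skipped")
    tab <- tab[ok, , drop = FALSE]
  }
  sf <- vapply(strsplit(tab$sccs, ".", fixed = TRUE),
               function(x) paste(x[1:3], collapse = "."), character(1))
  stats::setNames(sf, paste(tab$struct_id, tab$chain, sep = "|"))
}

#' Attach EC, SCOP and GO annotations to sites
#'
#' @param sites List of [CatalyticSite-class] objects.
#' @param scop Named character vector from [loadScopTable()] (keys
#'   `"<struct_id>|<chain>"`); matched via each site's structure id and the
#'   chain of its residues.
#' @param ec data.frame with columns `site_id`, `ec` (one row per EC
#'   number), or a named list mapping site id to EC character vectors.
#' @param go Named list mapping site id to a named list of GO term vectors
#'   per namespace (`MF`/`BP`/`CC`), e.g. from [loadGAF()].
#' @return The annotated site list.
#' @export
annotateSites <- function(sites, scop = NULL, ec = NULL, go = NULL) {
  ecMap <- NULL
  if (!is.null(ec)) {
    ecMap <- if (is.data.frame(ec)) split(ec$ec, ec$site_id) else ec
  }
  lapply(sites, function(s) {
    if (!is.null(scop)) {
      chains <- unique(vapply(s@residues, function(r) r@chainId,
                              character(1)))
      hit <- scop[paste(s@structId, chains, sep = "|")]
      hit <- hit[!is.na(hit)]
      s@superfamily <- if (length(hit)) unname(hit[1L]) else NA_character_
    }
    if (!is.null(ecMap)) {
      s@ec <- as.character(ecMap[[s@siteId]] %||% character())
    }
    if (!is.null(go)) {
      s@go <- go[[s@siteId]] %||% list()
    }
    s
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
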