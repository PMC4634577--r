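# Emit synthetic data in the same plain-text formats the real pipeline
# consumes (PDB, site/SCOP/EC TSV, OBO, GAF).

.pdbAtomLine <- function(serial, name, resid, chain, resno, x, y, z,
                         occ = 1, b = 0, element = "") {
  nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, "", resid, chain, as.integer(resno), "", x, y, z,
          occ, b, element)
}

#' Write a site as a PDB-format file
#'
#' @param site A [CatalyticSite-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeSitePDB <- function(site, path) {
  lines <- character(0)
  serial <- 0L
  for (r in site@residues) {
    for (k in seq_len(nrow(r@atoms))) {
      serial <- serial + 1L
      lines <- c(lines, .pdbAtomLine(
        serial, r@atoms$name[k], r@aa, r@chainId, r@seqPos,
        r@atoms$x[k], r@atoms$y[k], r@atoms$z[k],
        element = r@atoms$element[k]))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write an ontology as OBO 1.2
#'
#' @param graph An [OntologyGraph-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeOBO <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (k in seq_len(nrow(graph@terms))) {
    t <- graph@terms[k, ]
    writeLines(c("[Term]", paste0("id: ", t$id), paste0("name: ", t$name),
                 paste0("namespace: ", t$namespace)), con)
    e <- graph@edges[graph@edges$child == t$id, , drop = FALSE]
    for (q in seq_len(nrow(e))) {
      if (e$relation[q] == "is_a") {
        writeLines(paste0("is_a: ", e$parent[q]), con)
      } else {
        writeLines(paste0("relationship: part_of ", e$parent[q]), con)
      }
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Write synthetic data as pipeline input files
#'
#' Emits one PDB file per site plus `sites.tsv`, `scop.tsv`, `ec.tsv`,
#' `ontology.obo` and `annotations.gaf` into a directory, so that the full
#' file-based pipeline (structure reading, site resolution, annotation,
#' curation, comparison) can be exercised end to end.
#'
#' @param sim Output of [makeSites()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSyntheticFixtures <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  siteRows <- list(); scopRows <- list(); ecRows <- list(); gafRows <- list()
  for (s in sim$sites) {
    writeSitePDB(s, file.path(dir, paste0(s@structId, ".pdb")))
    for (r in s@residues) {
      siteRows[[length(siteRows) + 1L]] <- data.frame(
        site_id = s@siteId, struct_id = s@structId, chain = r@chainId,
        seq_pos = r@seqPos, res_type = r@aa, stringsAsFactors = FALSE)
    }
    scopRows[[length(scopRows) + 1L]] <- data.frame(
      struct_id = s@structId, chain = "A",
      sccs = paste0(s@superfamily, ".1"), stringsAsFactors = FALSE)
    for (e in s@ec) {
      ecRows[[length(ecRows) + 1L]] <- data.frame(
        site_id = s@siteId, ec = e, stringsAsFactors = FALSE)
    }
    asp <- c(MF = "F", BP = "P", CC = "C")
    for (ns in names(s@go)) {
      for (term in s@go[[ns]]) {
        gafRows[[length(gafRows) + 1L]] <- paste(
          "SYN", s@siteId, s@siteId, "", term, "SYN:0000001", "IDA", "",
          asp[[ns]], "synthetic enzyme", "", "protein", "taxon:0", "20260101",
          "SYN", "", "", sep = "\t")
      }
    }
  }
  utils::write.table(do.call(rbind, siteRows), file.path(dir, "sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, scopRows), file.path(dir, "scop.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, ecRows), file.path(dir, "ec.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeOBO(sim$ontology, file.path(dir, "ontology.obo"))
  writeLines(c("!gaf-version: 2.1", unlist(gafRows)),
             file.path(dir, "annotations.gaf"))
  invisible(dir)
}
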