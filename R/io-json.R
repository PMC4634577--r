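# JSON interchange for curated site collections.

#' Write / read a site collection as JSON
#'
#' Serializes a list of [CatalyticSite-class] objects (residues, atom
#' coordinates at full precision, EC/SCOP/GO labels) to a JSON interchange
#' file and back. `readSitesJSON(writeSitesJSON(sites, f))` reproduces all
#' field values.
#'
#' @param sites List of [CatalyticSite-class] objects.
#' @param path Output (input) file path.
#' @return `writeSitesJSON` returns `path` invisibly; `readSitesJSON`
#'   returns the site list.
#' @export
writeSitesJSON <- function(sites, path) {
  payload <- lapply(sites, function(s) {
    list(
      site_id = s@siteId,
      struct_id = s@structId,
      ec = as.list(s@ec),
      superfamily = if (is.na(s@superfamily)) NULL else s@superfamily,
      go = lapply(s@go, as.list),
      residues = lapply(s@residues, function(r) {
        list(aa = r@aa, chain_id = r@chainId, seq_pos = r@seqPos,
             atoms = list(name = as.list(r@atoms$name),
                          element = as.list(r@atoms$element),
                          x = r@atoms$x, y = r@atoms$y, z = r@atoms$z))
      })
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeSitesJSON
#' @export
readSitesJSON <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(s) {
    res <- lapply(s$residues, function(r) {
      residue(r$aa, r$chain_id, r$seq_pos, data.frame(
        name = unlist(r$atoms$name), element = unlist(r$atoms$element),
        x = as.numeric(unlist(r$atoms$x)),
        y = as.numeric(unlist(r$atoms$y)),
        z = as.numeric(unlist(r$atoms$z)), stringsAsFactors = FALSE))
    })
    go <- lapply(s$go, function(v) as.character(unlist(v)))
    catalyticSite(
      siteId = s$site_id, structId = s$struct_id, residues = res,
      ec = as.character(unlist(s$ec)),
      superfamily = if (is.null(s$superfamily)) NA_character_
                    else s$superfamily,
      go = go)
  })
}
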