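# Building the analysis-ready site set via the exclusion cascade.

CURATION_REASONS <- c("single_residue", "non_canonical", "multi_chain",
                      "no_ec", "multifunctional", "no_scop", "inconsistent")

.isFullEC <- function(ec) {
  grepl("^[1-7]\\.[0-9]+\\.[0-9]+\\.[0-9]+$", ec)
}

#' Curate a catalytic-site collection
#'
#' Applies the exclusion cascade that defines the analysis-ready set, in
#' fixed order: (1) sites of a single residue, (2) sites containing a
#' non-canonical residue, (3) sites whose residues span more than one chain,
#' (4) sites without a full (4-field) EC number, (5) multifunctional sites
#' (more than one full EC number), (6) sites without a SCOP superfamily,
#' (7) sites flagged inconsistent between the site table and the
#' coordinates. Each excluded site is logged under the first filter it
#' violates, so the per-reason counts are disjoint and
#' `retained + sum(excluded) = input`.
#'
#' @param sites List of annotated [CatalyticSite-class] objects (see
#'   [annotateSites()]).
#' @param inconsistent Character vector of site ids flagged inconsistent
#'   (e.g. from [loadSiteDefinitions()]'s `inconsistencies$site_id`).
#' @return List with `retained` (sites passing all filters) and `log`, a
#'   list with per-reason `counts` (named integer vector over all seven
#'   reasons) and `siteIds` (named list of excluded ids per reason).
#' @export
curateSites <- function(sites, inconsistent = character()) {
  reason <- vapply(sites, function(s) {
    n <- length(s@residues)
    if (n <= 1L) return("single_residue")
    aa <- vapply(s@residues, function(r) r@aa, character(1))
    if (!all(isCanonical(aa))) return("non_canonical")
    chains <- vapply(s@residues, function(r) r@chainId, character(1))
    if (length(unique(chains)) > 1L) return("multi_chain")
    full <- s@ec[.isFullEC(s@ec)]
    if (length(full) == 0L) return("no_ec")
    if (length(unique(full)) > 1L) return("multifunctional")
    if (is.na(s@superfamily)) return("no_scop")
    if (s@siteId %in% inconsistent) return("inconsistent")
    ""
  }, character(1))
  keep <- reason == ""
  countsV <- stats::setNames(integer(length(CURATION_REASONS)),
                             CURATION_REASONS)
  idsV <- stats::setNames(vector("list", length(CURATION_REASONS)),
                          CURATION_REASONS)
  ids <- vapply(sites, siteId, character(1))
  for (rn in CURATION_REASONS) {
    hit <- reason == rn
    countsV[[rn]] <- sum(hit)
    idsV[[rn]] <- ids[hit]
  }
  list(retained = sites[keep],
       log = list(counts = countsV, siteIds = idsV))
}

#' Descriptive statistics of site sizes
#'
#' @param sites List of [CatalyticSite-class] objects, or an integer vector
#'   of residue counts per site.
#' @return List with `mean` (1 decimal), `min`, `max`, `histogram` (table of
#'   residue counts) and `pctAtMin`, the percentage of sites at the minimum
#'   size (1 decimal).
#' @examples
#' siteStatistics(c(2L, 3L, 4L))
#' @export
siteStatistics <- function(sites) {
  sizes <- if (is.numeric(sites)) {
    as.integer(sites)
  } else {
    vapply(sites, length, integer(1))
  }
  if (!length(sizes)) stop("site statistics are undefined for an empty set")
  list(
    mean = roundHalfUp(mean(sizes), 1),
    min = min(sizes),
    max = max(sizes),
    histogram = table(sizes),
    pctAtMin = roundHalfUp(100 * mean(sizes == min(sizes)), 1)
  )
}
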