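# Census of non-homologous isofunctional enzymes (NISE): how many SCOP
# superfamilies realize each enzymatic function, and EC-class compositions.

#' Select enzymes eligible for the superfamily census
#'
#' Keeps single-domain enzymes carrying exactly one full (4-field) EC
#' number.
#'
#' @param records data.frame with columns `enzyme_id`, `domain_count`, `ec`
#'   (semicolon-separated EC numbers) and `superfamily`.
#' @return The filtered data.frame with a single `ec` string per row.
#' @export
selectCensusEnzymes <- function(records) {
  ecl <- strsplit(records$ec, ";", fixed = TRUE)
  full <- lapply(ecl, function(v) unique(v[.isFullEC(trimws(v))]))
  keep <- records$domain_count == 1L &
    vapply(ecl, function(v) length(unique(trimws(v))), integer(1)) == 1L &
    vapply(full, length, integer(1)) == 1L
  out <- records[keep, , drop = FALSE]
  out$ec <- vapply(full[keep], `[`, character(1), 1L)
  rownames(out) <- NULL
  out
}

#' Superfamily census per enzymatic function
#'
#' Groups enzymes by the first `ecLevel` fields of their EC number and
#' counts, per function, the number of distinct SCOP superfamilies realizing
#' it. Functions found in two or more superfamilies are candidate
#' non-homologous isofunctional enzymes.
#'
#' @param records Filtered records from [selectCensusEnzymes()].
#' @param ecLevel 4 (substrate-specific function) or 3 (reaction).
#' @return List with `ecLevel`, `perFunction` (named integer vector of
#'   superfamily counts), `histogram` (table over superfamily counts) and
#'   `fractions`: share of functions with exactly one, with two or more, and
#'   with five or more superfamilies.
#' @export
censusSuperfamilies <- function(records, ecLevel = 4L) {
  stopifnot(ecLevel %in% c(3L, 4L))
  key <- vapply(strsplit(records$ec, ".", fixed = TRUE), function(x)
    paste(x[seq_len(ecLevel)], collapse = "."), character(1))
  per <- vapply(split(records$superfamily, key), function(sf)
    length(unique(sf)), integer(1))
  list(
    ecLevel = ecLevel,
    perFunction = per,
    histogram = table(per),
    fractions = c(one = mean(per == 1L), twoPlus = mean(per >= 2L),
                  fivePlus = mean(per >= 5L))
  )
}

#' EC-class composition of two enzyme sets
#'
#' Computes, for each of the six EC classes, the fraction of enzymes in each
#' set and the ratio of the two fractions (set1 / set2). A ratio is `NA`
#' when the class is absent from `set2`.
#'
#' @param ec1,ec2 Character vectors of EC numbers (first field used).
#' @return data.frame with columns `class`, `frac1`, `frac2`, `ratio`.
#' @export
ecClassComposition <- function(ec1, ec2) {
  stopifnot(length(ec1) > 0, length(ec2) > 0)
  cls <- as.character(1:6)
  f1 <- vapply(cls, function(k) mean(substr(ec1, 1, 1) == k), numeric(1))
  f2 <- vapply(cls, function(k) mean(substr(ec2, 1, 1) == k), numeric(1))
  data.frame(class = as.integer(cls), frac1 = f1, frac2 = f2,
             ratio = ifelse(f2 == 0, NA_real_, f1 / f2))
}
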