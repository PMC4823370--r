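## GC-MS profiling normalization, matrix back-filling, and percent-of-reference
## group summaries.

#' Normalize a raw profiling intensity
#'
#' Divides the quantitation-ion intensity by the internal-standard intensity
#' and the sample protein content.
#'
#' @param raw raw quantitation-ion intensity
#' @param isIntensity internal-standard intensity (> 0)
#' @param protein protein content in mg (> 0)
#' @return normalized abundance (arbitrary units per mg protein)
#' @examples
#' normalizeAbundance(1000, 1000, 1)
#' @export
normalizeAbundance <- function(raw, isIntensity, protein) {
  if (any(isIntensity <= 0)) stop("internal-standard intensity must be > 0")
  if (any(protein <= 0)) stop("protein must be > 0")
  raw / isIntensity / protein
}

#' Back-fill missing values in a study table
#'
#' Replaces missing (NA) values per metabolite with a floor value, by
#' default half the minimum observed value of that metabolite, so that all
#' metabolites have a numerical value for all samples. Fill events are
#' recorded in the `fills` attribute of the result.
#'
#' @param table long-format data.frame with at least `sample`, `metabolite`,
#'   `value` columns
#' @param floorFraction floor as a fraction of the minimum observed value
#'   (default 0.5, half-minimum imputation)
#' @return the table with no missing values; `attr(, "fills")` lists the
#'   filled (sample, metabolite) pairs and the fill values
#' @export
backfillMatrix <- function(table, floorFraction = 0.5) {
  stopifnot(all(c("sample", "metabolite", "value") %in% names(table)))
  fills <- list()
  for (met in unique(table$metabolite)) {
    rows <- which(table$metabolite == met)
    vals <- table$value[rows]
    if (all(is.na(vals)))
      stop("metabolite entirely missing, cannot back-fill: ", met)
    miss <- rows[is.na(vals)]
    if (!length(miss)) next
    floor <- floorFraction * min(vals, na.rm = TRUE)
    table$value[miss] <- floor
    fills[[met]] <- data.frame(sample = table$sample[miss], metabolite = met,
                               value = floor)
  }
  attr(table, "fills") <- if (length(fills))
    do.call(rbind, c(fills, list(make.row.names = FALSE)))
  else data.frame(sample = character(0), metabolite = character(0),
                  value = numeric(0))
  table
}

#' Per-metabolite group means as percent of a reference line
#'
#' For each metabolite and cell line, the group mean expressed as a
#' percentage of the reference line's mean, with SEM propagated by the
#' delta method for the ratio of independent means. The reference line
#' itself is reported as exactly 100 with its own relative SEM.
#'
#' @param table long-format data.frame with `line`, `metabolite`, `value`
#' @param reference reference line name (must have >= 2 samples per
#'   metabolite)
#' @return data.frame: metabolite, line, percent, sem, n
#' @export
percentOfReference <- function(table, reference) {
  stopifnot(all(c("line", "metabolite", "value") %in% names(table)))
  if (!reference %in% table$line) stop("reference line not present: ", reference)
  out <- list()
  for (met in unique(table$metabolite)) {
    sub <- table[table$metabolite == met, ]
    ref <- sub$value[sub$line == reference]
    if (length(ref) < 2L) stop("reference line needs >= 2 samples for ", met)
    mRef <- mean(ref)
    if (mRef == 0) stop("zero reference mean for ", met)
    semRef <- stats::sd(ref) / sqrt(length(ref))
    for (ln in unique(sub$line)) {
      v <- sub$value[sub$line == ln]
      mX <- mean(v)
      semX <- stats::sd(v) / sqrt(length(v))
      if (ln == reference) {
        pct <- 100
        sem <- 100 * semRef / mRef
      } else {
        pct <- 100 * mX / mRef
        ## delta method for the ratio of two independent means
        sem <- 100 / abs(mRef) * sqrt(semX^2 + (mX / mRef)^2 * semRef^2)
      }
      out[[paste(met, ln)]] <- data.frame(metabolite = met, line = ln,
                                          percent = pct, sem = sem,
                                          n = length(v))
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
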