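## Stage conveniences: apply the correction / quantification operations
## across whole long-format tables.

#' Natural-abundance-correct a GC-MS isotopologue table
#'
#' Applies [correctMid()] per (sample, metabolite, fragment) group using the
#' fragment library, and computes both enrichment conventions.
#'
#' @param gcms long data.frame: sample_id, metabolite, fragment_id, shift,
#'   intensity (plus any metadata columns, carried through)
#' @param library fragment library data.frame; default the shipped TBDMS set
#' @return list with `mids` (corrected long table: sample_id, metabolite,
#'   fragment_id, shift, value, corrected, residual) and `enrichments`
#'   (per sample x metabolite: enrichmentAtom, enrichmentLabeled)
#' @export
correctMidTable <- function(gcms, library = readFragmentLibrary()) {
  .requireColumns(gcms, c("sample_id", "metabolite", "fragment_id", "shift",
                          "intensity"), "GC-MS isotopologue table")
  keys <- unique(gcms[, c("sample_id", "metabolite", "fragment_id")])
  meta_cols <- intersect(c("line", "tracer"), names(gcms))
  mids <- list(); enr <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- gcms$sample_id == keys$sample_id[i] &
      gcms$metabolite == keys$metabolite[i] &
      gcms$fragment_id == keys$fragment_id[i]
    sub <- gcms[sel, ]
    sub <- sub[order(sub$shift), ]
    frag <- library[library$fragment_id == keys$fragment_id[i], ]
    if (nrow(frag) != 1L)
      stop("fragment not in library: ", keys$fragment_id[i])
    cm <- .cachedCorrectionMatrix(frag$formula, frag$n_backbone,
                                  frag$fragment_id)
    mid <- correctMid(sub$intensity, cm, metabolite = keys$metabolite[i])
    row <- .df(sample_id = keys$sample_id[i], metabolite = keys$metabolite[i],
               fragment_id = keys$fragment_id[i],
               shift = 0:mid@nBackbone, value = mid@fractions,
               corrected = TRUE, residual = attr(mid, "residual"))
    erow <- .df(sample_id = keys$sample_id[i], metabolite = keys$metabolite[i],
                enrichmentAtom = fractionalEnrichment(mid),
                enrichmentLabeled = fractionalEnrichment(mid, "labeled-fraction"))
    for (mc in meta_cols) {
      row[[mc]] <- sub[[mc]][1L]
      erow[[mc]] <- sub[[mc]][1L]
    }
    mids[[i]] <- row; enr[[i]] <- erow
  }
  list(mids = do.call(rbind, c(mids, list(make.row.names = FALSE))),
       enrichments = do.call(rbind, c(enr, list(make.row.names = FALSE))))
}

#' Tracer-source fractions from an NMR integral table
#'
#' Applies [satelliteFraction()] per row.
#'
#' @param nmr data.frame with `center` and `satellites` columns
#' @return the table with `f13` and `tracerFraction` columns appended
#' @export
nmrSourceTable <- function(nmr) {
  .requireColumns(nmr, c("center", "satellites"), "NMR integral table")
  res <- t(vapply(seq_len(nrow(nmr)), function(i) {
    r <- satelliteFraction(nmr$center[i], nmr$satellites[i])
    c(r$f13, r$tracerFraction)
  }, numeric(2)))
  nmr$f13 <- res[, 1]
  nmr$tracerFraction <- res[, 2]
  nmr
}

#' Net exchanges from a media concentration table
#'
#' Applies [netExchange()] per row of the media schema.
#'
#' @param media data.frame in the media schema (see [readMediaTable()])
#' @return the table with an `exchange_umol_mg` column appended
#' @export
mediaExchangeTable <- function(media) {
  .requireColumns(media, c("fresh_mM", "end_mM", "volume_ml", "protein_mg"),
                  "media table")
  media$exchange_umol_mg <- netExchange(media$fresh_mM, media$end_mM,
                                        media$volume_ml, media$protein_mg)
  media
}
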