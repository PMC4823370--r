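## Group statistics: one-way ANOVA, Tukey HSD post hoc, Benjamini-Hochberg
## FDR across metabolites within a measurement family.

#' Classical one-way fixed-effects ANOVA
#'
#' @param groups list of >= 2 numeric vectors, each with n >= 2 finite values
#' @return list with `F`, `p`, `df` (between, within)
#' @examples
#' oneWayAnova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
#' @export
oneWayAnova <- function(groups) {
  .checkGroups(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(values) == 0)
    return(list(F = 0, p = 1, df = c(length(groups) - 1L, length(values) - length(groups))))
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic), p = unname(fit$p.value),
       df = unname(fit$parameter))
}

#' Tukey honestly-significant-difference pairwise comparisons
#'
#' Studentized-range adjusted pairwise p-values from `TukeyHSD` on the
#' one-way fit.
#'
#' @param groups named list of >= 2 numeric vectors (names label the groups)
#' @return data.frame: contrast, diff, pAdj
#' @export
tukeyHsd <- function(groups) {
  .checkGroups(groups)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (stats::var(values) == 0) {
    cmb <- utils::combn(names(groups), 2)
    return(data.frame(contrast = paste(cmb[2, ], cmb[1, ], sep = "-"),
                      diff = 0, pAdj = 1))
  }
  tk <- stats::TukeyHSD(stats::aov(values ~ g))$g
  data.frame(contrast = rownames(tk), diff = tk[, "diff"],
             pAdj = tk[, "p adj"], row.names = NULL)
}

.checkGroups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least two groups")
  for (v in groups) {
    if (length(v) < 2L) stop("each group needs n >= 2")
    if (any(!is.finite(v))) stop("groups must contain finite values only")
  }
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment with enforced monotonicity.
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`
#' @return adjusted p-values, same order as the input
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03))
#' @export
bhFdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-metabolite group testing across a study table
#'
#' Runs one-way ANOVA across cell lines for every metabolite, adjusts the
#' ANOVA p-values by Benjamini-Hochberg FDR within the measurement family,
#' and reports Tukey HSD pairwise contrasts (adjusted within metabolite,
#' not across the family; the family-level FDR is applied to the ANOVA
#' p-values).
#'
#' @param table long-format data.frame with `line`, `metabolite`, `value`
#' @param alpha significance levels for the star annotation
#' @return data.frame: metabolite, F, p, pFdr, stars, plus one `tukey_`
#'   column per pairwise contrast, and group means/SEMs
#' @export
metaboliteStats <- function(table, alpha = c(0.05, 0.01, 0.001)) {
  stopifnot(all(c("line", "metabolite", "value") %in% names(table)))
  lines <- unique(table$line)
  mets <- unique(table$metabolite)
  rows <- list()
  for (met in mets) {
    sub <- table[table$metabolite == met, ]
    groups <- split(sub$value, factor(sub$line, levels = lines))
    an <- oneWayAnova(groups)
    tk <- tukeyHsd(groups)
    row <- data.frame(metabolite = met, F = an$F, p = an$p)
    for (i in seq_len(nrow(tk)))
      row[[paste0("tukey_", tk$contrast[i])]] <- tk$pAdj[i]
    for (ln in lines) {
      v <- groups[[ln]]
      row[[paste0("mean_", ln)]] <- mean(v)
      row[[paste0("sem_", ln)]] <- stats::sd(v) / sqrt(length(v))
      row[[paste0("n_", ln)]] <- length(v)
    }
    rows[[met]] <- row
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$pFdr <- bhFdr(out$p)
  out$stars <- vapply(out$pFdr, function(p)
    paste(rep("*", sum(p < alpha)), collapse = ""), character(1))
  out[, c("metabolite", "F", "p", "pFdr", "stars",
          setdiff(names(out), c("metabolite", "F", "p", "pFdr", "stars")))]
}
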