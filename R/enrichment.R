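#' Build a 2x2 hotspot/coldspot contingency table
#'
#' `HM`/`HN` are hotspot regions with / without at least one motif
#' occurrence; `CM`/`CN` the same for coldspots. Coldspot cells may be
#' fractional means over replicate coldspot draws.
#'
#' @param HM,HN Non-negative integers.
#' @param CM,CN Non-negative reals (replicate averages allowed).
#' @return An object of class `contingency_table` with elements `HM`, `HN`,
#'   `CM`, `CN`, `N_H`, `N_C`.
#' @export
contingency_table <- function(HM, HN, CM, CN) {
  if (any(c(HM, HN, CM, CN) < 0) || any(!is.finite(c(HM, HN, CM, CN))))
    stop_config("all cells must be finite and non-negative")
  if (HM != round(HM) || HN != round(HN))
    stop_config("hotspot cells must be integers")
  structure(list(HM = HM, HN = HN, CM = CM, CN = CN,
                 N_H = HM + HN, N_C = CM + CN),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$HM, x$CM, x$HN, x$CN), 2, 2,
              dimnames = list(c("hotspots", "coldspots"),
                              c("with hit", "without hit")))
  print(m)
  invisible(x)
}

#' Average coldspot hit counts over replicate draws
#'
#' @param per_replicate_CM Integer vector: number of coldspots with >= 1 hit
#'   in each replicate coldspot draw.
#' @param N_C Number of coldspots per draw.
#' @return List with `CM` (mean) and `CN = N_C - CM`.
#' @export
average_replicates <- function(per_replicate_CM, N_C) {
  if (!length(per_replicate_CM)) stop_config("no replicate counts supplied")
  if (any(per_replicate_CM < 0 | per_replicate_CM > N_C))
    stop_config("replicate counts must lie in [0, N_C]")
  CM <- mean(per_replicate_CM)
  list(CM = CM, CN = N_C - CM)
}

#' Hotspot/coldspot enrichment odds ratio
#'
#' `O_hc = (HM/HN) / (CM/CN)`: the odds that a hotspot carries at least one
#' motif occurrence relative to the same odds in matched coldspots. Values
#' above 1 indicate preferential binding in hotspots. The value is kept at
#' full precision; rounding (3 decimals) happens only in printed reports.
#'
#' @param t A [contingency_table()].
#' @return Numeric odds ratio with attribute `flag`: `"ok"`, or
#'   `"zero_numerator"` (`HM = 0`, value 0), or `"infinite_odds"` (`HN = 0`
#'   or `CM = 0`, value `Inf`).
#' @examples
#' odds_ratio(contingency_table(1405, 8469, 1120.35, 8753.65))
#' @export
odds_ratio <- function(t) {
  if (t$HM == 0 && t$CM > 0)
    return(structure(0, flag = "zero_numerator"))
  if (t$HN == 0 || t$CM == 0)
    return(structure(Inf, flag = "infinite_odds"))
  structure((t$HM / t$HN) / (t$CM / t$CN), flag = "ok")
}

#' Yates-corrected chi-square test on a 2x2 table
#'
#' Continuity-corrected chi-square statistic
#' `N * (max(|HM*CN - HN*CM| - N/2, 0))^2 / (N_H * N_C * (HM+CM) * (HN+CN))`
#' with `N = N_H + N_C`, compared against the chi-square distribution with
#' one degree of freedom (upper tail, the conventional two-sided reading).
#' Fractional coldspot cells (replicate means) are used as-is.
#'
#' @param t A [contingency_table()].
#' @return List with `chi2`, `p_value` and `flag` (`"ok"` or
#'   `"degenerate"` when a marginal is zero, in which case `chi2 = 0`,
#'   `p_value = 1`).
#' @export
yates_chisq <- function(t) {
  N <- t$N_H + t$N_C
  marg <- c(t$N_H, t$N_C, t$HM + t$CM, t$HN + t$CN)
  if (any(marg == 0))
    return(list(chi2 = 0, p_value = 1, flag = "degenerate"))
  d <- max(abs(t$HM * t$CN - t$HN * t$CM) - N / 2, 0)
  chi2 <- N * d^2 / prod(marg)
  list(chi2 = chi2,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       flag = "ok")
}

#' Enrichment analysis over a set of motifs
#'
#' Assembles, for each motif, the contingency table from hotspot hit counts
#' and (replicate-averaged) coldspot hit counts, and computes the odds ratio
#' and Yates-corrected significance.
#'
#' @param hot_counts Named integer vector: hotspot regions with >= 1 hit
#'   (`HM`) per motif.
#' @param cold_counts Named list: for each motif, an integer vector of
#'   per-replicate coldspot `CM` counts.
#' @param N_H,N_C Numbers of hotspots and coldspots per draw.
#' @return A data.frame of class `enrichment_table` with columns `gene`,
#'   `HM`, `HN`, `CM`, `CN`, `O_hc`, `chi2`, `p_value`, ranked by ascending
#'   p-value then descending odds ratio.
#' @export
enrich_motifs <- function(hot_counts, cold_counts, N_H, N_C) {
  genes <- names(hot_counts)
  if (is.null(genes) || !all(genes %in% names(cold_counts)))
    stop_config("hot_counts and cold_counts must be named by the same motifs")
  rows <- lapply(genes, function(g) {
    avg <- average_replicates(cold_counts[[g]], N_C)
    tab <- contingency_table(hot_counts[[g]], N_H - hot_counts[[g]],
                             avg$CM, avg$CN)
    or <- odds_ratio(tab)
    yc <- yates_chisq(tab)
    data.frame(gene = g, HM = tab$HM, HN = tab$HN, CM = tab$CM, CN = tab$CN,
               O_hc = as.numeric(or), chi2 = yc$chi2, p_value = yc$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, -out$O_hc, out$gene), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' @export
print.enrichment_table <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df$O_hc <- round(df$O_hc, digits)
  df$chi2 <- round(df$chi2, 2)
  df$p_value <- signif(df$p_value, 3)
  print(df)
  invisible(x)
}

#' Select candidate trans-regulators (the HG set)
#'
#' Keeps genes whose odds ratio exceeds `or_min` and whose Yates chi-square
#' p-value is below `p_max`, ranked by ascending p-value then descending
#' odds ratio.
#'
#' @param results An [enrich_motifs()] table (or any data.frame with columns
#'   `gene`, `O_hc`, `p_value`).
#' @param or_min Odds-ratio threshold (exclusive). Default 1.20.
#' @param p_max p-value threshold (exclusive). Default 0.05.
#' @return Character vector of candidate gene names (possibly empty, with a
#'   warning).
#' @export
select_candidates <- function(results, or_min = 1.20, p_max = 0.05) {
  if (!nrow(results)) stop_config("empty results table")
  keep <- results$O_hc > or_min & results$p_value < p_max
  keep[is.na(keep)] <- FALSE
  sel <- results[keep, , drop = FALSE]
  sel <- sel[order(sel$p_value, -sel$O_hc, sel$gene), ]
  if (!nrow(sel)) warning("no candidate passes the odds-ratio/p-value filter")
  sel$gene
}
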