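# repstats: repeat-abundance vs genome-size statistics. Pearson correlation
# (R^2 and p) of per-lineage abundance with monoploid genome size, the
# average contribution of each repeat to pairwise genome-size differences,
# and Kruskal-Wallis rank tests across sample groups.

#' Squared Pearson correlation with p-value
#'
#' Standard Pearson r between repeat abundance and genome size; p from the
#' t transform with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors (n >= 3, non-constant).
#' @param lineage optional label carried into the result.
#' @return data.table `lineage`, `r`, `R2`, `p`, `n`.
#' @export
pearson_r2 <- function(x, y, lineage = NA_character_) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant vector")
  ct <- cor.test(x, y, method = "pearson")
  data.table::data.table(lineage = lineage, r = unname(ct$estimate),
                         R2 = unname(ct$estimate)^2, p = ct$p.value,
                         n = length(x))
}

#' Average contribution of a repeat to pairwise genome-size differences
#'
#' Over all unordered sample pairs with `GS_i > GS_j`, the pair contribution
#' is `(A_i - A_j) / (GS_i - GS_j) * 100` (absolute amounts in Mbp);
#' negative pair values are floored at zero by default (a repeat cannot
#' negatively explain a size difference) before averaging. Pairs with equal
#' genome size are skipped.
#'
#' @param amount_mbp per-sample repeat amounts (Mbp).
#' @param genome_mbp per-sample genome sizes (Mbp), same order.
#' @param floor_negative floor negative pair contributions at 0 (default
#'   `TRUE`); set `FALSE` for the signed mean.
#' @param lineage optional label.
#' @return data.table `lineage`, `min_mbp`, `max_mbp`,
#'   `mean_contribution_pct`, `n_pairs`.
#' @export
pairwise_contribution <- function(amount_mbp, genome_mbp,
                                  floor_negative = TRUE,
                                  lineage = NA_character_) {
  stopifnot(length(amount_mbp) == length(genome_mbp))
  if (length(unique(genome_mbp)) < 2)
    stop("all genome sizes equal: pairwise differences undefined")
  pairs <- utils::combn(length(genome_mbp), 2)
  gi <- genome_mbp[pairs[1, ]]; gj <- genome_mbp[pairs[2, ]]
  ai <- amount_mbp[pairs[1, ]]; aj <- amount_mbp[pairs[2, ]]
  swap <- gi < gj
  tmp <- gi[swap]; gi[swap] <- gj[swap]; gj[swap] <- tmp
  tmp <- ai[swap]; ai[swap] <- aj[swap]; aj[swap] <- tmp
  keep <- gi > gj
  contrib <- (ai[keep] - aj[keep]) / (gi[keep] - gj[keep]) * 100
  if (floor_negative) contrib <- pmax(contrib, 0)
  data.table::data.table(lineage = lineage,
                         min_mbp = min(amount_mbp), max_mbp = max(amount_mbp),
                         mean_contribution_pct = mean(contrib),
                         n_pairs = sum(keep))
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with the chi-square approximation on
#' `groups - 1` degrees of freedom (delegates to [stats::kruskal.test()]).
#'
#' @param values numeric observations.
#' @param groups group labels, same length.
#' @param lineage optional label.
#' @return data.table `lineage`, `H`, `df`, `p`, `n_groups`.
#' @export
kruskal_wallis <- function(values, groups, lineage = NA_character_) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("at least 2 groups required")
  if (length(values) < 2) stop("at least 2 observations required")
  if (length(unique(values)) == 1)  # fully tied data carry no rank signal
    return(data.table::data.table(lineage = lineage, H = 0,
                                  df = nlevels(groups) - 1, p = 1,
                                  n_groups = nlevels(groups)))
  kt <- kruskal.test(values, groups)
  data.table::data.table(lineage = lineage,
                         H = unname(kt$statistic),
                         df = unname(kt$parameter), p = kt$p.value,
                         n_groups = nlevels(groups))
}

#' Genome-size statistics table over all lineages
#'
#' For each lineage of an abundance table: correlation of Mbp amount with
#' monoploid genome size (R^2, p), amount range, and average contribution
#' to pairwise genome-size differences.
#'
#' @param abundance output of [quantify_repeats()] (long table).
#' @param genome_sizes data.table with `sample` and `monoploid_mbp`.
#' @param floor_negative see [pairwise_contribution()].
#' @return data.table, one row per lineage (including `"All repeats"`).
#' @export
repeat_size_stats <- function(abundance, genome_sizes,
                              floor_negative = TRUE) {
  wide <- merge(abundance, genome_sizes[, list(sample, monoploid_mbp)],
                by = "sample")
  out <- lapply(split(wide, wide$lineage), function(dd) {
    corr <- tryCatch(pearson_r2(dd$amount_mbp, dd$monoploid_mbp,
                                lineage = dd$lineage[1]),
                     error = function(e)
                       data.table::data.table(lineage = dd$lineage[1],
                                              r = NA_real_, R2 = NA_real_,
                                              p = NA_real_, n = nrow(dd)))
    ctr <- pairwise_contribution(dd$amount_mbp, dd$monoploid_mbp,
                                 floor_negative, lineage = dd$lineage[1])
    cbind(corr, ctr[, list(min_mbp, max_mbp, mean_contribution_pct)])
  })
  data.table::rbindlist(out)
}
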