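# 2x2 association testing (chi-square, risk ratio, odds ratio) for
# group-vs-trait questions such as "are predicted scaffolds enriched for
# disease genes?", plus native hypergeometric term enrichment with
# multiple-testing correction.

#' Build a group-vs-trait 2x2 table over a protein universe
#'
#' Rows are group membership, columns trait status:
#' `a` = group with trait, `b` = group without, `c` = trait outside the
#' group, `d` = neither. The trait set is intersected with the universe
#' first; the group must be a subset of the universe.
#'
#' @param group character vector of accessions (e.g. predicted Type I
#'   scaffolds)
#' @param trait an [annotation_map()] (any annotated protein counts as
#'   trait-positive) or a character vector of accessions
#' @param universe character vector of all accessions under consideration
#' @return a [contingency_2x2()]
#' @export
build_association_table <- function(group, trait, universe) {
  group <- unique(as.character(group))
  universe <- unique(as.character(universe))
  if (inherits(trait, "annotation_map")) trait <- names(trait$assignments)
  trait <- intersect(unique(as.character(trait)), universe)
  if (!all(group %in% universe))
    stop("group must be a subset of the universe", call. = FALSE)
  contingency_2x2(a = length(intersect(group, trait)),
                  b = length(setdiff(group, trait)),
                  c = length(setdiff(trait, group)),
                  d = length(setdiff(universe, union(group, trait))))
}

#' Chi-square association test on a 2x2 table
#'
#' Pearson's chi-square statistic without continuity correction (the
#' observed-vs-expected comparison on one degree of freedom), with the
#' upper-tail p-value, plus risk ratio `(a/(a+b)) / (c/(c+d))` and odds
#' ratio `ad/bc`. The ratios are reported as `NA` when a denominator cell
#' is zero; the chi-square is still computed as long as every marginal is
#' positive. A Yates continuity correction is available but off by
#' default.
#'
#' Orientation matters for the risk ratio (rows = group membership); the
#' chi-square and odds ratio are invariant under transposition.
#'
#' @param table a [contingency_2x2()]
#' @param correct apply the Yates continuity correction
#' @return a list of class `association_result` with `table`,
#'   `chi_square`, `p_value`, `risk_ratio`, `odds_ratio`, `df`
#' @examples
#' # Type I scaffolds vs disease genes
#' tab <- build_association_table(
#'   group = paste0("S", 1:4), trait = c("S1", "S2", "X1"),
#'   universe = c(paste0("S", 1:4), paste0("X", 1:6)))
#' association_test(tab)
#' @export
association_test <- function(table, correct = FALSE) {
  stopifnot(inherits(table, "contingency_2x2"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  m <- as.matrix(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate table: a zero marginal leaves chi-square undefined",
         call. = FALSE)
  ct <- stats::chisq.test(m, correct = correct)
  rr <- if (a + b > 0 && c + d > 0 && c > 0) (a / (a + b)) / (c / (c + d))
        else NA_real_
  or <- if (b > 0 && c > 0) (a * d) / (b * c) else NA_real_
  structure(list(table = table,
                 chi_square = unname(ct$statistic),
                 p_value = unname(ct$p.value),
                 risk_ratio = rr, odds_ratio = or,
                 df = unname(ct$parameter)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("chi-square = %.4g (df = %d), p = %.3g\n",
              x$chi_square, x$df, x$p_value))
  cat(sprintf("risk ratio = %s, odds ratio = %s\n",
              if (is.na(x$risk_ratio)) "NA" else sprintf("%.4g", x$risk_ratio),
              if (is.na(x$odds_ratio)) "NA" else sprintf("%.4g", x$odds_ratio)))
  invisible(x)
}

#' Adjust p-values for multiple testing
#'
#' Thin wrapper over [stats::p.adjust()] exposing the two corrections used
#' for term enrichment: Bonferroni (`min(1, m * p)`) and
#' Benjamini-Hochberg step-up FDR. Output order matches input order.
#'
#' @param pvals numeric vector of raw p-values in `(0, 1]`
#' @param method `"bonferroni"` or `"bh"`
#' @return numeric vector of adjusted p-values
#' @export
adjust_pvalues <- function(pvals, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  pvals <- as.numeric(pvals)
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = c(bonferroni = "bonferroni", bh = "BH")[method])
}

#' Term enrichment of a protein set
#'
#' For every annotation term hit by the foreground, tests over-representation
#' with the hypergeometric upper tail `P[X >= k]` for
#' `X ~ Hypergeom(N, K, n)` where `N` = background size, `K` = background
#' proteins with the term, `n` = foreground size, `k` = foreground proteins
#' with the term (this is Fisher's one-sided exact test; `test = "fisher"`
#' computes it through [stats::fisher.test()] instead and gives identical
#' p-values). Terms with `k = 0` are skipped.
#'
#' @param foreground character vector of accessions, a subset of
#'   `background`
#' @param annotations an [annotation_map()]
#' @param background character vector; defaults to every protein in the
#'   annotation map (an explicit universe is better when you have one)
#' @param correction `"bh"` (default) or `"bonferroni"`
#' @param alpha significance threshold applied to the adjusted p-value
#' @param test `"hypergeometric"` (default) or `"fisher"`
#' @return a `data.frame`, one row per tested term, sorted by adjusted
#'   p-value then term: `term`, `k`, `K`, `n`, `N`, `fold_enrichment`
#'   (`(k/n)/(K/N)`), `p_value`, `adjusted_p`, `significant`
#' @export
enrich <- function(foreground, annotations,
                   background = names(annotations$assignments),
                   correction = c("bh", "bonferroni"), alpha = 0.05,
                   test = c("hypergeometric", "fisher")) {
  stopifnot(inherits(annotations, "annotation_map"))
  correction <- match.arg(correction)
  test <- match.arg(test)
  foreground <- unique(as.character(foreground))
  background <- unique(as.character(background))
  if (!all(foreground %in% background))
    stop("foreground must be a subset of the background", call. = FALSE)
  N <- length(background); n <- length(foreground)
  ann <- annotations$assignments[names(annotations$assignments) %in% background]
  prot <- rep(names(ann), lengths(ann))
  df <- data.frame(protein = prot, term = unlist(ann, use.names = FALSE),
                   stringsAsFactors = FALSE)
  K_all <- table(df$term)
  k_all <- table(df$term[df$protein %in% foreground])
  terms <- sort(names(k_all))
  if (!length(terms))
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0),
                      fold_enrichment = numeric(0), p_value = numeric(0),
                      adjusted_p = numeric(0), significant = logical(0)))
  k <- as.integer(k_all[terms]); K <- as.integer(K_all[terms])
  p <- if (test == "hypergeometric") {
    stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  } else {
    vapply(seq_along(terms), function(i)
      stats::fisher.test(matrix(c(k[i], n - k[i], K[i] - k[i],
                                  N - K[i] - n + k[i]), 2, 2),
                         alternative = "greater")$p.value,
      numeric(1))
  }
  p <- pmin(p, 1)
  adj <- adjust_pvalues(p, if (correction == "bh") "bh" else "bonferroni")
  out <- data.frame(term = terms, k = k, K = K, n = n, N = N,
                    fold_enrichment = (k / n) / (K / N),
                    p_value = p, adjusted_p = adj,
                    significant = adj <= alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$adjusted_p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
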