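# Performance evaluation against gold-standard positive/negative protein
# lists: confusion counts and the standard 2x2 metric panel.

#' Confusion table of a predicted protein set
#'
#' Proteins outside both gold lists are ignored: the prediction is only
#' judged on the universe where the truth is known.
#'
#' @param predicted character vector of predicted-positive accessions (or a
#'   `scaffold_predictions` object, in which case every predicted scaffold
#'   counts as positive)
#' @param gold_pos,gold_neg disjoint character vectors of known positive and
#'   known negative accessions
#' @return a [contingency_2x2()] with `a` = TP, `b` = FP, `c` = FN,
#'   `d` = TN
#' @export
confusion <- function(predicted, gold_pos, gold_neg) {
  if (inherits(predicted, "scaffold_predictions"))
    predicted <- scaffolds_of_type(predicted)
  predicted <- unique(as.character(predicted))
  gold_pos <- unique(as.character(gold_pos))
  gold_neg <- unique(as.character(gold_neg))
  if (length(intersect(gold_pos, gold_neg)))
    stop("gold positive and negative sets overlap", call. = FALSE)
  contingency_2x2(a = length(intersect(predicted, gold_pos)),
                  b = length(intersect(predicted, gold_neg)),
                  c = length(setdiff(gold_pos, predicted)),
                  d = length(setdiff(gold_neg, predicted)))
}

#' Performance metric panel from a confusion table
#'
#' Computes precision `a/(a+b)`, sensitivity `a/(a+c)`, specificity
#' `d/(b+d)`, accuracy `(a+d)/n`, prevalence `(a+c)/n`, miss rate
#' `c/(a+c)`, fall-out `b/(b+d)` and false omission rate `c/(c+d)`.
#' A metric whose denominator is zero is undefined and reported as `NA`
#' (never as 0).
#'
#' @param table a `contingency_2x2` interpreted as TP/FP/FN/TN
#' @return a list of class `metric_panel` with the eight fractions plus the
#'   raw counts `tp`, `fp`, `fn`, `tn`
#' @examples
#' metric_panel(contingency_2x2(67, 13, 91, 831))
#' @export
metric_panel <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  n <- a + b + c + d
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    precision = frac(a, a + b),
    sensitivity = frac(a, a + c),
    specificity = frac(d, b + d),
    accuracy = frac(a + d, n),
    prevalence = frac(a + c, n),
    miss_rate = frac(c, a + c),
    fall_out = frac(b, b + d),
    false_omission_rate = frac(c, c + d),
    tp = a, fp = b, fn = c, tn = d),
    class = "metric_panel")
}

#' Format a fraction as a percentage, one decimal, round half up
#'
#' Matches the conventional presentation of performance tables (e.g. 0.8375
#' prints as `"83.8"`, 0.425 as `"42.5"`). Base `round()` rounds half to
#' even, which is not what published tables use.
#'
#' @param x fraction in `[0, 1]` (or `NA`)
#' @return character scalar, without the `%` sign (`"NA"` if undefined)
#' @export
format_pct <- function(x) {
  if (is.na(x)) return("NA")
  sprintf("%.1f", floor(x * 1000 + 0.5) / 10)
}

#' @export
print.metric_panel <- function(x, ...) {
  cat(sprintf("counts: TP=%d FP=%d FN=%d TN=%d\n", x$tp, x$fp, x$fn, x$tn))
  for (m in c("precision", "sensitivity", "specificity", "accuracy",
              "prevalence", "miss_rate", "fall_out", "false_omission_rate"))
    cat(sprintf("  %-20s %s %%\n", m, format_pct(x[[m]])))
  invisible(x)
}
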