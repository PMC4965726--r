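# Scaffold-partner annotation agreement: for each predicted type class, how
# many scaffolds carry an annotation at all, and how many of those share at
# least one term with at least one partner. A scaffold that recruits its
# partners should usually live in the same compartment / pathway as they do,
# so high agreement supports the predictions.

#' Scaffold-partner annotation agreement per type class
#'
#' For each type class: `n_total` = predicted scaffolds of that class,
#' `n_known` = those with at least one annotation term, `n_matched` = known
#' scaffolds sharing at least one term with at least one partner in scope.
#' The match rule is plain set overlap of one or more terms.
#'
#' Scope `"witness"` (default) compares against the witness partners — the
#' recruited pair(s) certifying the prediction, i.e. the scaffold's
#' functional partners under the model. Scope `"all_partners"` compares
#' against every direct interactor and requires the interactome; it can
#' only increase `n_matched`.
#'
#' @param predictions a `scaffold_predictions` object (non-empty)
#' @param annotations an [annotation_map()] (e.g. localization compartments
#'   or pathway membership)
#' @param scope `"witness"` or `"all_partners"`
#' @param net an `interactome`; required when `scope = "all_partners"`
#' @return a `data.frame` with one row per type class: `type_class`,
#'   `n_total`, `n_known`, `n_matched`, `pct_known`, `pct_matched`
#'   (fractions; `pct_matched` is `NA` when no scaffold of the class is
#'   annotated)
#' @export
partner_match_summary <- function(predictions, annotations,
                                  scope = c("witness", "all_partners"),
                                  net = NULL) {
  stopifnot(inherits(predictions, "scaffold_predictions"),
            inherits(annotations, "annotation_map"))
  scope <- match.arg(scope)
  if (!nrow(predictions)) stop("predictions are empty", call. = FALSE)
  if (scope == "all_partners" && !inherits(net, "interactome"))
    stop("scope 'all_partners' needs the interactome", call. = FALSE)
  df <- as.data.frame(predictions)
  out <- lapply(c("I", "II", "III"), function(tc) {
    sc <- sort(unique(df$scaffold[df$type_class == tc]))
    known <- matched <- 0L
    for (s in sc) {
      st <- terms_of(annotations, s)
      if (!length(st)) next
      known <- known + 1L
      prt <- if (scope == "witness") {
        rows <- df[df$scaffold == s, ]
        unique(c(rows$p1, rows$p2))
      } else partners(net, s)
      hit <- any(vapply(prt, function(p)
        length(intersect(st, terms_of(annotations, p))) > 0, logical(1)))
      if (hit) matched <- matched + 1L
    }
    data.frame(type_class = tc, n_total = length(sc), n_known = known,
               n_matched = matched,
               pct_known = if (length(sc)) known / length(sc) else NA_real_,
               pct_matched = if (known) matched / known else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
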