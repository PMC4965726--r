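# Scaffold prediction: apply the three structural criteria to every protein
# in the interactome and classify candidates into Type I/II/III.
#
# criterion 1: direct interaction with at least two other proteins
# criterion 2: the two partners are recruited through domain-domain
#              interactions that use *different* domain regions of the
#              candidate (this is what separates a scaffold from a hub,
#              whose partners compete for one binding region)
# criterion 3: candidate and both partners co-occur in one protein complex
#
# Type I = criteria 2 and 3, Type II = 2 only, Type III = 3 only.

#' Predictor configuration
#'
#' @param joint_witness if `TRUE` (default) a candidate is Type I only when
#'   one and the same partner pair satisfies criteria 2 *and* 3; if `FALSE`
#'   the criteria may be certified by different partner pairs. The joint
#'   reading is stricter and biologically the more coherent one: the two
#'   partners recruited through distinct regions are the ones found together
#'   with the scaffold in a complex.
#' @param region_semantics what counts as "different domain regions":
#'   `"instance"` (default) treats two copies of the same family as distinct
#'   physical regions; `"family"` requires two different domain families,
#'   which is the natural reading for a pipeline that only knows family-level
#'   domain assignments.
#' @param require_partner_domain_known if `TRUE` (default) a partner with no
#'   known domain architecture cannot contribute a criterion-2 witness; if
#'   `FALSE` such a partner is optimistically assumed compatible with every
#'   region of the candidate.
#' @return a list of class `predictor_config`
#' @export
predictor_config <- function(joint_witness = TRUE,
                             region_semantics = c("instance", "family"),
                             require_partner_domain_known = TRUE) {
  structure(list(joint_witness = isTRUE(joint_witness),
                 region_semantics = match.arg(region_semantics),
                 require_partner_domain_known = isTRUE(require_partner_domain_known)),
            class = "predictor_config")
}

#' Criterion 1: proteins with at least two interaction partners
#'
#' Self-loops do not count; a scaffold must be able to recruit two other
#' proteins.
#'
#' @param net an `interactome`
#' @return sorted character vector of accessions
#' @export
criterion1 <- function(net) {
  stopifnot(inherits(net, "interactome"))
  ps <- interactome_proteins(net)
  deg <- igraph::degree(net$graph, loops = FALSE)
  sort(ps[deg >= 2])
}

#' Domain regions of a candidate that can mediate one partner
#'
#' Returns every domain instance of `s` whose family forms a known
#' domain-domain interaction with some family carried by partner `p`.
#' Homotypic pairs (a family interacting with itself) count when both
#' proteins carry the family. The result is empty when `s` has no known
#' domains, or when `p` has none (unless
#' `config$require_partner_domain_known` is `FALSE`, in which case a
#' domain-less partner matches every region of `s`).
#'
#' @param s,p accessions; the edge `s`-`p` must exist in `net`
#' @param net an `interactome`
#' @param arch a `domain_architectures` object
#' @param ddi a `ddi_network`
#' @param config a [predictor_config()]
#' @return instance rows of `s` (a `data.frame` with `protein`, `family`,
#'   `copy_index`, `start`, `end`), ordered by (`copy_index`, `family`)
#' @export
mediating_regions <- function(s, p, net, arch, ddi,
                              config = predictor_config()) {
  if (!are_partners(net, s, p))
    stop(sprintf("no edge between '%s' and '%s'", s, p), call. = FALSE)
  inst_s <- architecture_of(arch, s)
  if (!nrow(inst_s)) return(inst_s)
  inst_s <- inst_s[order(inst_s$copy_index, inst_s$family), , drop = FALSE]
  rownames(inst_s) <- NULL
  fams_p <- unique(architecture_of(arch, p)$family)
  if (!length(fams_p)) {
    if (config$require_partner_domain_known)
      return(inst_s[0, , drop = FALSE])
    return(inst_s)
  }
  keep <- vapply(inst_s$family, function(f)
    any(vapply(fams_p, function(g) has_ddi(ddi, f, g), logical(1))),
    logical(1))
  out <- inst_s[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

regions_distinct <- function(r1, r2, semantics) {
  if (semantics == "family") r1$family != r2$family
  else !(r1$family == r2$family && r1$copy_index == r2$copy_index)
}

#' Criterion 2: partner pairs recruited through distinct domain regions
#'
#' For candidate `s`, every unordered pair of partners `(p1, p2)` for which
#' region assignments `r1` mediating `p1` and `r2` mediating `p2` exist with
#' `r1 != r2` under the configured region semantics. One witness per pair is
#' kept, with a deterministic representative assignment: candidate regions
#' are scanned in (copy_index, family) order and the first admissible pair
#' wins.
#'
#' A hub whose partners all dock onto the same single region yields no
#' witness here — that is the hub filter.
#'
#' @inheritParams mediating_regions
#' @return a `data.frame` with columns `p1`, `p2` (`p1 < p2`), `region1`,
#'   `region2` (instance labels `family.copy`); zero rows when the criterion
#'   fails
#' @export
criterion2_witnesses <- function(s, net, arch, ddi,
                                 config = predictor_config()) {
  ps <- partners(net, s)
  out <- data.frame(p1 = character(0), p2 = character(0),
                    region1 = character(0), region2 = character(0),
                    stringsAsFactors = FALSE)
  if (length(ps) < 2) return(out)
  mr <- lapply(ps, mediating_regions, s = s, net = net, arch = arch,
               ddi = ddi, config = config)
  names(mr) <- ps
  with_regions <- ps[vapply(mr, nrow, integer(1)) > 0]
  if (length(with_regions) < 2) return(out)
  for (i in seq_len(length(with_regions) - 1)) {
    for (j in seq(i + 1, length(with_regions))) {
      p1 <- with_regions[i]; p2 <- with_regions[j]
      m1 <- mr[[p1]]; m2 <- mr[[p2]]
      found <- FALSE
      for (a in seq_len(nrow(m1))) {
        for (b in seq_len(nrow(m2))) {
          if (regions_distinct(m1[a, ], m2[b, ], config$region_semantics)) {
            out <- rbind(out, data.frame(
              p1 = p1, p2 = p2,
              region1 = region_label(m1$family[a], m1$copy_index[a]),
              region2 = region_label(m2$family[b], m2$copy_index[b]),
              stringsAsFactors = FALSE))
            found <- TRUE; break
          }
        }
        if (found) break
      }
    }
  }
  out[order(out$p1, out$p2), , drop = FALSE]
}

#' Criterion 3: partner pairs co-complexed with the candidate
#'
#' Every unordered pair of direct partners `(p1, p2)` of `s` such that some
#' catalogued complex contains all of `s`, `p1` and `p2`. Both pair members
#' must be direct interaction partners of `s`; complex co-membership alone
#' is not enough. The witness records the lexicographically smallest
#' qualifying complex id.
#'
#' @param s candidate accession
#' @param net an `interactome`
#' @param catalog a `complex_catalog`
#' @return a `data.frame` with columns `p1`, `p2` (`p1 < p2`), `complex_id`
#' @export
criterion3_witnesses <- function(s, net, catalog) {
  stopifnot(inherits(catalog, "complex_catalog"))
  ps <- partners(net, s)
  out <- data.frame(p1 = character(0), p2 = character(0),
                    complex_id = character(0), stringsAsFactors = FALSE)
  if (length(ps) < 2) return(out)
  cx <- complexes_containing(catalog, s)
  if (!length(cx)) return(out)
  members <- catalog$members[cx]
  for (i in seq_len(length(ps) - 1)) {
    for (j in seq(i + 1, length(ps))) {
      p1 <- ps[i]; p2 <- ps[j]
      hit <- cx[vapply(members, function(s_) p1 %in% s_ && p2 %in% s_,
                       logical(1))]
      if (length(hit))
        out <- rbind(out, data.frame(p1 = p1, p2 = p2,
                                     complex_id = min(hit),
                                     stringsAsFactors = FALSE))
    }
  }
  out[order(out$p1, out$p2), , drop = FALSE]
}

pair_key <- function(p1, p2) paste(p1, p2, sep = "\t")

#' Classify one candidate from its criterion-2 and criterion-3 witnesses
#'
#' Under the default joint-witness policy, Type I requires one partner pair
#' that appears in both witness sets (its witness merges the regions and
#' the complex id); under the independent policy, Type I only requires both
#' sets to be non-empty. Type II: criterion 2 holds but not Type I.
#' Type III: criterion 3 holds and criterion 2 does not. A candidate with
#' neither kind of witness is not called (criterion 1 alone is not
#' considered reliable evidence of scaffolding).
#'
#' @param s candidate accession
#' @param c2 witnesses from [criterion2_witnesses()]
#' @param c3 witnesses from [criterion3_witnesses()]
#' @param config a [predictor_config()]
#' @return `NULL`, or a list with `scaffold`, `type_class` (`"I"`, `"II"`,
#'   `"III"`) and `witnesses` (a `data.frame` with `p1`, `p2`, `region1`,
#'   `region2`, `complex_id`; absent parts `NA`)
#' @export
classify_scaffold <- function(s, c2, c3, config = predictor_config()) {
  has2 <- nrow(c2) > 0; has3 <- nrow(c3) > 0
  if (!has2 && !has3) return(NULL)
  k2 <- if (has2) pair_key(c2$p1, c2$p2) else character(0)
  k3 <- if (has3) pair_key(c3$p1, c3$p2) else character(0)
  joint <- intersect(k2, k3)
  type <- if (config$joint_witness) {
    if (length(joint)) "I" else if (has2) "II" else "III"
  } else {
    if (has2 && has3) "I" else if (has2) "II" else "III"
  }
  wit <- if (type == "I" && config$joint_witness) {
    w <- c2[k2 %in% joint, , drop = FALSE]
    w$complex_id <- c3$complex_id[match(pair_key(w$p1, w$p2), k3)]
    w
  } else if (type == "I") {
    # independent policy: union of both witness kinds, merged where pairs agree
    w <- merge(c2, c3, by = c("p1", "p2"), all = TRUE)
    w
  } else if (type == "II") {
    w <- c2; w$complex_id <- NA_character_; w
  } else {
    w <- c3; w$region1 <- NA_character_; w$region2 <- NA_character_
    w[, c("p1", "p2", "region1", "region2", "complex_id")]
  }
  if (!"region1" %in% names(wit)) wit$region1 <- NA_character_
  if (!"region2" %in% names(wit)) wit$region2 <- NA_character_
  wit <- wit[order(wit$p1, wit$p2),
             c("p1", "p2", "region1", "region2", "complex_id"), drop = FALSE]
  rownames(wit) <- NULL
  list(scaffold = s, type_class = type, witnesses = wit)
}

new_scaffold_predictions <- function(df) {
  need <- c("scaffold", "type_class", "p1", "p2", "region1", "region2",
            "complex_id")
  stopifnot(all(need %in% names(df)))
  df <- df[order(df$scaffold, df$p1, df$p2), need, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("scaffold_predictions", "data.frame")
  df
}

#' Predict scaffold candidates for a whole interactome
#'
#' Applies criterion 1 to every protein, computes criterion-2 and
#' criterion-3 witnesses for each candidate and classifies it. Proteins
#' absent from the architecture table are treated as having no domains
#' (they can still be Type III: the structural resources are known to be
#' incomplete and missing domain data should not veto complex evidence).
#'
#' @param net an `interactome`
#' @param arch a `domain_architectures` object
#' @param ddi a `ddi_network`
#' @param catalog a `complex_catalog`
#' @param config a [predictor_config()]
#' @param verbose emit per-criterion candidate counts as messages
#' @return a `scaffold_predictions` object: a `data.frame` with one row per
#'   witness pair (columns `scaffold`, `type_class`, `p1`, `p2`, `region1`,
#'   `region2`, `complex_id`), ordered by scaffold then pair. Use
#'   [prediction_counts()] for the per-type summary.
#' @examples
#' net <- build_interactome(rbind(c("S", "A"), c("S", "B")))
#' arch <- domain_architectures(data.frame(
#'   protein = c("S", "S", "A", "B"),
#'   family = c("PF_X", "PF_Y", "PF_U", "PF_V")))
#' ddi <- ddi_network(rbind(c("PF_X", "PF_U"), c("PF_Y", "PF_V")))
#' cat <- complex_catalog(list(CPX1 = c("S", "A", "B")))
#' predict_scaffolds(net, arch, ddi, cat)
#' @export
predict_scaffolds <- function(net, arch, ddi, catalog,
                              config = predictor_config(), verbose = FALSE) {
  cand <- criterion1(net)
  if (verbose)
    message(sprintf("criterion 1: %d candidate(s) with >= 2 partners",
                    length(cand)))
  rows <- list()
  for (s in cand) {
    c2 <- criterion2_witnesses(s, net, arch, ddi, config)
    c3 <- criterion3_witnesses(s, net, catalog)
    cls <- classify_scaffold(s, c2, c3, config)
    if (is.null(cls)) next
    w <- cls$witnesses
    w$scaffold <- s; w$type_class <- cls$type_class
    rows[[s]] <- w
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scaffold = character(0), type_class = character(0),
               p1 = character(0), p2 = character(0),
               region1 = character(0), region2 = character(0),
               complex_id = character(0), stringsAsFactors = FALSE)
  pred <- new_scaffold_predictions(df)
  if (verbose) {
    cnt <- prediction_counts(pred)
    message(sprintf("predicted scaffolds: Type I %d, Type II %d, Type III %d",
                    cnt[["I"]], cnt[["II"]], cnt[["III"]]))
  }
  pred
}

#' Per-type scaffold counts of a prediction set
#' @param predictions a `scaffold_predictions` object
#' @return named integer vector with elements `I`, `II`, `III`
#' @export
prediction_counts <- function(predictions) {
  stopifnot(inherits(predictions, "scaffold_predictions"))
  u <- unique(as.data.frame(predictions)[, c("scaffold", "type_class")])
  out <- c(I = 0L, II = 0L, III = 0L)
  tab <- table(u$type_class)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Scaffold accessions of one type class
#' @param predictions a `scaffold_predictions` object
#' @param type one or more of `"I"`, `"II"`, `"III"`
#' @return sorted character vector
#' @export
scaffolds_of_type <- function(predictions, type = c("I", "II", "III")) {
  stopifnot(inherits(predictions, "scaffold_predictions"))
  type <- match.arg(type, several.ok = TRUE)
  df <- as.data.frame(predictions)
  sort(unique(df$scaffold[df$type_class %in% type]))
}

#' @export
print.scaffold_predictions <- function(x, ...) {
  cnt <- prediction_counts(x)
  cat(sprintf("<scaffold_predictions> %d scaffold(s): I=%d II=%d III=%d; %d witness row(s)\n",
              sum(cnt), cnt[["I"]], cnt[["II"]], cnt[["III"]], nrow(x)))
  if (nrow(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}
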