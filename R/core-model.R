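#' scaffpred: scaffold protein prediction from interactomes
#'
#' Scaffold proteins assemble two or more partner proteins into one place to
#' organise signalling and metabolic reactions. This package predicts
#' scaffold candidates from a protein-protein interaction network by asking,
#' for every protein, whether structural evidence supports simultaneous
#' recruitment of two partners: interaction with at least two other proteins
#' (criterion 1), domain-domain interactions mediating the two partners
#' through *different* domain regions of the candidate (criterion 2, which
#' filters out hub proteins whose partners compete for one binding region),
#' and co-membership of the candidate and both partners in one protein
#' complex (criterion 3). Candidates are classified Type I (criteria 2 and
#' 3), Type II (criterion 2 only) or Type III (criterion 3 only).
#'
#' See `vignette("scaffold-prediction", package = "scaffpred")` for the full
#' model description, and [predict_scaffolds()] for the main entry point.
#'
#' @keywords internal
"_PACKAGE"

# ---- accession validation ---------------------------------------------------

assert_accessions <- function(x, what = "accession") {
  x <- as.character(x)
  bad <- is.na(x) | !nzchar(x) | grepl("[[:space:]]", x)
  if (any(bad)) {
    stop(sprintf("invalid %s value(s): %s", what,
                 paste(utils::head(unique(x[bad]), 3), collapse = ", ")),
         call. = FALSE)
  }
  x
}

# strip UniProt isoform suffixes such as "-1"; opt-in at the parser level
strip_isoform <- function(x) sub("-[0-9]+$", "", x)

# ---- interactome ------------------------------------------------------------

#' Build an interactome from an edge list
#'
#' Constructs an undirected, deduplicated protein-protein interaction graph.
#' Edges are unordered: `(A,B)` and `(B,A)` are the same edge. Self-loops
#' are stored (so the protein is part of the network) but never counted as
#' partners: a scaffold must recruit two *other* proteins, and the method
#' takes no position on homodimerisation.
#'
#' @param edge_list a two-column `data.frame`, `matrix`, or list of
#'   length-2 character vectors of protein accessions. Accessions are opaque
#'   case-sensitive tokens; they must be non-empty and contain no whitespace.
#' @return an object of class `interactome`, backed by an [igraph] graph,
#'   with components `graph` (loop-free simple graph), `self_loops`
#'   (accessions with a recorded self-interaction) and `edges` (canonical
#'   edge table, `p1 <= p2`, self-loops included).
#' @examples
#' net <- build_interactome(rbind(c("A", "B"), c("B", "A"), c("A", "C")))
#' partners(net, "A")
#' @seealso [partners()], [read_ppi()]
#' @export
build_interactome <- function(edge_list) {
  if (is.list(edge_list) && !is.data.frame(edge_list)) {
    if (length(edge_list) && !all(lengths(edge_list) == 2L))
      stop("each edge must have exactly two endpoints", call. = FALSE)
    edge_list <- do.call(rbind, lapply(edge_list, as.character))
  }
  m <- as.matrix(edge_list)
  if (length(m) && ncol(m) != 2L)
    stop("edge_list must have two columns", call. = FALSE)
  if (!nrow(m)) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(structure(list(graph = g, self_loops = character(0),
                          edges = data.frame(p1 = character(0), p2 = character(0),
                                             stringsAsFactors = FALSE)),
                     class = "interactome"))
  }
  a <- assert_accessions(m[, 1]); b <- assert_accessions(m[, 2])
  p1 <- pmin(a, b); p2 <- pmax(a, b)
  edges <- unique(data.frame(p1 = p1, p2 = p2, stringsAsFactors = FALSE))
  edges <- edges[order(edges$p1, edges$p2), , drop = FALSE]
  rownames(edges) <- NULL
  loop <- edges$p1 == edges$p2
  verts <- sort(unique(c(a, b)))
  g <- igraph::graph_from_data_frame(edges[!loop, , drop = FALSE],
                                     directed = FALSE,
                                     vertices = data.frame(name = verts))
  structure(list(graph = g, self_loops = edges$p1[loop], edges = edges),
            class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("<interactome> %d proteins, %d edges (%d self-loops)\n",
              length(interactome_proteins(x)), nrow(x$edges),
              length(x$self_loops)))
  invisible(x)
}

#' Proteins of an interactome
#' @param net an `interactome`
#' @return character vector of accessions (sorted)
#' @export
interactome_proteins <- function(net) {
  stopifnot(inherits(net, "interactome"))
  igraph::V(net$graph)$name %||% character(0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Interaction partners of a protein
#'
#' Neighbours of `p` in the interaction graph, excluding `p` itself
#' (self-loops never count as partners).
#'
#' @param net an `interactome`
#' @param p a protein accession present in the network
#' @return character vector of partner accessions, sorted
#' @export
partners <- function(net, p) {
  stopifnot(inherits(net, "interactome"))
  if (!p %in% interactome_proteins(net))
    stop(sprintf("protein '%s' is not in the interactome", p), call. = FALSE)
  sort(setdiff(names(igraph::neighbors(net$graph, p)), p))
}

#' Test whether two proteins interact
#' @inheritParams partners
#' @param q a second accession
#' @return logical scalar; `FALSE` for unknown proteins
#' @export
are_partners <- function(net, p, q) {
  ps <- interactome_proteins(net)
  if (!(p %in% ps) || !(q %in% ps) || p == q) return(FALSE)
  igraph::are_adjacent(net$graph, p, q)
}

# ---- domain architectures ---------------------------------------------------

#' Build per-protein domain architectures
#'
#' A domain architecture is the ordered list of domain instances (Pfam-style
#' family plus copy number and optional residue coordinates) on one protein.
#' Within a protein, instances are ordered by start coordinate where
#' coordinates exist; rows without coordinates keep their input order and
#' follow the coordinate-bearing rows. Copies of the same family are then
#' numbered `copy_index` = 1..k in that order, so indices are deterministic
#' given the input.
#'
#' @param df a `data.frame` with columns `protein`, `family` and optionally
#'   `start`, `end` (1-based inclusive residue coordinates; `NA` allowed
#'   per row). Rows with `start > end` are dropped with a warning.
#' @return an object of class `domain_architectures`: a `data.frame` with
#'   columns `protein`, `family`, `copy_index`, `start`, `end`.
#' @examples
#' arch <- domain_architectures(data.frame(
#'   protein = c("S", "S"), family = c("PF1", "PF1"),
#'   start = c(60, 1), end = c(110, 50)))
#' arch  # the copy starting at residue 1 gets copy_index 1
#' @export
domain_architectures <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("protein", "family")
  if (!all(need %in% names(df)))
    stop("need columns 'protein' and 'family'", call. = FALSE)
  if (!"start" %in% names(df)) df$start <- NA_integer_
  if (!"end" %in% names(df)) df$end <- NA_integer_
  df <- df[, c("protein", "family", "start", "end")]
  if (nrow(df)) {
    df$protein <- assert_accessions(df$protein, "protein")
    df$family <- assert_accessions(df$family, "domain family")
    df$start <- as.integer(df$start); df$end <- as.integer(df$end)
    bad <- !is.na(df$start) & !is.na(df$end) & df$start > df$end
    if (any(bad)) {
      warning(sprintf("dropping %d row(s) with start > end", sum(bad)),
              call. = FALSE)
      df <- df[!bad, , drop = FALSE]
    }
    neg <- (!is.na(df$start) & df$start < 1L) | (!is.na(df$end) & df$end < 1L)
    if (any(neg)) stop("residue coordinates must be >= 1", call. = FALSE)
    # stable: coordinates first (by start), coordinate-less rows in file order
    ord <- order(df$protein, is.na(df$start), df$start, seq_len(nrow(df)))
    df <- df[ord, , drop = FALSE]
    df$copy_index <- stats::ave(seq_len(nrow(df)),
                                df$protein, df$family,
                                FUN = seq_along)
  } else {
    df$copy_index <- integer(0)
  }
  rownames(df) <- NULL
  structure(df[, c("protein", "family", "copy_index", "start", "end")],
            class = c("domain_architectures", "data.frame"))
}

#' Domain instances of one protein
#'
#' @param arch a `domain_architectures` object
#' @param p protein accession
#' @return the instance rows for `p` (zero rows if the architecture is
#'   unknown or empty — an absent protein is treated as having no domains)
#' @export
architecture_of <- function(arch, p) {
  stopifnot(inherits(arch, "domain_architectures"))
  out <- arch[arch$protein == p, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# region labels "FAMILY.copy" identify a domain instance within one protein
region_label <- function(family, copy_index) paste0(family, ".", copy_index)

# ---- DDI network ------------------------------------------------------------

#' Build a domain-domain interaction network
#'
#' Unordered pairs of domain families with (structural) evidence of
#' interaction. Pairs are symmetric and deduplicated; homotypic pairs (a
#' family with itself) are allowed and meaningful.
#'
#' @param pairs a two-column `data.frame`/`matrix` of family accessions
#' @return an object of class `ddi_network` with a canonical pair table
#'   (`f1 <= f2`)
#' @export
ddi_network <- function(pairs) {
  m <- as.matrix(pairs)
  if (!nrow(m)) {
    tab <- data.frame(f1 = character(0), f2 = character(0),
                      stringsAsFactors = FALSE)
    return(structure(list(pairs = tab, keys = character(0)),
                     class = "ddi_network"))
  }
  if (ncol(m) != 2L) stop("pairs must have two columns", call. = FALSE)
  a <- assert_accessions(m[, 1], "domain family")
  b <- assert_accessions(m[, 2], "domain family")
  tab <- unique(data.frame(f1 = pmin(a, b), f2 = pmax(a, b),
                           stringsAsFactors = FALSE))
  tab <- tab[order(tab$f1, tab$f2), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(pairs = tab, keys = paste(tab$f1, tab$f2, sep = "\t")),
            class = "ddi_network")
}

#' @export
print.ddi_network <- function(x, ...) {
  cat(sprintf("<ddi_network> %d family pairs\n", nrow(x$pairs)))
  invisible(x)
}

#' Do two domain families interact?
#' @param ddi a `ddi_network`
#' @param fa,fb family accessions (order irrelevant)
#' @return logical scalar
#' @export
has_ddi <- function(ddi, fa, fb) {
  stopifnot(inherits(ddi, "ddi_network"))
  paste(pmin(fa, fb), pmax(fa, fb), sep = "\t") %in% ddi$keys
}

# ---- complex catalog --------------------------------------------------------

#' Build a protein complex catalog
#'
#' @param complexes a named list: complex id -> character vector of member
#'   accessions (each complex must have at least one member; memberships are
#'   deduplicated)
#' @return an object of class `complex_catalog`
#' @export
complex_catalog <- function(complexes) {
  stopifnot(is.list(complexes))
  ids <- names(complexes)
  if (length(complexes) && (is.null(ids) || any(!nzchar(ids))))
    stop("every complex needs a non-empty id", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate complex id", call. = FALSE)
  members <- lapply(complexes, function(v) sort(unique(assert_accessions(v))))
  if (any(lengths(members) == 0L))
    stop("complexes must have at least one member", call. = FALSE)
  structure(list(members = members), class = "complex_catalog")
}

#' @export
print.complex_catalog <- function(x, ...) {
  cat(sprintf("<complex_catalog> %d complexes, %d distinct proteins\n",
              length(x$members), length(unique(unlist(x$members)))))
  invisible(x)
}

#' Complexes containing a given protein set
#'
#' Returns the ids of every catalogued complex whose membership is a
#' superset of `members`. Unknown proteins simply match no complex.
#' Enlarging the query set can only shrink the result.
#'
#' @param catalog a `complex_catalog`
#' @param members non-empty character vector of accessions
#' @return sorted character vector of complex ids
#' @export
complexes_containing <- function(catalog, members) {
  stopifnot(inherits(catalog, "complex_catalog"))
  members <- unique(as.character(members))
  if (!length(members)) stop("members must be non-empty", call. = FALSE)
  hit <- vapply(catalog$members, function(s) all(members %in% s), logical(1))
  sort(names(catalog$members)[hit])
}

# ---- annotation maps --------------------------------------------------------

#' Build an annotation map
#'
#' Maps proteins to sets of annotation terms within one namespace
#' (e.g. `"localization"`, `"pathway"`, `"disease"`, `"drug_target"`).
#' Unannotated proteins are simply absent; an empty term set is invalid.
#'
#' @param assignments a named list: protein accession -> character vector of
#'   terms
#' @param namespace a label describing the vocabulary
#' @return an object of class `annotation_map`
#' @export
annotation_map <- function(assignments, namespace = "annotation") {
  stopifnot(is.list(assignments))
  ids <- names(assignments)
  if (length(assignments) && (is.null(ids) || any(!nzchar(ids))))
    stop("assignments must be named by protein accession", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate protein in annotation map", call. = FALSE)
  terms <- lapply(assignments, function(v) sort(unique(as.character(v))))
  if (any(lengths(terms) == 0L))
    stop("mapped proteins must have at least one term", call. = FALSE)
  terms <- terms[order(names(terms))]   # canonical protein order
  structure(list(assignments = terms, namespace = namespace),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("<annotation_map '%s'> %d proteins, %d distinct terms\n",
              x$namespace, length(x$assignments),
              length(unique(unlist(x$assignments)))))
  invisible(x)
}

#' Annotation terms of one protein
#' @param map an `annotation_map`
#' @param p protein accession
#' @return character vector of terms (empty if unannotated)
#' @export
terms_of <- function(map, p) {
  stopifnot(inherits(map, "annotation_map"))
  map$assignments[[p]] %||% character(0)
}

#' Proteins carrying a given term
#' @param map an `annotation_map`
#' @param term a term string
#' @return character vector of accessions
#' @export
proteins_with_term <- function(map, term) {
  hit <- vapply(map$assignments, function(v) term %in% v, logical(1))
  sort(names(map$assignments)[hit])
}

# ---- 2x2 contingency table --------------------------------------------------

#' Construct a 2x2 contingency table
#'
#' Cell layout follows the epidemiological convention: row 1 is the
#' exposed / predicted-positive group (`a`, `b`), row 2 the rest (`c`, `d`);
#' column 1 is trait/condition positive. Marginals are always derived from
#' the cells, never stored.
#'
#' @param a,b,c,d nonnegative integer cell counts; the grand total must be
#'   at least 1
#' @return an object of class `contingency_2x2`
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cells must be nonnegative integers", call. = FALSE)
  if (sum(cells) < 1) stop("grand total must be >= 1", call. = FALSE)
  cells <- as.integer(round(cells))
  structure(list(a = cells[1], b = cells[2], c = cells[3], d = cells[4]),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- as.matrix(x)
  print(m)
  invisible(x)
}

#' @export
as.matrix.contingency_2x2 <- function(x, ...) {
  matrix(c(x$a, x$b, x$c, x$d), nrow = 2, byrow = TRUE,
         dimnames = list(group = c("in", "out"),
                         trait = c("positive", "negative")))
}
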