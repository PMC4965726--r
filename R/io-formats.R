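# File formats
#
#  - two-column TSV edge list ("tsv2"): '#' comments, blank lines ignored
#  - PSI-MI TAB 2.5 ("mitab"): interactor ids from columns 1-2 (the
#    "uniprotkb:" prefix is stripped), detection method from column 7
#  - domain table: protein TAB family [TAB start TAB end]
#  - DDI pair list: familyA TAB familyB [TAB evidence]
#  - GMT gene sets: set-id TAB description TAB member1 TAB member2 ...
#  - prediction table: see write_predictions()

read_text_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
}

#' Evidence filter configuration
#'
#' Mirrors the curation steps applied to public interaction resources:
#' keeping protein interactions with an experimental detection method and
#' domain interactions with three-dimensional structural evidence.
#'
#' When a `require_*` flag is on, records lacking a recognisable evidence
#' column are *dropped*, not passed through. `allowed_evidence_codes` lists
#' acceptable method identifiers (e.g. PSI-MI codes such as `"MI:0018"`);
#' an empty set means "any non-empty method".
#'
#' @param require_experimental_ppi drop PPI records without an acceptable
#'   detection method
#' @param require_structural_ddi drop DDI records without an acceptable
#'   evidence tag
#' @param allowed_evidence_codes character vector of acceptable codes
#' @return a list of class `evidence_filter`
#' @export
evidence_filter <- function(require_experimental_ppi = FALSE,
                            require_structural_ddi = FALSE,
                            allowed_evidence_codes = character(0)) {
  structure(list(require_experimental_ppi = isTRUE(require_experimental_ppi),
                 require_structural_ddi = isTRUE(require_structural_ddi),
                 allowed_evidence_codes = as.character(allowed_evidence_codes)),
            class = "evidence_filter")
}

evidence_ok <- function(field, allowed) {
  field <- trimws(field)
  if (!nzchar(field) || field == "-") return(FALSE)
  if (!length(allowed)) return(TRUE)
  any(vapply(allowed, grepl, logical(1), x = field, fixed = TRUE))
}

#' Read a protein-protein interaction file
#'
#' Parses either a plain two-column TSV edge list or a PSI-MI TAB 2.5 file
#' into an [interactome][build_interactome]. Malformed lines are counted
#' and reported as a warning; the read only fails if no line is valid.
#'
#' @param path file path
#' @param format `"tsv2"` (default) or `"mitab"`
#' @param filter an [evidence_filter()]; with `require_experimental_ppi`
#'   only MITAB rows with an acceptable detection method (column 7) are
#'   kept, and plain TSV rows, having no evidence column, are all dropped
#' @param strip_isoforms drop UniProt isoform suffixes (`"P12345-2"` ->
#'   `"P12345"`); off by default
#' @return an `interactome`
#' @export
read_ppi <- function(path, format = c("tsv2", "mitab"),
                     filter = evidence_filter(), strip_isoforms = FALSE) {
  format <- match.arg(format)
  stopifnot(inherits(filter, "evidence_filter"))
  lines <- read_text_lines(path)
  edges <- matrix(character(0), 0, 2)
  n_bad <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    ok <- FALSE
    if (format == "tsv2") {
      if (length(f) >= 2 && nzchar(trimws(f[1])) && nzchar(trimws(f[2])) &&
          !filter$require_experimental_ppi) {
        a <- trimws(f[1]); b <- trimws(f[2]); ok <- TRUE
      }
    } else {
      if (length(f) >= 7) {
        a <- sub("^uniprotkb:", "", trimws(f[1]))
        b <- sub("^uniprotkb:", "", trimws(f[2]))
        if (nzchar(a) && nzchar(b) &&
            (!filter$require_experimental_ppi ||
             evidence_ok(f[7], filter$allowed_evidence_codes)))
          ok <- TRUE
      }
    }
    if (ok) edges <- rbind(edges, c(a, b)) else n_bad <- n_bad + 1L
  }
  if (!nrow(edges))
    stop(sprintf("format error: no valid interaction records in '%s'", path),
         call. = FALSE)
  if (n_bad > 0)
    warning(sprintf("%d line(s) skipped in '%s'", n_bad, path), call. = FALSE)
  if (strip_isoforms) edges[] <- strip_isoform(edges)
  build_interactome(edges)
}

#' Write an interactome as a two-column TSV edge list
#'
#' One canonical row per edge (`p1 <= p2`, self-loops included), sorted;
#' re-reading with [read_ppi()] restores an identical graph.
#'
#' @param net an `interactome`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ppi <- function(net, path) {
  stopifnot(inherits(net, "interactome"))
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-protein domain architectures
#'
#' Expects a TSV with columns protein, family and optionally start, end
#' (1-based inclusive residue coordinates; either both or neither per row).
#' Rows with `start > end` are rejected with a warning. Copy indices are
#' assigned by [domain_architectures()].
#'
#' @param path file path
#' @param strip_isoforms as in [read_ppi()]
#' @return a `domain_architectures` object
#' @export
read_architectures <- function(path, strip_isoforms = FALSE) {
  lines <- read_text_lines(path)
  rows <- lapply(lines, function(ln) {
    f <- trimws(strsplit(ln, "\t", fixed = TRUE)[[1]])
    if (length(f) < 2 || !nzchar(f[1]) || !nzchar(f[2])) return(NULL)
    data.frame(protein = f[1], family = f[2],
               start = if (length(f) >= 3 && nzchar(f[3])) as.integer(f[3]) else NA_integer_,
               end = if (length(f) >= 4 && nzchar(f[4])) as.integer(f[4]) else NA_integer_,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(protein = character(0), family = character(0),
                                    start = integer(0), end = integer(0))
  if (strip_isoforms) df$protein <- strip_isoform(df$protein)
  domain_architectures(df)
}

#' Write domain architectures
#' @param arch a `domain_architectures` object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_architectures <- function(arch, path) {
  stopifnot(inherits(arch, "domain_architectures"))
  out <- arch[, c("protein", "family", "start", "end")]
  out$start[is.na(out$start)] <- ""
  out$end[is.na(out$end)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a domain-domain interaction pair list
#'
#' Two tab-separated family accessions per line; an optional third column
#' carries an evidence tag, consulted when `filter$require_structural_ddi`
#' is on (rows without an acceptable tag are dropped).
#'
#' @param path file path
#' @param filter an [evidence_filter()]
#' @return a `ddi_network`
#' @export
read_ddi <- function(path, filter = evidence_filter()) {
  stopifnot(inherits(filter, "evidence_filter"))
  lines <- read_text_lines(path)
  pairs <- matrix(character(0), 0, 2)
  n_bad <- 0L
  for (ln in lines) {
    f <- trimws(strsplit(ln, "\t", fixed = TRUE)[[1]])
    ok <- length(f) >= 2 && nzchar(f[1]) && nzchar(f[2])
    if (ok && filter$require_structural_ddi)
      ok <- length(f) >= 3 && evidence_ok(f[3], filter$allowed_evidence_codes)
    if (ok) pairs <- rbind(pairs, f[1:2]) else n_bad <- n_bad + 1L
  }
  if (!nrow(pairs))
    stop(sprintf("format error: no valid DDI records in '%s'", path),
         call. = FALSE)
  if (n_bad > 0)
    warning(sprintf("%d line(s) skipped in '%s'", n_bad, path), call. = FALSE)
  ddi_network(pairs)
}

#' Write a DDI pair list
#' @param ddi a `ddi_network`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_ddi <- function(ddi, path) {
  stopifnot(inherits(ddi, "ddi_network"))
  utils::write.table(ddi$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' GMT: one set per line, `set-id TAB description TAB member1 TAB ...`.
#' Read either as a [complex_catalog()] (`as = "complexes"`) or inverted
#' into a protein -> term [annotation_map()] (`as = "annotations"`, where
#' the set id is the term). Sets with an empty member list are dropped with
#' a warning; a duplicated set id is a format error.
#'
#' @param path file path
#' @param as `"complexes"` or `"annotations"`
#' @param namespace namespace label for the annotation map
#' @return a `complex_catalog` or `annotation_map`
#' @export
read_gene_sets <- function(path, as = c("complexes", "annotations"),
                           namespace = "annotation") {
  as <- match.arg(as)
  lines <- read_text_lines(path)
  sets <- list(); n_empty <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 1 || !nzchar(trimws(f[1]))) next
    id <- trimws(f[1])
    members <- if (length(f) >= 3) trimws(f[3:length(f)]) else character(0)
    members <- members[nzchar(members)]
    if (!length(members)) { n_empty <- n_empty + 1L; next }
    if (id %in% names(sets))
      stop(sprintf("format error: duplicate set id '%s' in '%s'", id, path),
           call. = FALSE)
    sets[[id]] <- members
  }
  if (n_empty > 0)
    warning(sprintf("%d empty set(s) dropped in '%s'", n_empty, path),
            call. = FALSE)
  if (as == "complexes") return(complex_catalog(sets))
  # invert term -> members into protein -> terms
  prot <- unlist(sets, use.names = FALSE)
  term <- rep(names(sets), lengths(sets))
  annotation_map(split(term, prot), namespace = namespace)
}

#' Write gene sets in GMT format
#'
#' Accepts a `complex_catalog` (one line per complex) or an
#' `annotation_map` (inverted back to one line per term). Round-trips with
#' [read_gene_sets()].
#'
#' @param x a `complex_catalog` or `annotation_map`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gene_sets <- function(x, path) {
  if (inherits(x, "complex_catalog")) {
    sets <- x$members
  } else if (inherits(x, "annotation_map")) {
    term <- unlist(x$assignments, use.names = FALSE)
    prot <- rep(names(x$assignments), lengths(x$assignments))
    sets <- lapply(split(prot, term), function(v) sort(unique(v)))
  } else stop("x must be a complex_catalog or annotation_map", call. = FALSE)
  ids <- sort(names(sets))
  lines <- vapply(ids, function(id)
    paste(c(id, "na", sets[[id]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain protein list
#'
#' One accession per line; comments and blanks ignored. Used for gold
#' standard positive/negative sets and group/universe lists.
#'
#' @param path file path
#' @return character vector of unique accessions
#' @export
read_protein_list <- function(path) {
  lines <- trimws(read_text_lines(path))
  unique(assert_accessions(lines[nzchar(lines)], "protein"))
}

#' Write a plain protein list
#' @param proteins character vector of accessions
#' @param path output path
#' @return `path`, invisibly
#' @export
write_protein_list <- function(proteins, path) {
  writeLines(sort(unique(as.character(proteins))), path)
  invisible(path)
}

# ---- predictions ------------------------------------------------------------

#' Write scaffold predictions
#'
#' One row per witness pair, TSV columns: `scaffold`, `type_class`,
#' `n_witnesses`, `p1`, `p2`, `region1`, `region2` (domain instance labels
#' `family.copy`, or `"."` when the witness carries no region),
#' `complex_id` (`"."` when none). Rows are ordered by scaffold, then
#' `p1`, `p2`, so output is deterministic.
#'
#' @param predictions a `scaffold_predictions` object from
#'   [predict_scaffolds()]
#' @param path output path
#' @return `path`, invisibly
#' @seealso [read_predictions()]
#' @export
write_predictions <- function(predictions, path) {
  stopifnot(inherits(predictions, "scaffold_predictions"))
  df <- as.data.frame(predictions)
  df <- df[order(df$scaffold, df$p1, df$p2), , drop = FALSE]
  nw <- stats::ave(seq_len(nrow(df)), df$scaffold, FUN = length)
  out <- data.frame(scaffold = df$scaffold, type_class = df$type_class,
                    n_witnesses = nw, p1 = df$p1, p2 = df$p2,
                    region1 = ifelse(is.na(df$region1), ".", df$region1),
                    region2 = ifelse(is.na(df$region2), ".", df$region2),
                    complex_id = ifelse(is.na(df$complex_id), ".", df$complex_id),
                    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  if (nrow(out))
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read scaffold predictions written by [write_predictions()]
#'
#' @param path file path
#' @return a `scaffold_predictions` object
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  need <- c("scaffold", "type_class", "p1", "p2", "region1", "region2",
            "complex_id")
  if (!all(need %in% names(df)))
    stop(sprintf("format error: missing prediction columns in '%s'", path),
         call. = FALSE)
  out <- df[, need]
  for (col in c("region1", "region2", "complex_id"))
    out[[col]][out[[col]] == "."] <- NA_character_
  new_scaffold_predictions(out)
}
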