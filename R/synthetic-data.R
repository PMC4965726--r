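# Seeded generator of complete synthetic datasets with planted ground
# truth. Each planted motif mirrors one structural pattern the predictor is
# designed to detect (or reject):
#
#   Type I   scaffold with two domain families, each DDI-linked to a
#            different partner's family, both edges present, plus a triad
#            complex {scaffold, partner A, partner B}
#   Type II  the same minus the complex
#   Type III the triad complex, but the scaffold carries at most one domain
#            instance, so distinct-region recruitment is impossible
#   hub      a single-domain protein with `hub_degree` partners all docking
#            through that one domain (competitive binding) and no triad
#            complex -- must NOT be predicted
#
# Background proteins carry fresh domain families that appear in no DDI
# pair and belong to no complex, and are wired only among themselves, so
# they can never accidentally complete a criterion-2 or criterion-3 motif:
# the planted labels are exact by construction.

#' Configuration for the synthetic data generator
#'
#' Defaults plant a small benchmark with 5/7/3 scaffolds of Types I/II/III
#' and 4 hub decoys against 50 background proteins — large enough that each
#' motif class is exercised several times, small enough to audit by hand.
#'
#' @param n_type1,n_type2,n_type3 number of planted scaffolds per type
#' @param n_hub_decoys number of hub decoys (high-degree, single-region)
#' @param n_background_proteins proteins with no planted role
#' @param hub_degree partners per hub decoy (must be >= 2 or the decoy
#'   would not even pass criterion 1)
#' @param background_edge_prob Erdős–Rényi edge probability among
#'   background proteins
#' @param ddi_dropout probability that a planted DDI pair is deleted,
#'   emulating incomplete domain-interaction resources (erodes criterion 2:
#'   Type I degrades toward Type III, Type II toward no call)
#' @param complex_dropout probability that a planted complex is deleted
#'   (erodes criterion 3: Type I degrades toward Type II, Type III toward
#'   no call)
#' @param annotation_match_rate probability that a planted scaffold shares
#'   its localization/pathway term with one of its witness partners
#' @param seed integer seed; identical seed and config give identical output
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_type1 = 5, n_type2 = 7, n_type3 = 3,
                       n_hub_decoys = 4, n_background_proteins = 50,
                       hub_degree = 4, background_edge_prob = 0.02,
                       ddi_dropout = 0, complex_dropout = 0,
                       annotation_match_rate = 0.9, seed = 1L) {
  cfg <- list(n_type1 = as.integer(n_type1), n_type2 = as.integer(n_type2),
              n_type3 = as.integer(n_type3),
              n_hub_decoys = as.integer(n_hub_decoys),
              n_background_proteins = as.integer(n_background_proteins),
              hub_degree = as.integer(hub_degree),
              background_edge_prob = background_edge_prob,
              ddi_dropout = ddi_dropout, complex_dropout = complex_dropout,
              annotation_match_rate = annotation_match_rate,
              seed = as.integer(seed))
  counts <- unlist(cfg[c("n_type1", "n_type2", "n_type3", "n_hub_decoys",
                         "n_background_proteins")])
  if (any(is.na(counts)) || any(counts < 0))
    stop("config error: counts must be nonnegative", call. = FALSE)
  if (cfg$n_hub_decoys > 0 && cfg$hub_degree < 2)
    stop("config error: hub_degree must be >= 2", call. = FALSE)
  probs <- unlist(cfg[c("background_edge_prob", "ddi_dropout",
                        "complex_dropout", "annotation_match_rate")])
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    stop("config error: probabilities must lie in [0, 1]", call. = FALSE)
  structure(cfg, class = "sim_config")
}

# the 17 cellular compartments used as the localization vocabulary
compartments17 <- c(
  "cell_surface", "chromosome", "cytoplasm",
  "cytoplasmic_membrane_bounded_vesicle", "cytoskeleton", "cytosol",
  "endoplasmic_reticulum", "endosome", "er_golgi_intermediate_compartment",
  "extracellular_region", "golgi_apparatus", "mitochondrion", "nucleus",
  "plasma_membrane", "ribosome", "sarcoplasmic_reticulum", "vacuole")

#' Generate a synthetic scaffold-prediction dataset
#'
#' Builds every input the prediction pipeline consumes — interactome,
#' domain architectures, DDI network, complex catalog, localization and
#' pathway annotation maps, gold-standard lists — with planted ground
#' truth. See the package source header of this file for the motif
#' templates.
#'
#' Gold lists: positives are the planted scaffolds, negatives the hub
#' decoys and background proteins.
#'
#' @param config a [sim_config()]
#' @return a list of class `sim_dataset` with elements `net`, `arch`,
#'   `ddi`, `catalog`, `localization`, `pathway`, `gold_pos`, `gold_neg`,
#'   `truth` (a `data.frame` of `protein`, `label` in
#'   `I`/`II`/`III`/`hub`/`partner`/`background`) and `config`
#' @examples
#' d <- generate_scaffold_data(sim_config(n_type1 = 1, n_type2 = 0,
#'                                        n_type3 = 0, n_hub_decoys = 0,
#'                                        n_background_proteins = 0))
#' prediction_counts(predict_scaffolds(d$net, d$arch, d$ddi, d$catalog))
#' @export
generate_scaffold_data <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, generate_impl(config))
}

generate_impl <- function(cfg) {
  edges <- list(); arch <- list(); ddi <- list(); complexes <- list()
  loc <- list(); pw <- list(); truth <- list()
  add_edge <- function(a, b) edges[[length(edges) + 1L]] <<- c(a, b)
  add_dom <- function(p, f) arch[[length(arch) + 1L]] <<-
    data.frame(protein = p, family = f, stringsAsFactors = FALSE)
  add_ddi <- function(a, b) ddi[[length(ddi) + 1L]] <<- c(a, b)
  add_truth <- function(p, l) truth[[p]] <<- l
  annotate <- function(p, lterm, pterm) {
    loc[[p]] <<- unique(c(loc[[p]], lterm)); pw[[p]] <<- unique(c(pw[[p]], pterm))
  }
  fresh_term <- function(used, vocab) {
    free <- setdiff(vocab, used)
    if (length(free)) sample(free, 1) else sample(vocab, 1)
  }
  pathways <- sprintf("PW_%02d", 1:25)

  plant_scaffold <- function(i, type) {
    tag <- sprintf("%s_%03d", c(I = "S1", II = "S2", III = "S3")[type], i)
    s <- tag; pa <- paste0(tag, "A"); pb <- paste0(tag, "B")
    add_edge(s, pa); add_edge(s, pb)
    add_truth(s, type); add_truth(pa, "partner"); add_truth(pb, "partner")
    if (type %in% c("I", "II")) {
      dsa <- paste0("D", tag, "a"); dsb <- paste0("D", tag, "b")
      dpa <- paste0("D", tag, "pa"); dpb <- paste0("D", tag, "pb")
      add_dom(s, dsa); add_dom(s, dsb); add_dom(pa, dpa); add_dom(pb, dpb)
      if (stats::runif(1) >= cfg$ddi_dropout) add_ddi(dsa, dpa)
      if (stats::runif(1) >= cfg$ddi_dropout) add_ddi(dsb, dpb)
    } else {
      add_dom(s, paste0("D", tag, "x"))           # single instance: no
      add_dom(pa, paste0("D", tag, "pa"))         # distinct-region pair
      add_dom(pb, paste0("D", tag, "pb"))         # possible, no DDI planted
    }
    if (type %in% c("I", "III") && stats::runif(1) >= cfg$complex_dropout)
      complexes[[paste0("CPX_", tag)]] <<- c(s, pa, pb)
    # annotations: the scaffold shares its term with partner A at the
    # configured match rate; partner B always gets a fresh term
    lt <- sample(compartments17, 1); pt <- sample(pathways, 1)
    matched <- stats::runif(1) < cfg$annotation_match_rate
    annotate(s, lt, pt)
    if (matched) annotate(pa, lt, pt)
    else annotate(pa, fresh_term(lt, compartments17), fresh_term(pt, pathways))
    annotate(pb, fresh_term(lt, compartments17), fresh_term(pt, pathways))
  }

  for (i in seq_len(cfg$n_type1)) plant_scaffold(i, "I")
  for (i in seq_len(cfg$n_type2)) plant_scaffold(i, "II")
  for (i in seq_len(cfg$n_type3)) plant_scaffold(i, "III")

  for (i in seq_len(cfg$n_hub_decoys)) {
    h <- sprintf("HUB_%03d", i)
    dh <- paste0("D", h); fh <- paste0("F", h)
    add_dom(h, dh); add_ddi(dh, fh); add_truth(h, "hub")
    annotate(h, sample(compartments17, 1), sample(pathways, 1))
    for (j in seq_len(cfg$hub_degree)) {
      p <- sprintf("%sP%02d", h, j)
      add_edge(h, p); add_dom(p, fh); add_truth(p, "partner")
    }
  }

  bg <- sprintf("BG_%03d", seq_len(cfg$n_background_proteins))
  for (p in bg) {
    add_dom(p, paste0("D", p)); add_truth(p, "background")
    annotate(p, sample(compartments17, 1), sample(pathways, 1))
  }
  if (length(bg) >= 2) {
    pairs <- utils::combn(bg, 2)
    pick <- stats::runif(ncol(pairs)) < cfg$background_edge_prob
    for (k in which(pick)) add_edge(pairs[1, k], pairs[2, k])
  }

  # isolated proteins (possible under low edge probability) still belong to
  # the universe: anchor them with a self-loop so readers/writers keep them
  all_p <- names(truth)
  seen <- unique(unlist(edges))
  for (p in setdiff(all_p, seen)) add_edge(p, p)

  if (!length(ddi)) ddi <- list(c("DNULL_A", "DNULL_B"))  # non-empty network

  net <- build_interactome(do.call(rbind, edges))
  labels <- unlist(truth)
  scaffolds <- sort(names(labels)[labels %in% c("I", "II", "III")])
  structure(list(
    net = net,
    arch = domain_architectures(do.call(rbind, arch)),
    ddi = ddi_network(do.call(rbind, ddi)),
    catalog = complex_catalog(complexes),
    localization = annotation_map(loc, "localization"),
    pathway = annotation_map(pw, "pathway"),
    gold_pos = scaffolds,
    gold_neg = sort(names(labels)[labels %in% c("hub", "background")]),
    truth = data.frame(protein = names(labels),
                       label = unname(labels),
                       stringsAsFactors = FALSE),
    config = cfg), class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  tab <- table(x$truth$label)
  cat("<sim_dataset>", paste(names(tab), as.integer(tab), sep = "=",
                             collapse = " "), "\n")
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Emits every file format the readers understand: `ppi.tsv`,
#' `domains.tsv`, `ddi.tsv`, `complexes.gmt`, `localization.gmt`,
#' `pathway.gmt`, `gold_pos.txt`, `gold_neg.txt` and `truth_labels.tsv`.
#' Output is deterministic: the same dataset writes byte-identical files.
#'
#' @param dataset a `sim_dataset` from [generate_scaffold_data()]
#' @param outdir output directory (created if needed)
#' @return named character vector of written paths, invisibly
#' @export
write_scaffold_data <- function(dataset, outdir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(outdir, f)
  write_ppi(dataset$net, pth("ppi.tsv"))
  write_architectures(dataset$arch, pth("domains.tsv"))
  write_ddi(dataset$ddi, pth("ddi.tsv"))
  write_gene_sets(dataset$catalog, pth("complexes.gmt"))
  write_gene_sets(dataset$localization, pth("localization.gmt"))
  write_gene_sets(dataset$pathway, pth("pathway.gmt"))
  write_protein_list(dataset$gold_pos, pth("gold_pos.txt"))
  write_protein_list(dataset$gold_neg, pth("gold_neg.txt"))
  tr <- dataset$truth[order(dataset$truth$protein), ]
  utils::write.table(tr, pth("truth_labels.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  files <- c("ppi.tsv", "domains.tsv", "ddi.tsv", "complexes.gmt",
             "localization.gmt", "pathway.gmt", "gold_pos.txt",
             "gold_neg.txt", "truth_labels.tsv")
  invisible(stats::setNames(file.path(outdir, files), files))
}
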