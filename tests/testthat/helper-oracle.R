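# Brute-force reference implementation used to cross-check the predictor.
# Works directly on raw inputs (edge matrix, architecture table, DDI
# matrix, complex list) and enumerates every (scaffold, p1, p2) triple and
# every region assignment. Deliberately naive and independent of the
# package's data structures.

oracle_neighbors <- function(edges, p) {
  hit <- c(edges[edges[, 1] == p, 2], edges[edges[, 2] == p, 1])
  sort(setdiff(unique(hit), p))
}

# copy indices by per-(protein, family) file order, as the parser does
oracle_instances <- function(arch_df, p) {
  rows <- arch_df[arch_df$protein == p, , drop = FALSE]
  if (!nrow(rows)) return(data.frame(family = character(0), copy = integer(0)))
  copy <- stats::ave(seq_len(nrow(rows)), rows$family, FUN = seq_along)
  data.frame(family = rows$family, copy = copy, stringsAsFactors = FALSE)
}

oracle_ddi_has <- function(ddi_mat, fa, fb) {
  if (!nrow(ddi_mat)) return(FALSE)
  any((ddi_mat[, 1] == fa & ddi_mat[, 2] == fb) |
      (ddi_mat[, 1] == fb & ddi_mat[, 2] == fa))
}

oracle_regions <- function(arch_df, ddi_mat, s, p, require_known = TRUE) {
  rs <- oracle_instances(arch_df, s)
  if (!nrow(rs)) return(rs)
  fp <- unique(arch_df$family[arch_df$protein == p])
  if (!length(fp)) {
    if (require_known) return(rs[0, , drop = FALSE])
    return(rs)
  }
  keep <- vapply(seq_len(nrow(rs)), function(i)
    any(vapply(fp, function(g) oracle_ddi_has(ddi_mat, rs$family[i], g),
               logical(1))), logical(1))
  rs[keep, , drop = FALSE]
}

# returns list(types = named character, c2 = named list of pair keys,
#              c3 = named list of pair keys)
oracle_classify_all <- function(edges, arch_df, ddi_mat, complexes,
                                joint = TRUE, semantics = "instance",
                                require_known = TRUE) {
  prots <- sort(unique(c(edges[, 1], edges[, 2])))
  types <- stats::setNames(character(0), character(0))
  c2l <- list(); c3l <- list()
  for (s in prots) {
    ps <- oracle_neighbors(edges, s)
    if (length(ps) < 2) next
    k2 <- character(0); k3 <- character(0)
    combs <- utils::combn(ps, 2)
    for (ci in seq_len(ncol(combs))) {
      p1 <- combs[1, ci]; p2 <- combs[2, ci]
      r1 <- oracle_regions(arch_df, ddi_mat, s, p1, require_known)
      r2 <- oracle_regions(arch_df, ddi_mat, s, p2, require_known)
      ok2 <- FALSE
      if (nrow(r1) && nrow(r2)) {
        for (a in seq_len(nrow(r1))) for (b in seq_len(nrow(r2))) {
          distinct <- if (semantics == "family") r1$family[a] != r2$family[b]
            else !(r1$family[a] == r2$family[b] && r1$copy[a] == r2$copy[b])
          if (distinct) ok2 <- TRUE
        }
      }
      if (ok2) k2 <- c(k2, paste(p1, p2))
      ok3 <- any(vapply(complexes, function(m)
        all(c(s, p1, p2) %in% m), logical(1)))
      if (ok3) k3 <- c(k3, paste(p1, p2))
    }
    if (!length(k2) && !length(k3)) next
    types[s] <- if (joint) {
      if (length(intersect(k2, k3))) "I" else if (length(k2)) "II" else "III"
    } else {
      if (length(k2) && length(k3)) "I" else if (length(k2)) "II" else "III"
    }
    c2l[[s]] <- sort(k2); c3l[[s]] <- sort(k3)
  }
  list(types = types, c2 = c2l, c3 = c3l)
}

# random instance generator for the equivalence checks
random_instance <- function(seed, n_max = 30) {
  withr::with_seed(seed, {
    n <- sample(4:n_max, 1)
    prots <- sprintf("P%02d", seq_len(n))
    pairs <- utils::combn(prots, 2)
    pick <- stats::runif(ncol(pairs)) < 0.15
    edges <- t(pairs[, pick, drop = FALSE])
    if (!nrow(edges)) edges <- t(pairs[, 1, drop = FALSE])
    fams <- sprintf("F%02d", 1:8)
    arch_rows <- list()
    for (p in prots) {
      k <- sample(0:3, 1)
      if (k > 0)
        arch_rows[[p]] <- data.frame(protein = p,
                                     family = sample(fams, k, replace = TRUE),
                                     stringsAsFactors = FALSE)
    }
    arch_df <- if (length(arch_rows)) do.call(rbind, arch_rows)
      else data.frame(protein = character(0), family = character(0))
    fpairs <- expand.grid(f1 = fams, f2 = fams, stringsAsFactors = FALSE)
    fpairs <- fpairs[fpairs$f1 <= fpairs$f2, ]
    dd <- fpairs[stats::runif(nrow(fpairs)) < 0.2, , drop = FALSE]
    ddi_mat <- as.matrix(dd)
    if (!nrow(ddi_mat)) ddi_mat <- matrix(c("F01", "F02"), 1)
    n_cx <- sample(0:4, 1)
    complexes <- list()
    for (i in seq_len(n_cx))
      complexes[[paste0("CX", i)]] <- sample(prots, sample(2:min(5, n), 1))
    list(edges = edges, arch = arch_df, ddi = ddi_mat,
         complexes = complexes)
  })
}

# run the package predictor on a raw instance
package_predict_instance <- function(inst, joint = TRUE,
                                     semantics = "instance",
                                     require_known = TRUE) {
  net <- build_interactome(inst$edges)
  arch <- domain_architectures(inst$arch)
  ddi <- ddi_network(inst$ddi)
  catalog <- if (length(inst$complexes)) complex_catalog(inst$complexes)
    else complex_catalog(list(CX_EMPTY = "ZZ_NONE"))
  cfg <- predictor_config(joint_witness = joint, region_semantics = semantics,
                          require_partner_domain_known = require_known)
  predict_scaffolds(net, arch, ddi, catalog, cfg)
}

prediction_types <- function(pred) {
  u <- unique(as.data.frame(pred)[, c("scaffold", "type_class")])
  stats::setNames(u$type_class, u$scaffold)[order(u$scaffold)]
}
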