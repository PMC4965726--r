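# Shared toy instance: S is a genuine Type I scaffold, H is a hub decoy
# whose four partners all dock on the same single domain region.
toy_instance <- function() {
  list(
    net = build_interactome(rbind(c("S", "A"), c("S", "B"),
                                  c("H", "P1"), c("H", "P2"),
                                  c("H", "P3"), c("H", "P4"))),
    arch = domain_architectures(data.frame(
      protein = c("S", "S", "A", "B", "H", "P1", "P2", "P3", "P4"),
      family = c("D1", "D2", "D3", "D4", "D5", "D6", "D6", "D6", "D6"))),
    ddi = ddi_network(rbind(c("D1", "D3"), c("D2", "D4"), c("D5", "D6"))),
    catalog = complex_catalog(list(X = c("S", "A", "B"))))
}

test_that("criterion 1 selects proteins with at least two partners", {
  path <- build_interactome(rbind(c("A", "B"), c("B", "C")))
  expect_equal(criterion1(path), "B")
  tri <- build_interactome(rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  expect_equal(criterion1(tri), c("A", "B", "C"))
  # self-loop does not rescue a degree-1 protein
  loopy <- build_interactome(rbind(c("A", "B"), c("A", "A")))
  expect_length(criterion1(loopy), 0)
  # random graph: equals the brute-force degree filter
  for (seed in 1:5) {
    inst <- random_instance(seed)
    net <- build_interactome(inst$edges)
    want <- Filter(function(p) length(oracle_neighbors(inst$edges, p)) >= 2,
                   interactome_proteins(net))
    expect_equal(criterion1(net), sort(want))
  }
})

test_that("mediating regions follow the DDI network, including homotypic pairs", {
  t <- toy_instance()
  mr <- mediating_regions("S", "A", t$net, t$arch, t$ddi)
  expect_equal(mr$family, "D1")
  expect_equal(mediating_regions("S", "B", t$net, t$arch, t$ddi)$family, "D2")
  expect_error(mediating_regions("S", "P1", t$net, t$arch, t$ddi), "no edge")

  # partner without domains contributes nothing (default)...
  net <- build_interactome(rbind(c("S", "Q")))
  arch <- domain_architectures(data.frame(protein = "S", family = "D1"))
  ddi <- ddi_network(rbind(c("D1", "D9")))
  expect_equal(nrow(mediating_regions("S", "Q", net, arch, ddi)), 0)
  # ...unless the config is permissive about unknown partner domains
  cfg <- predictor_config(require_partner_domain_known = FALSE)
  expect_equal(nrow(mediating_regions("S", "Q", net, arch, ddi, cfg)), 1)

  # homotypic DDI: both proteins carry D5, D5-D5 interacts
  net2 <- build_interactome(rbind(c("S", "P")))
  arch2 <- domain_architectures(data.frame(protein = c("S", "S", "P"),
                                           family = c("D5", "D5", "D5")))
  ddi2 <- ddi_network(rbind(c("D5", "D5")))
  mr2 <- mediating_regions("S", "P", net2, arch2, ddi2)
  expect_equal(nrow(mr2), 2)
  expect_equal(mr2$copy_index, c(1, 2))
})

test_that("criterion 2 certifies distinct-region recruitment and filters hubs", {
  t <- toy_instance()
  w <- criterion2_witnesses("S", t$net, t$arch, t$ddi)
  expect_equal(nrow(w), 1)
  expect_equal(w$p1, "A"); expect_equal(w$p2, "B")
  expect_equal(w$region1, "D1.1"); expect_equal(w$region2, "D2.1")

  # the hub: four partners, all through the single D5 region
  expect_equal(nrow(criterion2_witnesses("H", t$net, t$arch, t$ddi)), 0)
})

test_that("two copies of one family count as distinct regions only at instance semantics", {
  net <- build_interactome(rbind(c("H", "Q1"), c("H", "Q2")))
  arch <- domain_architectures(data.frame(
    protein = c("H", "H", "Q1", "Q2"),
    family = c("D5", "D5", "D6", "D6")))
  ddi <- ddi_network(rbind(c("D5", "D6")))
  w_inst <- criterion2_witnesses("H", net, arch, ddi,
                                 predictor_config(region_semantics = "instance"))
  expect_equal(nrow(w_inst), 1)
  expect_equal(c(w_inst$region1, w_inst$region2), c("D5.1", "D5.2"))
  w_fam <- criterion2_witnesses("H", net, arch, ddi,
                                predictor_config(region_semantics = "family"))
  expect_equal(nrow(w_fam), 0)
})

test_that("criterion 3 requires direct edges to both co-complexed partners", {
  t <- toy_instance()
  w <- criterion3_witnesses("S", t$net, t$catalog)
  expect_equal(nrow(w), 1)
  expect_equal(w$complex_id, "X")

  # complex membership without the S-B edge is not enough
  net2 <- build_interactome(rbind(c("S", "A"), c("S", "C")))
  expect_equal(nrow(criterion3_witnesses("S", net2, t$catalog)), 0)

  # complex of four with all edges: C(3,2) pairs
  net3 <- build_interactome(cbind("S", c("A", "B", "C")))
  cat3 <- complex_catalog(list(X = c("S", "A", "B", "C")))
  expect_equal(nrow(criterion3_witnesses("S", net3, cat3)), 3)

  # smallest qualifying complex id is recorded
  cat4 <- complex_catalog(list(ZZ = c("S", "A", "B"), AA = c("S", "A", "B")))
  expect_equal(criterion3_witnesses("S", t$net, cat4)$complex_id, "AA")
})

test_that("classification follows the witness-policy contract", {
  c2 <- data.frame(p1 = "A", p2 = "B", region1 = "D1.1", region2 = "D2.1",
                   stringsAsFactors = FALSE)
  c3 <- data.frame(p1 = "A", p2 = "B", complex_id = "X",
                   stringsAsFactors = FALSE)
  none2 <- c2[0, ]; none3 <- c3[0, ]

  cls <- classify_scaffold("S", c2, c3)
  expect_equal(cls$type_class, "I")
  expect_equal(cls$witnesses$complex_id, "X")
  expect_equal(cls$witnesses$region1, "D1.1")

  expect_equal(classify_scaffold("S", c2, none3)$type_class, "II")
  expect_equal(classify_scaffold("S", none2, c3)$type_class, "III")
  expect_null(classify_scaffold("S", none2, none3))

  # disjoint pairs: joint policy says II, independent policy says I
  c3b <- data.frame(p1 = "C", p2 = "D", complex_id = "Y",
                    stringsAsFactors = FALSE)
  expect_equal(classify_scaffold("S", c2, c3b)$type_class, "II")
  ind <- predictor_config(joint_witness = FALSE)
  cls_ind <- classify_scaffold("S", c2, c3b, ind)
  expect_equal(cls_ind$type_class, "I")
  expect_equal(nrow(cls_ind$witnesses), 2)
})

test_that("predict_scaffolds finds the planted scaffold and rejects the hub", {
  t <- toy_instance()
  pred <- predict_scaffolds(t$net, t$arch, t$ddi, t$catalog)
  expect_equal(scaffolds_of_type(pred), "S")
  expect_equal(unname(prediction_counts(pred)), c(1L, 0L, 0L))

  # no DDI evidence and no complexes: nothing is called
  pred0 <- predict_scaffolds(t$net, t$arch, ddi_network(rbind(c("ZA", "ZB"))),
                             complex_catalog(list(E = "ZZ")))
  expect_equal(nrow(pred0), 0)
  expect_equal(sum(prediction_counts(pred0)), 0)
})

test_that("predictor matches the brute-force oracle on random instances", {
  for (seed in 1:25) {
    inst <- random_instance(seed)
    for (joint in c(TRUE, FALSE)) for (sem in c("instance", "family")) {
      pred <- package_predict_instance(inst, joint = joint, semantics = sem)
      ora <- oracle_classify_all(inst$edges, inst$arch, inst$ddi,
                                 inst$complexes, joint = joint,
                                 semantics = sem)
      expect_identical(prediction_types(pred),
                       ora$types[order(names(ora$types))],
                       info = sprintf("seed %d joint=%s sem=%s",
                                      seed, joint, sem))
    }
  }
})

test_that("witness pair sets match the oracle's criterion-2 and criterion-3 pairs", {
  for (seed in 26:35) {
    inst <- random_instance(seed)
    net <- build_interactome(inst$edges)
    arch <- domain_architectures(inst$arch)
    ddi <- ddi_network(inst$ddi)
    catalog <- if (length(inst$complexes)) complex_catalog(inst$complexes)
      else complex_catalog(list(E = "ZZ_NONE"))
    ora <- oracle_classify_all(inst$edges, inst$arch, inst$ddi,
                               inst$complexes)
    for (s in criterion1(net)) {
      c2 <- criterion2_witnesses(s, net, arch, ddi)
      c3 <- criterion3_witnesses(s, net, catalog)
      expect_equal(sort(paste(c2$p1, c2$p2)), ora$c2[[s]] %||% character(0))
      expect_equal(sort(paste(c3$p1, c3$p2)), ora$c3[[s]] %||% character(0))
    }
  }
})

test_that("adding a DDI pair or a complex never demotes a candidate", {
  rank <- c(none = 0, III = 1, II = 1, I = 2)
  for (seed in 1:8) {
    inst <- random_instance(seed, n_max = 15)
    base <- prediction_types(package_predict_instance(inst))
    # enrich the evidence
    inst2 <- inst
    inst2$ddi <- rbind(inst$ddi, c("F01", "F03"), c("F02", "F05"))
    inst2$complexes <- c(inst$complexes,
                         list(EXTRA = sort(unique(c(inst$edges[1, ],
                                                    inst$edges[nrow(inst$edges), ])))))
    after <- prediction_types(package_predict_instance(inst2))
    for (s in names(base)) {
      # called candidates never drop out, and I=2 > II=III=1 never decreases
      expect_true(s %in% names(after))
      expect_gte(rank[[after[[s]]]], rank[[base[[s]]]])
      if (base[[s]] == "I") expect_equal(after[[s]], "I")
      if (base[[s]] == "II") expect_true(after[[s]] %in% c("I", "II"))
    }
  }
})

test_that("a single-domain protein can never be Type I or II", {
  for (seed in 1:10) {
    inst <- random_instance(seed)
    single <- names(which(table(inst$arch$protein) == 1))
    for (sem in c("instance", "family")) {
      types <- prediction_types(package_predict_instance(inst, semantics = sem))
      expect_false(any(types[names(types) %in% single] %in% c("I", "II")))
    }
  }
})

test_that("type classes partition the called candidates", {
  for (seed in 11:16) {
    inst <- random_instance(seed)
    pred <- package_predict_instance(inst)
    df <- unique(as.data.frame(pred)[, c("scaffold", "type_class")])
    expect_equal(anyDuplicated(df$scaffold), 0)
    # under the independent policy, Type II candidates have no c3 witness
    pred_ind <- package_predict_instance(inst, joint = FALSE)
    ora <- oracle_classify_all(inst$edges, inst$arch, inst$ddi,
                               inst$complexes, joint = FALSE)
    t2 <- names(ora$types)[ora$types == "II"]
    expect_true(all(vapply(t2, function(s) length(ora$c3[[s]]) == 0,
                           logical(1))))
  }
})
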