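test_that("the whole synthetic bundle is a pure function of the config", {
  cfg <- synthetic_config(seed = 7, preset = "toy")
  b1 <- suppressMessages(generate_bundle(cfg))
  b2 <- suppressMessages(generate_bundle(cfg))
  expect_identical(network_edges(b1$network), network_edges(b2$network))
  expect_identical(b1$panel$fingerprint, b2$panel$fingerprint)
  expect_identical(b1$panel$targets, b2$panel$targets)
  expect_identical(b1$catalogue$fingerprint, b2$catalogue$fingerprint)
  expect_identical(b1$known_targets, b2$known_targets)
  expect_identical(b1$gene_sets, b2$gene_sets)
  expect_identical(b1$truth, b2$truth)
})

test_that("per-stage substreams keep upstream outputs stable", {
  cfg_a <- synthetic_config(seed = 3, preset = "toy", n_gene_sets = 5)
  cfg_b <- synthetic_config(seed = 3, preset = "toy", n_gene_sets = 9)
  a <- suppressMessages(generate_bundle(cfg_a))
  b <- suppressMessages(generate_bundle(cfg_b))
  expect_identical(network_edges(a$network), network_edges(b$network))
  expect_identical(a$panel$fingerprint, b$panel$fingerprint)
  expect_identical(a$catalogue$fingerprint, b$catalogue$fingerprint)
  expect_identical(a$known_targets$members, b$known_targets$members)
})

test_that("generated networks are simple, connected and sized as configured", {
  for (model in c("scale-free", "block-model")) {
    cfg <- synthetic_config(seed = 11, n_proteins = 80, ppi_model = model)
    g <- generate_ppi(cfg)
    expect_equal(igraph::vcount(g), 80)
    expect_false(any(igraph::which_loop(g)))
    expect_false(any(igraph::which_multiple(g)))
    expect_equal(igraph::components(g)$no, 1)
  }
  expect_error(synthetic_config(seed = 1, pa_edges = 0), "attachment")
})

test_that("scale-free degree distributions are right-skewed", {
  cfg <- synthetic_config(seed = 5, n_proteins = 500, ppi_model = "scale-free")
  deg <- igraph::degree(generate_ppi(cfg))
  expect_gt(max(deg), 3 * stats::median(deg))
})

test_that("planted drug modules are network-localized", {
  cfg <- synthetic_config(seed = 2, n_proteins = 150, target_module_size = 5,
                          n_panel_drugs = 10)
  g <- generate_ppi(cfg)
  pn <- generate_panel(cfg, g)
  for (i in seq_len(nrow(pn$panel))) {
    tg <- pn$panel$targets[[i]]
    d <- igraph::distances(g, v = tg, to = tg, weights = NA)
    expect_lte(max(d), cfg$module_radius)
    expect_true(all(tg %in% pn$truth$modules[[pn$panel$drug_id[i]]]))
  }
  pn2 <- generate_panel(cfg, g)
  expect_identical(pn$panel$targets, pn2$panel$targets)

  cfg1 <- synthetic_config(seed = 2, n_proteins = 150, targets_per_drug = 1,
                           n_panel_drugs = 5)
  single <- generate_panel(cfg1, g)
  expect_true(all(lengths(single$panel$targets) == 1))

  expect_error(synthetic_config(seed = 1, n_proteins = 10,
                                n_disease_targets = 5,
                                target_module_size = 40),
               "target_module_size")
})

test_that("compound fingerprints are bit-flipped parent copies", {
  g_cfg <- synthetic_config(seed = 4, n_proteins = 100, n_herbs = 1,
                            compounds_per_herb = 200,
                            fingerprint_length = 128, bit_flip_rate = 0)
  g <- generate_ppi(g_cfg)
  pn <- generate_panel(g_cfg, g)

  hb0 <- generate_herbs(g_cfg, pn$panel)
  for (i in seq_len(5)) {
    parent <- hb0$truth$parents[[hb0$catalogue$compound_id[i]]]
    pfp <- pn$panel$fingerprint[[match(parent, pn$panel$drug_id)]]
    expect_identical(hb0$catalogue$fingerprint[[i]], pfp)
    expect_equal(tanimoto(hb0$catalogue$fingerprint[[i]], pfp), 1)
  }

  cfg1 <- synthetic_config(seed = 4, n_proteins = 100, n_herbs = 1,
                           compounds_per_herb = 5, fingerprint_length = 128,
                           bit_flip_rate = 1)
  hb1 <- generate_herbs(cfg1, pn$panel)
  for (i in seq_len(5)) {
    parent <- hb1$truth$parents[[hb1$catalogue$compound_id[i]]]
    pfp <- pn$panel$fingerprint[[match(parent, pn$panel$drug_id)]]
    expect_identical(hb1$catalogue$fingerprint[[i]],
                     setdiff(0:127, pfp))
  }

  ## binomial oracle: mean Hamming distance over 200 compounds within 3 sigma
  rate <- 0.05
  cfg <- synthetic_config(seed = 4, n_proteins = 100, n_herbs = 1,
                          compounds_per_herb = 200, fingerprint_length = 128,
                          bit_flip_rate = rate)
  hb <- generate_herbs(cfg, pn$panel)
  hamming <- vapply(seq_len(200), function(i) {
    parent <- hb$truth$parents[[hb$catalogue$compound_id[i]]]
    pfp <- pn$panel$fingerprint[[match(parent, pn$panel$drug_id)]]
    fp <- hb$catalogue$fingerprint[[i]]
    length(setdiff(fp, pfp)) + length(setdiff(pfp, fp))
  }, numeric(1))
  expected <- 128 * rate
  sigma <- sqrt(128 * rate * (1 - rate)) / sqrt(200)
  expect_lt(abs(mean(hamming) - expected), 3 * sigma)
})

test_that("disease targets respect the module-overlap fraction", {
  cfg <- synthetic_config(seed = 9, n_proteins = 150, n_panel_drugs = 15,
                          target_module_size = 5, n_disease_targets = 12,
                          disease_module_overlap = 1)
  g <- generate_ppi(cfg)
  pn <- generate_panel(cfg, g)
  kt <- generate_disease_targets(cfg, g, pn$truth)
  target_union <- unique(unlist(pn$truth$drug_targets))
  module_union <- unique(unlist(pn$truth$modules))
  expect_true(all(kt$members %in% target_union))
  expect_true(all(kt$members %in% module_union))
  expect_equal(length(kt$members), 12)

  cfg0 <- synthetic_config(seed = 9, n_proteins = 150, n_panel_drugs = 15,
                           target_module_size = 5, n_disease_targets = 12,
                           disease_module_overlap = 0)
  kt0 <- generate_disease_targets(cfg0, g, pn$truth)
  expect_equal(unname(kt0$per_source[["planted"]]), 0)
  expect_equal(length(kt0$members), 12)

  cfg_bad <- synthetic_config(seed = 9, n_proteins = 150, n_panel_drugs = 2,
                              targets_per_drug = 2, target_module_size = 3,
                              n_disease_targets = 100,
                              disease_module_overlap = 1)
  g2 <- generate_ppi(cfg_bad)
  pn2 <- generate_panel(cfg_bad, g2)
  expect_error(generate_disease_targets(cfg_bad, g2, pn2$truth),
               "infeasible")
})

test_that("gene-set collections carry the planted positive control", {
  b <- suppressMessages(generate_bundle(synthetic_config(seed = 21, preset = "toy")))
  expect_true("PLANTED_DISEASE" %in% names(b$gene_sets$sets))
  expect_identical(b$gene_sets$sets$PLANTED_DISEASE$members,
                   sort(b$truth$disease_module))
  expect_equal(length(b$gene_sets$sets), 10)
  sizes <- lengths(lapply(b$gene_sets$sets[-1], `[[`, "members"))
  expect_true(all(sizes >= 5 & sizes <= 15))
})

test_that("paper-scale preset mirrors the published study dimensions", {
  cfg <- synthetic_config(seed = 1, preset = "paper_scale")
  expect_equal(cfg$n_proteins, 1746L)
  expect_equal(cfg$n_herbs, 5L)
  expect_equal(cfg$compounds_per_herb, c(22L, 122L, 39L, 65L, 203L))
  expect_equal(sum(cfg$compounds_per_herb), 451L)
  expect_equal(cfg$n_disease_targets, 208L)
})
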