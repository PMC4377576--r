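test_that("Tanimoto similarity follows the set definition", {
  expect_equal(tanimoto(c(1, 5, 9), c(1, 5, 9)), 1)
  expect_equal(tanimoto(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(tanimoto(c(1, 2), c(7, 8)), 0)
  expect_warning(z <- tanimoto(integer(0), integer(0)), "empty")
  expect_equal(z, 0)
})

test_that("chemical similarity vectors stay aligned to the panel order", {
  panel <- drug_panel(c("D1", "D2", "D3"),
                      fingerprints = list(c(0, 1), c(2, 3), c(0, 3)),
                      targets = list("A", "B", "C"),
                      fingerprint_length = 8)
  v <- chem_similarity_vector(c(0, 1), panel)
  expect_equal(unname(v["D1"]), 1)
  expect_equal(names(v), c("D1", "D2", "D3"))

  perm <- panel[c(3, 1, 2), ]
  attr(perm, "fingerprint_length") <- 8
  class(perm) <- class(panel)
  vp <- chem_similarity_vector(c(0, 1), perm)
  expect_equal(vp[names(v)], v)

  one <- drug_panel("D9", list(c(0, 1)), list("A"), fingerprint_length = 8)
  expect_length(chem_similarity_vector(c(0, 1), one), 1)
  expect_error(chem_similarity_vector(c(0, 1), one[0, ]), "empty")
})

test_that("network proximity follows the gaussian-of-distance kernel", {
  toy <- toy_prediction_case()
  net <- toy$network
  ker <- gaussian_kernel()
  d1 <- list(targets = list("A"))
  expect_equal(proximity("A", d1, net, ker), 1)
  expect_equal(proximity("B", d1, net, ker), exp(-1))
  expect_equal(proximity("C", d1, net, ker), exp(-4))

  two_comp <- interaction_network(data.frame(from = c("A", "X"),
                                             to = c("B", "Y")))
  expect_equal(proximity("X", list(targets = list("A")), two_comp, ker), 0)
  expect_error(proximity("ZZ", d1, net, ker), "not in network")
  expect_message(proximity("A", list(targets = list(c("A", "NOPE"))), net, ker),
                 "absent")
})

test_that("functional similarity vectors align with the panel and stay non-negative", {
  toy <- toy_prediction_case()
  v <- functional_similarity_vector("A", toy$panel, toy$network)
  expect_equal(names(v), c("D1", "D2"))
  expect_equal(unname(v["D1"]), 1)
  expect_true(all(v >= 0))

  far <- interaction_network(data.frame(from = c("A", "X"), to = c("B", "Y")))
  pan <- drug_panel(c("D1", "D2"), list(c(0), c(1)),
                    targets = list("X", "Y"), fingerprint_length = 4)
  vv <- functional_similarity_vector("A", pan, far)
  expect_equal(unname(vv), c(0, 0))
})

test_that("concordance scores are Pearson correlations with undefined flagging", {
  expect_equal(concordance_score(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(concordance_score(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_true(is.na(concordance_score(c(1, 1, 1), c(1, 5, 9))))
  expect_error(concordance_score(1, 2), "panel")
  expect_error(concordance_score(c(1, 2), c(1, 2, 3)), "differ")
})

test_that("the worked 4-node example ranks exactly as hand-computed", {
  toy <- toy_prediction_case()
  rk <- rank_targets(list(compound_id = "Q", fingerprint = toy$query),
                     toy$panel, toy$network)
  expect_equal(rk$protein, c("A", "B", "C", "D"))
  expect_equal(rk$score, c(1, 1, -1, -1), tolerance = 1e-12)
  expect_equal(rk$rank, 1:4)

  ## panel order must not matter
  perm <- toy$panel[c(2, 1), ]
  attr(perm, "fingerprint_length") <- 16
  class(perm) <- class(toy$panel)
  rk2 <- rank_targets(list(compound_id = "Q", fingerprint = toy$query),
                      perm, toy$network)
  expect_equal(rk2$score, rk$score)
  expect_equal(rk2$protein, rk$protein)
})

test_that("any strictly decreasing kernel preserves the toy ranking", {
  toy <- toy_prediction_case()
  kernels <- list(gaussian_kernel(),
                  gaussian_kernel(function(d) exp(-d), "exponential"),
                  gaussian_kernel(function(d) ifelse(is.infinite(d), 0,
                                                     1 / (1 + d)),
                                  "inverse-distance"))
  for (ker in kernels) {
    rk <- rank_targets(list(compound_id = "Q", fingerprint = toy$query),
                       toy$panel, toy$network, ker)
    expect_equal(rk$protein, c("A", "B", "C", "D"))
  }
  expect_error(gaussian_kernel(function(d) rep(1, length(d))), "decreasing")
  expect_error(gaussian_kernel(function(d) 0.5 * exp(-d) + 0.5), "vanish")
})

test_that("rankings match the brute-force oracle on random small instances", {
  for (case in 1:30) {
    set.seed(4000 + case)
    n <- sample(3:8, 1)
    adj <- rand_adj(n, 0.45, 4000 + case)
    nodes <- rownames(adj)
    g <- adj_to_graph(adj)
    n_drugs <- sample(2:3, 1)
    fps <- lapply(seq_len(n_drugs), function(i) sort(sample(0:15, sample(2:6, 1))))
    tgs <- lapply(seq_len(n_drugs), function(i)
      sample(nodes, sample(1:2, 1)))
    panel <- drug_panel(paste0("D", seq_len(n_drugs)), fps, tgs,
                        fingerprint_length = 16)
    query <- sort(sample(0:15, 4))
    got <- rank_targets(list(compound_id = "q", fingerprint = query), panel, g)
    want <- bf_rank_targets(query, panel$fingerprint, panel$targets, adj)
    expect_equal(got$protein, want$protein)
    defined <- !is.na(want$score)
    expect_equal(got$score[defined], want$score[defined], tolerance = 1e-9)
    expect_equal(is.na(got$score), is.na(want$score))
    expect_true(all(abs(got$score[defined]) <= 1 + 1e-12))
  }
})

test_that("undefined scores rank last instead of aborting", {
  ## a protein isolated from every target gets a constant (all-zero)
  ## functional vector
  net <- interaction_network(data.frame(from = c("A", "X"), to = c("B", "Y")))
  panel <- drug_panel(c("D1", "D2"), list(c(0, 1), c(2, 3)),
                      targets = list("A", "B"), fingerprint_length = 8)
  rk <- rank_targets(list(compound_id = "q", fingerprint = c(0, 1)),
                     panel, net)
  expect_true(all(is.na(rk$score[rk$protein %in% c("X", "Y")])))
  expect_true(all(rk$rank[rk$protein %in% c("X", "Y")] >= 3))
  expect_equal(rk$rank, 1:4)
})

test_that("herb profiles aggregate compound scores by maximum", {
  scores <- matrix(c(0.2, 0.9,
                     0.8, 0.1,
                     NA, 0.5),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("P1", "P2", "P3"), c("c1", "c2")))
  pred <- structure(list(scores = scores,
                         compounds = data.frame(compound_id = c("c1", "c2"),
                                                herb = c("H", "H"))),
                    class = "target_predictions")
  prof <- herb_profile(pred, "H", k = 2)
  expect_equal(prof$protein, c("P1", "P2"))
  expect_equal(prof$score, c(0.9, 0.8))

  all3 <- herb_profile(pred, "H", k = 10)
  expect_equal(nrow(all3), 3)
  expect_equal(all3$score[3], 0.5)

  expect_error(herb_profile(pred, "nope"), "no compounds")

  one <- structure(list(scores = scores[, 1, drop = FALSE],
                        compounds = data.frame(compound_id = "c1", herb = "H")),
                   class = "target_predictions")
  prof1 <- herb_profile(one, "H", k = 2)
  expect_equal(prof1$protein, c("P2", "P1"))
})

test_that("profile overlaps and drug-target overlap reports count correctly", {
  pa <- structure(data.frame(protein = c("G1", "G2"), score = c(1, 0.5)),
                  class = c("herb_profile", "data.frame"))
  pb <- structure(data.frame(protein = c("G2", "G3"), score = c(1, 0.5)),
                  class = c("herb_profile", "data.frame"))
  m <- profile_overlap_matrix(list(A = pa, B = pb))
  expect_equal(m["A", "B"], 1L)
  expect_equal(diag(m), c(A = 2L, B = 2L))
  expect_equal(common_targets(list(A = pa, B = pb)), "G2")

  same <- replicate(3, structure(
    data.frame(protein = sprintf("G%03d", 1:100), score = 1),
    class = c("herb_profile", "data.frame")), simplify = FALSE)
  names(same) <- c("X", "Y", "Z")
  expect_true(all(profile_overlap_matrix(same) == 100))

  ## the published arithmetic: 101 shared of 1746 putative is 5.78%
  putative <- sprintf("G%04d", 1:1746)
  known <- c(sprintf("G%04d", 1:101), sprintf("K%03d", 1:107))
  ov <- overlap_with_drug_targets(putative, known)
  expect_equal(ov$n_shared, 101)
  expect_equal(ov$percentage, 5.78)
})

test_that("compounds recover their planted parent targets", {
  cfg <- synthetic_config(seed = 31, n_proteins = 200, n_herbs = 2,
                          compounds_per_herb = 15, bit_flip_rate = 0.05)
  b <- suppressMessages(generate_bundle(cfg))
  pred <- suppressMessages(predict_targets(b$catalogue, b$panel, b$network))
  set.seed(123)
  nodes <- rownames(pred$scores)
  wins <- 0
  for (i in seq_len(ncol(pred$scores))) {
    rk <- compound_ranking(pred, colnames(pred$scores)[i])
    ranks <- stats::setNames(rk$rank, rk$protein)
    tg <- b$truth$drug_targets[[b$truth$parents[[colnames(pred$scores)[i]]]]]
    rnd <- sample(nodes, length(tg))
    if (mean(ranks[tg]) < mean(ranks[rnd])) wins <- wins + 1
  }
  expect_gte(wins / ncol(pred$scores), 0.8)
})
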