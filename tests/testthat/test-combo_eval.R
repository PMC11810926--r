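# small helper: simulated single-cancer matrix with chosen effects
sim_feature_world <- function(effects, n = 60, seed = 1, base_mean = 0.3,
                              cancer = "c1") {
  pl <- data.frame(gene = names(effects), cancer = cancer,
                   effect = unname(effects), base_mean = base_mean,
                   stringsAsFactors = FALSE)
  spec <- sim_spec(cancers = cancer, n_tumor = n, n_normal = n,
                   planted = pl, n_null_genes = 0, probes_per_gene = 1,
                   outlier_rate = 0, seed = seed)
  simulate_beta_matrix(spec, cancer)
}

test_that("enumerate_panels is the Cartesian product over groups", {
  g521 <- list(a = paste0("A", 1:5), b = paste0("B", 1:2), c = "C1")
  expect_length(enumerate_panels(g521), 10)
  expect_length(enumerate_panels(list(a = "A", b = "B")), 1)
  p22 <- enumerate_panels(list(a = c("A1", "A2"), b = c("B1", "B2")))
  expect_length(p22, 4)
  expect_true(all(vapply(p22, length, 0L) == 2))
})

test_that("extract_features picks training-probe, imputes, guards leakage", {
  v <- rbind(cg1 = c(0.70, 0.80, 0.20, 0.30, NA, 0.25),
             cg2 = c(0.55, 0.50, 0.45, 0.50, 0.60, 0.50))
  colnames(v) <- paste0("s", 1:6)
  groups <- stats::setNames(c("tumor", "tumor", "normal", "normal",
                              "tumor", "normal"), colnames(v))
  bm <- beta_matrix(v, groups)
  mf <- probe_manifest(data.frame(probe = c("cg1", "cg2"), gene = "GX",
                                  region = "promoter",
                                  stringsAsFactors = FALSE))
  train <- paste0("s", 1:4)
  ft <- extract_features(bm, mf, "GX", train_samples = train)
  # on training data cg1 has |dbeta| 0.5 vs cg2 0.05 -> cg1 chosen
  expect_equal(unname(ft$probes["GX"]), "cg1")
  expect_equal(unname(ft$x["s1", "GX"]), 0.70)
  # identical column definition reused on held-out subjects (no re-selection)
  expect_equal(unname(ft$x["s6", "GX"]), 0.25)
  # the held-out NA is imputed with the training median of the chosen probe
  expect_equal(unname(ft$x["s5", "GX"]),
               stats::median(v["cg1", train]))

  # gene-mean mode averages a gene's probes
  ft2 <- extract_features(bm, mf, "GX", train_samples = train,
                          feature_mode = "gene_mean")
  expect_equal(unname(ft2$x["s1", "GX"]), mean(c(0.70, 0.55)))

  expect_error(extract_features(bm, mf, "MISSING", train), "MISSING")
})

test_that("metrics match a hand-computed confusion matrix", {
  truth <- c(rep("tumor", 6), rep("normal", 4))
  pred <- c("tumor", "tumor", "tumor", "tumor", "normal", "normal",
            "normal", "normal", "normal", "tumor")
  # by hand: TP = 4, FN = 2, TN = 3, FP = 1
  met <- classification_metrics(truth, pred)
  expect_equal(met$tp, 4); expect_equal(met$fn, 2)
  expect_equal(met$tn, 3); expect_equal(met$fp, 1)
  expect_equal(met$accuracy, 7 / 10)
  expect_equal(met$recall, 4 / 6)
  expect_equal(met$precision, 4 / 5)
  expect_equal(met$f_score, 2 * (4 / 5) * (4 / 6) / ((4 / 5) + (4 / 6)))
  expect_true(is.na(met$flag))

  # tumor-only test set: recall equals accuracy, report flagged
  met2 <- classification_metrics(rep("tumor", 5),
                                 c(rep("tumor", 4), "normal"))
  expect_equal(met2$recall, met2$accuracy)
  expect_equal(met2$flag, "no_negatives_in_test")
})

test_that("well-separated features classify nearly perfectly; shuffled labels do not", {
  sim <- sim_feature_world(c(GX = 0.5, GY = 0.5), n = 100, seed = 9,
                           base_mean = 0.2)
  cfg <- meth_config(seed = 9)
  rep1 <- train_eval(sim$beta, sim$manifest, c("GX", "GY"), cfg, "c1")
  expect_gte(rep1$accuracy, 0.95)

  # identical seed => bit-identical report
  rep2 <- train_eval(sim$beta, sim$manifest, c("GX", "GY"), cfg, "c1")
  expect_identical(rep1, rep2)

  # label shuffle: accuracy near chance
  set.seed(10)
  shuffled <- sim$beta
  shuffled$groups <- stats::setNames(sample(shuffled$groups),
                                     names(shuffled$groups))
  if (!all(c("tumor", "normal") %in% shuffled$groups)) skip("degenerate shuffle")
  acc <- train_eval(shuffled, sim$manifest, c("GX", "GY"), cfg, "c1")$accuracy
  expect_lt(acc, 0.75)
})

test_that("select_optimal takes argmax with size and lexicographic ties", {
  mk <- function(panel, acc) list(panel = panel, mean_accuracy = acc)
  reports <- list(mk(c("A", "B"), 0.93), mk(c("C"), 0.88), mk(c("D"), 0.90))
  expect_equal(select_optimal(reports)$panel, c("A", "B"))
  # tie on accuracy: fewer genes wins
  reports2 <- list(mk(c("A", "B", "C"), 0.9), mk(c("D", "E"), 0.9))
  expect_equal(select_optimal(reports2)$panel, c("D", "E"))
  # full tie: lexicographic
  reports3 <- list(mk(c("Z", "B", "C"), 0.9), mk(c("A", "B", "C"), 0.9))
  expect_equal(select_optimal(reports3)$panel, c("A", "B", "C"))
})

test_that("universal model transfers to an unseen cancer and checks inputs", {
  panel <- c("GX", "GY")
  tabs <- lapply(1:3, function(i) {
    sim <- sim_feature_world(c(GX = 0.35, GY = 0.35), n = 60, seed = 20 + i,
                             cancer = paste0("train", i))
    extract_features(sim$beta, sim$manifest, panel,
                     cancer = paste0("train", i))
  })
  names(tabs) <- paste0("train", 1:3)
  unseen <- sim_feature_world(c(GX = 0.35, GY = 0.35), n = 60, seed = 30,
                              cancer = "unseen")
  unseen_tab <- extract_features(unseen$beta, unseen$manifest, panel,
                                 cancer = "unseen")
  out <- universal_model(tabs, list(unseen = unseen_tab), meth_config())
  expect_gte(out$unseen$accuracy, 0.9)

  # inverted effect: the model should do no better than chance
  inv <- sim_feature_world(c(GX = -0.25, GY = -0.25), n = 60, seed = 31,
                           base_mean = 0.55, cancer = "inv")
  inv_tab <- extract_features(inv$beta, inv$manifest, panel, cancer = "inv")
  out_inv <- universal_model(tabs, list(inv = inv_tab), meth_config())
  expect_lte(out_inv$inv$accuracy, 0.5)

  # empty test table and mismatched panels are errors
  empty <- unseen_tab
  empty$x <- empty$x[0, , drop = FALSE]; empty$y <- character()
  expect_error(universal_model(tabs, list(empty = empty)), "empty")
  wrong <- unseen_tab
  colnames(wrong$x) <- c("GX", "OTHER")
  expect_error(universal_model(tabs, list(wrong = wrong)), "mismatch")
})
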