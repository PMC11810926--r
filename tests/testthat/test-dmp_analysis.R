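test_that("iqr_filter matches hand-computed Tukey fences and edge cases", {
  # zero IQR: fences collapse to the point, identical values retained
  expect_equal(as.numeric(iqr_filter(rep(0.1, 4))), rep(0.1, 4))

  # hand-derived: Q1 = 0.42, Q3 = 0.46 (type-7), fences [0.36, 0.52]
  x <- c(0.40, 0.42, 0.44, 0.46, 0.99)
  expect_equal(as.numeric(iqr_filter(x, 1.5)), x[1:4])

  # k -> Inf is the identity, including when IQR = 0
  expect_equal(as.numeric(iqr_filter(x, Inf)), x)
  expect_equal(as.numeric(iqr_filter(c(0.3, 0.3, 0.3, 0.3, 0.9), Inf)),
               c(0.3, 0.3, 0.3, 0.3, 0.9))

  # degenerate input passes through flagged
  short <- iqr_filter(c(0.1, 0.9))
  expect_false(attr(short, "filtered"))
  expect_equal(as.numeric(short), c(0.1, 0.9))
})

test_that("iqr_filter is idempotent on separated data and preserves order", {
  # bounded inliers + extreme outliers: the first pass removes exactly the
  # outliers and the recomputed fences still cover the inlier range, so a
  # second pass is a no-op (idempotence needs inliers separated from
  # outliers; heavy-tailed data can re-tighten)
  set.seed(7)
  for (rep in 1:20) {
    x <- c(seq(0.4, 0.6, length.out = 26), runif(4, 0.97, 1))[sample(30)]
    once <- as.numeric(iqr_filter(x))
    twice <- as.numeric(iqr_filter(once))
    expect_identical(twice, once)
    expect_identical(once, x[x %in% once])  # order preserved
  }
})

test_that("bh_adjust matches hand-applied step-up and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("bh_adjust equals the independent step-up oracle on random vectors", {
  set.seed(11)
  for (rep in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
})

test_that("probe_stats computes exact delta-beta and flat nulls", {
  v <- rbind(p1 = c(0.9, 0.9, 0.9, 0.9, 0.1, 0.1, 0.1, 0.1),
             p2 = rep(c(0.3, 0.5, 0.3, 0.5), 2))
  colnames(v) <- c(paste0("t", 1:4), paste0("n", 1:4))
  groups <- stats::setNames(rep(c("tumor", "normal"), each = 4), colnames(v))
  bm <- beta_matrix(v, groups)
  mf <- probe_manifest(data.frame(probe = c("p1", "p2"),
                                  gene = c("GA", "GB"), region = "promoter",
                                  stringsAsFactors = FALSE))
  rec <- probe_stats(bm, mf, meth_config())
  expect_equal(rec$delta_beta[rec$probe == "p1"], 0.8)
  expect_equal(rec$delta_beta[rec$probe == "p2"], 0)
  expect_equal(rec$p_value[rec$probe == "p2"], 1)
  expect_true(all(rec$q_value >= rec$p_value))
})

test_that("delta-beta antisymmetry: swapping labels negates effects", {
  spec <- sim_spec(cancers = "c1", n_null_genes = 20, seed = 3)
  sim <- simulate_beta_matrix(spec, "c1")
  cfg <- meth_config()
  rec <- probe_stats(sim$beta, sim$manifest, cfg)
  flipped <- sim$beta
  flipped$groups <- stats::setNames(
    ifelse(flipped$groups == "tumor", "normal", "tumor"),
    names(flipped$groups))
  rec2 <- probe_stats(flipped, sim$manifest, cfg)
  expect_equal(rec2$delta_beta, -rec$delta_beta)
  expect_equal(rec2$p_value, rec$p_value)
})

test_that("null probes show ~5% raw p < 0.05", {
  pl <- data.frame(gene = "PLT1", cancer = "c1", effect = 0)
  spec <- sim_spec(cancers = "c1", planted = pl, n_null_genes = 100,
                   probes_per_gene = 2, outlier_rate = 0, seed = 19)
  sim <- simulate_beta_matrix(spec, "c1")
  # filtering off: trimming tails makes Welch slightly anticonservative,
  # so the clean type-I property belongs to the unfiltered test
  rec <- probe_stats(sim$beta, sim$manifest, meth_config(iqr_k = Inf))
  frac <- mean(rec$p_value < 0.05)
  expect_gt(frac, 0.01)   # binomial band around 0.05 at 202 probes
  expect_lt(frac, 0.10)
  # with Tukey filtering the rate stays in the same ballpark
  rec_f <- probe_stats(sim$beta, sim$manifest, meth_config())
  expect_lt(mean(rec_f$p_value < 0.05), 0.15)
})

test_that("classify_volcano applies thresholds and promoter precedence", {
  cfg <- meth_config()
  expect_equal(classify_volcano(0.5, 1e-5, "other", cfg), "hyper")
  expect_equal(classify_volcano(-0.5, 1e-5, "other", cfg), "hypo")
  expect_equal(classify_volcano(-0.5, 1e-5, "promoter", cfg), "promoter")
  expect_equal(classify_volcano(0.1, 1e-5, "promoter", cfg), "other")
  expect_equal(classify_volcano(0.5, 0.5, "promoter", cfg), "other")
})

test_that("primary-marker rule: strict threshold, best probe, regions", {
  rec <- data.frame(
    probe = c("p1", "p2", "p3", "p4"),
    gene = c("GA", "GA", "GB", "GC"),
    region = c("promoter", "promoter", "promoter", "other"),
    delta_beta = c(0.40, 0.10, 0.34, 0.50),
    p_value = rep(1e-4, 4),
    q_value = c(0.001, 0.001, 0.001, 0.001),
    n_tumor_used = 10, n_normal_used = 10,
    volcano_class = "promoter",
    stringsAsFactors = FALSE)
  cfg <- meth_config()
  pm <- call_primary_markers(rec, cfg, "c1")
  expect_equal(pm$gene, "GA")               # GB at 0.34 < 0.35; GC non-promoter
  expect_equal(pm$delta_beta, 0.40)
  expect_equal(pm$status, "hyper")

  # boundary: exactly at the threshold is excluded (strict >)
  rec$delta_beta[1] <- 0.35
  expect_equal(nrow(call_primary_markers(rec, cfg)), 0)

  # promoter_only off admits GC
  pm2 <- call_primary_markers(rec, meth_config(promoter_only = FALSE))
  expect_true("GC" %in% pm2$gene)
})

test_that("lowering the delta-beta threshold never shrinks the marker set", {
  spec <- sim_spec(cancers = "c1", seed = 23)
  sim <- simulate_beta_matrix(spec, "c1")
  rec <- probe_stats(sim$beta, sim$manifest, meth_config())
  prev <- character()
  for (thr in c(0.45, 0.35, 0.25, 0.15)) {
    pm <- call_primary_markers(rec, meth_config(dmp_abs_dbeta_threshold = thr))
    expect_true(all(prev %in% pm$gene))
    prev <- pm$gene
  }
})

test_that("outlier filtering flips a threshold-straddling probe", {
  bm <- make_outlier_flip_matrix()
  mf <- make_flip_manifest()
  with_filter <- probe_stats(bm, mf, meth_config(iqr_k = 1.5))
  without_filter <- probe_stats(bm, mf, meth_config(iqr_k = Inf))
  db_with <- with_filter$delta_beta[with_filter$probe == "flip"]
  db_without <- without_filter$delta_beta[without_filter$probe == "flip"]
  expect_lt(db_without, 0.35)
  expect_gt(db_with, 0.35)
  expect_true("MARK1" %in% call_primary_markers(with_filter)$gene)
  expect_false("MARK1" %in% call_primary_markers(without_filter)$gene)
})
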