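test_that("decay families evaluate correctly, including unreachable reactions", {
  expect_equal(decay(c(0, 1, 7, 100), decay_spec("power", order = 0)),
               rep(1, 4))
  expect_equal(decay(c(0, 1, 3), decay_spec("power", order = 2)),
               c(1, 0.25, 1 / 16))
  expect_equal(decay(c(0, 6, 8), decay_spec("exponential", boundary = 6)),
               c(1, 1, 0.25))
  expect_equal(decay(c(5, 6, 6.5), decay_spec("hard_boundary", boundary = 6)),
               c(1, 1, 0))
  expect_equal(decay(Inf, decay_spec("power", order = 0)), 0)
  expect_equal(decay(Inf, decay_spec("exponential", boundary = 6)), 0)
  # decay is non-increasing in distance
  d <- seq(0, 12, by = 0.5)
  for (spec in list(decay_spec("power", order = 1.5),
                    decay_spec("exponential", boundary = 3),
                    decay_spec("hard_boundary", boundary = 3))) {
    expect_true(all(diff(decay(d, spec)) <= 1e-12))
  }
  expect_error(decay_spec("power"), "order")
  expect_error(decay_spec("exponential"), "boundary")
})

test_that("weights combine decay and shared base-reaction penalties", {
  dist_row <- c(A_f = 0, B_f = 2, B_r = 2, C_f = Inf)
  base <- c(A_f = "A", B_f = "B", B_r = "B", C_f = "C")
  pen <- c(A = 2, B = 4, C = 5)
  w <- efpa_weights(pen, dist_row, decay_spec("hard_boundary", boundary = 2),
                    base)
  expect_equal(w, c(A_f = 2, B_f = 4, B_r = 4, C_f = 0))
  w2 <- efpa_weights(pen, dist_row, decay_spec("power", order = 1), base)
  expect_equal(unname(w2["B_f"]), 4 / 3)
  # random instances match an element-wise oracle
  set.seed(13)
  for (i in 1:10) {
    d <- setNames(sample(c(0:5, Inf), 6, TRUE), paste0("r", 1:6, "_f"))
    b <- setNames(paste0("r", 1:6), names(d))
    p <- setNames(runif(6, 0, 10), paste0("r", 1:6))
    spec <- decay_spec("exponential", boundary = 2)
    expect_equal(efpa_weights(p, d, spec, b),
                 setNames(ifelse(is.finite(d),
                                 ifelse(d <= 2, 1, 2^(-(d - 2))) * p[b], 0),
                          names(d)))
  }
})

test_that("flux potential solves the chain LP to the hand-derived optimum", {
  net <- chain3()
  dnet <- split_reversible(net)
  w1 <- setNames(rep(1, 3), colnames(dnet$S))
  fp <- flux_potential(dnet, "R2_f", w1, allowance = 1)
  expect_equal(fp$fp, 1 / 3, tolerance = 1e-9)
  expect_equal(fp$status, "optimal")
  # penalties 2 halve the budgeted flux
  fp2 <- flux_potential(dnet, "R2_f", w1 * 2, allowance = 1)
  expect_equal(fp2$fp, 1 / 6, tolerance = 1e-9)
  # blocked ROI carries nothing
  dnet0 <- dnet; dnet0$ub["R2_f"] <- 0
  expect_equal(flux_potential(dnet0, "R2_f", w1)$fp, 0)
  # all-zero weights are only limited by the flux bounds, flagged clamped
  fpc <- flux_potential(dnet, "R2_f", w1 * 0, allowance = 1)
  expect_equal(fpc$fp, 1000)
  expect_equal(fpc$status, "clamped")
})

test_that("relative FP normalizes by the super condition and flags undefined", {
  expect_equal(relative_fp(0.2, 0.4), 0.5)
  expect_equal(relative_fp(0.4, 0.4), 1)
  expect_true(is.na(relative_fp(0.1, 0)))
})

test_that("rFP equals the ROI's own relative expression at boundary 0", {
  net <- make_toy_network("linear", length = 4)
  sim <- simulate_expression(net, n_conditions = 6, seed = 9)
  re <- reaction_expression(net, sim$levels)
  rel <- normalize_relative(re$raw, re$status)
  res <- run_efpa(net, rel, rois = "R2",
                  config = efpa_config(decay = decay_spec("hard_boundary",
                                                          boundary = 0)))
  expect_equal(res$rfp, unname(rel$rel["R2", res$condition]),
               tolerance = 1e-6)
})

test_that("uniform maximal expression gives rFP 1 everywhere", {
  net <- make_toy_network("linear", length = 3)
  rel <- uniform_rel(net, paste0("c", 1:3))
  res <- run_efpa(net, rel, rois = c("R1", "R2"), config = efpa_config())
  expect_true(all(abs(res$rfp - 1) < 1e-9))
})

test_that("rFP is invariant to the flux allowance", {
  net <- make_toy_network("branched", pathway_length = 3, distal_length = 2,
                          roi_has_gene = TRUE)
  sim <- simulate_expression(net, n_conditions = 4, seed = 23)
  re <- reaction_expression(net, sim$levels)
  rel <- normalize_relative(re$raw, re$status)
  base <- NULL
  for (A in c(0.1, 1, 10)) {
    res <- run_efpa(net, rel, rois = "ROI",
                    config = efpa_config(allowance = A))
    if (is.null(base)) base <- res$rfp
    else expect_equal(res$rfp, base, tolerance = 1e-6)
  }
})

test_that("raising expression in a condition never lowers that condition's FP", {
  for (seed in 1:8) {
    fx <- random_fixture(seed)
    re <- reaction_expression(fx$net, fx$sim$levels)
    rel <- normalize_relative(re$raw, re$status)
    roi <- attr(fx$net, "roi")
    cfg <- efpa_config()
    before <- run_efpa(fx$net, rel, rois = roi, config = cfg)
    set.seed(seed + 100)
    gene <- sample(rownames(fx$sim$levels), 1)
    cond <- sample(colnames(fx$sim$levels), 1)
    lev2 <- fx$sim$levels
    lev2[gene, cond] <- lev2[gene, cond] * 2
    re2 <- reaction_expression(fx$net, lev2)
    rel2 <- normalize_relative(re2$raw, re2$status)
    after <- run_efpa(fx$net, rel2, rois = roi, config = cfg)
    expect_gte(after$fp[after$condition == cond],
               before$fp[before$condition == cond] - 1e-7)
  }
})

test_that("neighborhood expression alone predicts flux for a data-less ROI", {
  # Fig-2G-style check: the ROI has no expression data at all, yet its rFP
  # tracks the simulated pathway flux through the coexpressed neighbors.
  net <- make_toy_network("branched", pathway_length = 4, distal_length = 4)
  pccs <- vapply(1:5, function(s) {
    sim <- simulate_expression(net, n_conditions = 25, rho = 0.8, seed = s)
    re <- reaction_expression(net, sim$levels)
    rel <- normalize_relative(re$raw, re$status)
    res <- run_efpa(net, rel, rois = "ROI", config = efpa_config())
    cor(res$rfp[match(colnames(rel$rel), res$condition)], sim$flux["ROI", ])
  }, numeric(1))
  expect_true(all(pccs > 0.4))
  # excluding the ROI's own penalty leaves a with-data ROI still predictive
  net2 <- make_toy_network("branched", pathway_length = 4, distal_length = 4,
                           roi_has_gene = TRUE)
  sim <- simulate_expression(net2, n_conditions = 25, rho = 0.8, seed = 77)
  re <- reaction_expression(net2, sim$levels)
  rel <- normalize_relative(re$raw, re$status)
  res <- run_efpa(net2, rel, rois = "ROI", config = efpa_config(),
                  exclude_roi = TRUE)
  expect_gt(cor(res$rfp[match(colnames(rel$rel), res$condition)],
                sim$flux["ROI", ]), 0.4)
})

test_that("reversible ROIs are reported per direction", {
  net <- chain3()
  net$lb["R2"] <- -1000
  rel <- uniform_rel(net, c("c1", "c2"), value = 0.5)
  res <- run_efpa(net, rel, rois = "R2", config = efpa_config())
  expect_setequal(unique(res$direction), c("f", "r"))
  expect_equal(nrow(res), 4)
  m <- rfp_matrix(res)
  expect_equal(rownames(m), c("R2_f", "R2_r"))
})

test_that("bound overrides block flux through a chosen direction", {
  net <- make_toy_network("linear", length = 3)
  rel <- uniform_rel(net, "c1")
  res <- run_efpa(net, rel, rois = "R2", config = efpa_config(),
                  bounds = c(UPT_f = 0))
  expect_equal(res$fp, 0)
})
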