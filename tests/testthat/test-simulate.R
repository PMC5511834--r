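test_that("indicator panel is monotone, positive and seed-reproducible", {
  truth <- indicator_truth(noise_sd = 0, seed = 3)
  panel <- gen_indicator_panel(truth)
  for (j in seq_len(ncol(panel))) {
    d <- diff(panel[, j])
    if (truth$criteria$direction[j] == "increasing")
      expect_true(all(d > 0)) else expect_true(all(d < 0))
  }
  noisy <- indicator_truth(noise_sd = 1.5, seed = 3)
  p1 <- gen_indicator_panel(noisy)
  p2 <- gen_indicator_panel(noisy)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0))
  expect_false(identical(p1, gen_indicator_panel(
    indicator_truth(noise_sd = 1.5, seed = 4))))
})

test_that("indicator truth rejects non-positive trends and disordered levels", {
  expect_error(indicator_truth(levels = c(0, 100, 50)), "strictly increasing")
  expect_error(indicator_truth(noise_sd = -1), "noise_sd")
  bad <- data.frame(name = "h", direction = "decreasing", baseline = 3,
                    step = 1)
  expect_error(indicator_truth(levels = 0:5, criteria = bad), "non-positive")
})

test_that("count matrix plants the requested DE structure", {
  truth <- de_truth(n_genes = 1000, prop_de = 0.1, lib_sizes = rep(1e6, 6),
                    seed = 8)
  sim <- gen_count_matrix(truth)
  expect_identical(sum(sim$labels != "null"), 100L)
  expect_identical(sum(sim$labels == "up"), as.integer(round(0.395 * 100)))
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == floor(sim$counts)))
  expect_setequal(unique(sim$labels), c("up", "down", "null"))
  expect_identical(sim$counts, gen_count_matrix(truth)$counts)
})

test_that("column sums stay within Poisson sampling error of lib_sizes", {
  truth <- de_truth(n_genes = 800, prop_de = 0.1, lfc_magnitude = 3,
                    dispersion = 0, lib_sizes = rep(2e6, 6), seed = 15)
  sim <- gen_count_matrix(truth)
  # balanced up/down flow: every column (both conditions) ~ Poisson(lib)
  z <- (colSums(sim$counts) - 2e6) / sqrt(2e6)
  expect_true(all(abs(z) < 5))
})

test_that("planted genes have expected FPKM ratio 2^(+/-lfc)", {
  truth <- de_truth(n_genes = 500, prop_de = 0.2, lfc_magnitude = 2,
                    dispersion = 0, lib_sizes = rep(5e6, 6), seed = 2)
  sim <- gen_count_matrix(truth)
  fk <- fpkm(sim$counts, sim$lengths)
  ratio <- rowMeans(fk[, 4:6]) / rowMeans(fk[, 1:3])
  expect_equal(median(ratio[sim$labels == "up"]), 4, tolerance = 0.05)
  expect_equal(median(ratio[sim$labels == "down"]), 0.25, tolerance = 0.05)
  expect_equal(median(ratio[sim$labels == "null"]), 1, tolerance = 0.05)
})

test_that("degenerate truth gives all-null genes with ratio 1", {
  truth <- de_truth(n_genes = 100, prop_de = 0, lfc_magnitude = 0,
                    dispersion = 0, lib_sizes = rep(1e6, 6))
  sim <- gen_count_matrix(truth)
  expect_true(all(sim$labels == "null"))
  expect_error(de_truth(prop_de = 1.2), "prop_de")
})

test_that("generator substreams are independent of each other", {
  truth <- de_truth(n_genes = 100, lib_sizes = rep(1e5, 6), seed = 5)
  sim <- gen_count_matrix(truth)
  panel_a <- gen_indicator_panel(indicator_truth(seed = 5))
  invisible(gen_count_matrix(truth))   # interleave another generator
  panel_b <- gen_indicator_panel(indicator_truth(seed = 5))
  expect_identical(panel_a, panel_b)
})

test_that("pathway generator plants excess DE membership", {
  sim <- small_sim()
  truth <- pathway_truth(n_pathways = 10, enriched_ids = c("PW01", "PW02"),
                         seed = 4)
  sets <- gen_pathways(truth, sim$labels)
  expect_length(sets, 10)
  expect_true(all(unlist(sets) %in% names(sim$labels)))
  de <- names(sim$labels)[sim$labels != "null"]
  frac <- vapply(sets, function(s) mean(s %in% de), numeric(1))
  expect_true(all(frac[c("PW01", "PW02")] > 0.4))
  expect_true(mean(frac[-(1:2)]) < 0.25)
  expect_error(gen_pathways(pathway_truth(n_pathways = 1, sizes = 10000),
                            sim$labels), "exceeds")
  # all genes in one pathway: overlap equals the full DE count
  all_in <- gen_pathways(pathway_truth(n_pathways = 1,
                                       sizes = length(sim$labels),
                                       enriched_ids = character(0)),
                         sim$labels)
  expect_setequal(all_in$PW01, names(sim$labels))
})

test_that("no planted enrichment means no planted excess", {
  sim <- small_sim()
  sets <- gen_pathways(pathway_truth(n_pathways = 30,
                                     enriched_ids = character(0), seed = 1),
                       sim$labels)
  er <- enrich(names(sim$labels)[sim$labels != "null"], names(sim$labels),
               sets)
  expect_lt(mean(er$Significant), 0.2)
})

test_that("ct table round-trips planted fold changes exactly at zero noise", {
  labels <- c(gU = "up", gD = "down", gN = "null")
  ct <- gen_ct_table(labels, lfc_magnitude = 1, noise_sd = 0, seed = 1)
  rq <- ddct(ct)
  expect_equal(rq$fold[rq$gene == "gU"], 2)
  expect_equal(rq$fold[rq$gene == "gD"], 0.5)
  expect_equal(rq$fold[rq$gene == "gN"], 1)
  expect_error(gen_ct_table(labels, reference_gene = ""), "reference")
  expect_identical(gen_ct_table(labels, seed = 7), gen_ct_table(labels, seed = 7))
})
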