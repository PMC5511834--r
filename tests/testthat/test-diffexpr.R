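test_that("fpkm matches its definition", {
  # count 10, length 1000 bp, library 1e6 -> FPKM 10
  m <- rbind(g1 = c(10, 5), g2 = c(1e6 - 10, 1e6 - 5))
  expect_equal(unname(fpkm(m, c(1000, 5000))["g1", 1]), 10)
  expect_equal(fpkm(rbind(c(0, 3), c(5, 2)), c(100, 100))[1, 1], 0)
  set.seed(1)
  cm <- matrix(rpois(24, 40), 4, 6)
  len <- sample(500:2000, 4)
  expect_equal(fpkm(cm, len), fpkm_oracle(cm, len))
  expect_error(fpkm(cbind(c(0, 0)), c(10, 10)), "library")
  expect_error(fpkm(cbind(c(1, 1)), c(0, 10)), "length")
})

test_that("log2 ratio honours the pseudocount convention", {
  expect_equal(log2_ratio(4, 1, pseudocount = 0), 2)
  expect_equal(log2_ratio(3.7, 3.7), 0)
  expect_equal(log2_ratio(0, 1, pseudocount = 0.125), log2(0.125 / 1.125))
  expect_error(log2_ratio(0, 0, pseudocount = 0), "pseudocount")
})

test_that("the per-gene test matches a hand-computed Welch t", {
  x <- c(5.1, 4.8, 5.6)
  y <- c(2.0, 2.4, 1.7)
  expect_equal(as.numeric(de_test(x, y)), welch_oracle(x, y), tolerance = 1e-12)
  expect_equal(as.numeric(de_test(c(1, 2, 3), c(1, 2, 3))),
               welch_oracle(c(1, 2, 3), c(1, 2, 3)))
  # identical constant groups: p = 1 by convention, flagged
  p <- de_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(as.numeric(p), 1)
  expect_true(attr(p, "degenerate"))
  expect_error(de_test(1, c(1, 2)), "replicates")
})

test_that("bh_adjust equals the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(10)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("call_de applies the threshold cascade row by row", {
  tab <- data.frame(
    gene = c("a", "b", "c", "d", "e"),
    fpkm_control = c(1, 1, 1, 0.01, 1),
    fpkm_salt = c(4, 1.5, 0.2, 0.04, 6),
    log2_ratio = c(1.5, 0.5, -1.8, 1.2, 2.5),
    p_value = c(0.001, 1e-7, 0.01, 0.001, 0.2),
    q_value = c(5e-4, 1e-6, 1e-4, 5e-4, 0.5))
  de <- call_de(tab)
  expect_identical(de$status,
                   c("up", "not_significant", "down", "up", "not_significant"))
  # key-gene screen needs FPKM above the floor in some condition
  expect_identical(de$key_gene, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  cnt <- attr(de, "counts")
  expect_identical(sum(cnt), nrow(tab))
  expect_error(call_de(tab[, -3]), "missing columns")

  # enumeration oracle on a random table
  set.seed(4)
  rt <- data.frame(gene = paste0("g", 1:300),
                   fpkm_control = runif(300, 0, 2),
                   fpkm_salt = runif(300, 0, 2),
                   log2_ratio = rnorm(300, 0, 1.5),
                   p_value = runif(300)^2)
  rt$q_value <- bh_oracle(rt$p_value)
  de2 <- call_de(rt)
  pass <- rt$p_value < 0.05 & rt$q_value <= 0.001 & abs(rt$log2_ratio) >= 1
  expect_identical(sum(attr(de2, "counts")[c("up", "down")]),
                   as.integer(sum(pass)))
  expect_identical(de2$status == "up", pass & rt$log2_ratio > 0)
})

test_that("raising the lfc threshold never increases the DE count", {
  sim <- small_sim()
  de_counts <- vapply(c(0.5, 1, 2, 3), function(cut) {
    de <- de_analysis(sim, lfc = cut)
    sum(de$status != "not_significant")
  }, numeric(1))
  expect_true(all(diff(de_counts) <= 0))
})

test_that("planted truth is recovered at high signal and zero dispersion", {
  sim <- gen_count_matrix(de_truth(n_genes = 400, prop_de = 0.1,
                                   lfc_magnitude = 4, dispersion = 0,
                                   lib_sizes = rep(2e6, 6), seed = 6))
  de <- de_analysis(sim)
  truth_de <- sim$labels != "null"
  called <- de$status != "not_significant"
  expect_gt(mean(called[truth_de]), 0.95)
  expect_lt(mean(called[!truth_de]), 0.05)
  # planted strong genes reach very small p
  expect_lt(median(de$p_value[truth_de]), 0.001)
  # direction agrees with the planted label for every called DE gene
  expect_true(all(de$status[called & sim$labels == "up"] == "up"))
  expect_true(all(de$status[called & sim$labels == "down"] == "down"))
})

test_that("key-gene screen applies both extra floors and groups by pathway", {
  sim <- small_sim()
  de <- de_analysis(sim)
  key <- screen_key_genes(de)
  manual <- de$status != "not_significant" &
    pmax(de$fpkm_control, de$fpkm_salt) > 0.05 & abs(de$log2_ratio) >= 1
  expect_setequal(key$gene, de$gene[manual])
  ann <- data.frame(gene = de$gene[manual][1:2],
                    pathway = c("starch and sucrose", "glutathione"))
  grouped <- screen_key_genes(de, annotation = ann)
  expect_true(all(c("pathway", "gene") %in% names(grouped)))
  expect_identical(nrow(grouped), 2L)
})

test_that("category tallies match a brute-force dictionary count", {
  ann <- data.frame(gene = c("g1", "g1", "g2", "g3"),
                    category = c("metabolic", "stress", "metabolic", "stress"))
  tal <- tally_categories(c("g1", "g2", "g4"), ann)
  expect_identical(tal$count[tal$category == "metabolic"], 2L)
  expect_identical(tal$count[tal$category == "stress"], 1L)
  expect_identical(tal$count[tal$category == "unclassified"], 1L)
  empty <- tally_categories(c("g1", "g2"),
                            data.frame(gene = character(0),
                                       category = character(0)))
  expect_identical(empty$category, "unclassified")
  expect_identical(empty$count, 2L)
})

test_that("volcano coordinates use the raw p-value axis", {
  sim <- small_sim()
  de <- de_analysis(sim)
  vd <- volcano_data(de)
  expect_equal(vd$neg_log10_p, -log10(de$p_value))
  expect_identical(nrow(vd), nrow(de))
})
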