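test_that("normalization gives unit-norm columns and known small cases", {
  expect_equal(as.vector(topsis_normalize(cbind(c(3, 4)))), c(0.6, 0.8))
  expect_equal(as.vector(topsis_normalize(cbind(rep(2, 3)))),
               rep(1 / sqrt(3), 3))
  set.seed(7)
  x <- matrix(runif(30, 0.1, 10), 6, 5)
  r <- topsis_normalize(x)
  expect_equal(colSums(r^2), rep(1, 5))
  expect_error(topsis_normalize(cbind(c(0, 0))), "all-zero")
})

test_that("weighting scales columns and validates the weight vector", {
  r <- topsis_normalize(matrix(runif(20, 1, 5), 4, 5))
  expect_equal(topsis_weight(r, rep(0.2, 5)), r / 5)
  v1 <- topsis_weight(r, c(1, 0, 0, 0, 0))
  expect_true(all(v1[, -1] == 0) && all(v1[, 1] != 0))
  w <- c(0.3, 0.25, 0.2, 0.15, 0.1)
  v <- topsis_weight(r, w)
  expect_equal(sweep(v, 2, w, "/"), r)
  expect_error(topsis_weight(r, c(0.5, 0.5, 0.5, 0.2, 0.2)), "sum to 1")
})

test_that("ideal solutions respect criterion orientation", {
  v <- cbind(c(0.1, 0.5, 0.3))
  expect_equal(unname(ideal_solutions(v, "benefit")$pos), 0.5)
  expect_equal(unname(ideal_solutions(v, "benefit")$neg), 0.1)
  expect_equal(unname(ideal_solutions(v, "cost")$pos), 0.1)
  expect_equal(unname(ideal_solutions(v, "cost")$neg), 0.5)
})

test_that("separations are Euclidean and satisfy the triangle inequality", {
  v <- rbind(a = c(0.5, 0.9), b = c(0.2, 0.5))
  ideals <- list(pos = c(0.5, 0.9), neg = c(0.2, 0.5))
  sep <- separations(v, ideals)
  expect_equal(unname(sep$d_pos["a"]), 0)
  expect_equal(unname(sep$d_neg["a"]), 0.5)  # componentwise (0.3, 0.4)
  set.seed(11)
  for (rep in 1:20) {
    x <- matrix(runif(24, 0.5, 5), 6, 4)
    fit <- topsis(x, orientations = sample(c("benefit", "cost"), 4, TRUE))
    gap <- sqrt(sum((fit$ideal_pos - fit$ideal_neg)^2))
    expect_true(all(fit$d_pos + fit$d_neg >= gap - 1e-12))
  }
})

test_that("closeness reproduces the published concentration and time tables", {
  conc <- data.frame(
    alt = c("0", "50", "100", "150", "200", "250"),
    d_pos = c(1.8515, 1.4561, 1.0262, 0.9217, 0.2262, 0.3819),
    d_neg = c(0, 0.3166, 0.6325, 0.7883, 1.4237, 1.3864),
    R = c(0, 0.1786, 0.3813, 0.461, 0.8629, 0.784),
    rank = c(6, 5, 4, 3, 1, 2))
  time <- data.frame(
    alt = c("7d", "11d", "15d", "19d", "23d"),
    d_pos = c(1.0664, 0.6952, 0.3626, 0.0985, 0.4511),
    d_neg = c(0, 0.1435, 0.4338, 0.741, 0.4728),
    R = c(0, 0.1711, 0.5447, 0.8827, 0.5117),
    rank = c(5, 4, 2, 1, 3))
  for (tab in list(conc, time)) {
    R <- closeness(tab$d_pos, tab$d_neg)
    expect_equal(round(R, 4), round(tab$R, 4), tolerance = 1e-12)
    expect_identical(rank_alternatives(R), as.integer(tab$rank))
    expect_identical(rank_alternatives(tab$R), as.integer(tab$rank))
  }
  expect_error(closeness(0, 0), "meaningless")
})

test_that("ranking breaks closeness ties by smaller d+ then input order", {
  expect_identical(rank_alternatives(c(0.5, 0.5), d_pos = c(0.2, 0.1)),
                   c(2L, 1L))
  expect_identical(rank_alternatives(c(0.5, 0.5)), c(1L, 2L))
  set.seed(3)
  R <- runif(8)
  expect_setequal(rank_alternatives(R), 1:8)
})

test_that("topsis fit invariants hold on random panels", {
  set.seed(21)
  x <- matrix(runif(30, 1, 9), 6, 5,
              dimnames = list(paste0("A", 1:6), paste0("C", 1:5)))
  ori <- c("benefit", "cost", "benefit", "benefit", "cost")
  fit <- topsis(x, ori)
  expect_true(all(fit$closeness >= 0 & fit$closeness <= 1))
  expect_setequal(fit$rank, 1:6)

  # scale invariance: normalization divides out any positive column scale
  x2 <- x; x2[, 3] <- x2[, 3] * 37.5
  expect_equal(topsis(x2, ori)$closeness, fit$closeness)

  # reversing every orientation reverses the rank order
  flip <- ifelse(ori == "benefit", "cost", "benefit")
  expect_identical(unname(topsis(x, flip)$rank),
                   as.integer(7 - unname(fit$rank)))

  # an alternative dominating every criterion gets rank 1 with R = 1
  dom <- x
  dom[1, ] <- ifelse(ori == "benefit", apply(x, 2, max) * 2,
                     apply(x, 2, min) / 2)
  fd <- topsis(dom, ori)
  expect_equal(unname(fd$closeness[1]), 1)
  expect_identical(unname(fd$rank[1]), 1L)

  # permuting alternative rows permutes ranks identically
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_identical(unname(topsis(x[perm, ], ori)$rank), unname(fit$rank)[perm])
})

test_that("single-criterion ranking reduces to sorting by orientation", {
  x <- cbind(val = c(3, 9, 1, 5))
  rownames(x) <- paste0("A", 1:4)
  expect_identical(unname(topsis(x, "benefit")$rank),
                   as.integer(rank(-x[, 1])))
  expect_identical(unname(topsis(x, "cost")$rank),
                   as.integer(rank(x[, 1])))
})

test_that("decision_matrix validates shape, finiteness and positivity", {
  expect_error(decision_matrix(matrix(1:3, 1)), "2 alternatives")
  expect_error(decision_matrix(rbind(c(1, NA), c(2, 3))), "missing")
  expect_error(decision_matrix(rbind(c(1, -2), c(2, 3))), "positive")
  dm <- decision_matrix(rbind(c(1, 2), c(3, 4)))
  expect_s3_class(dm, "decision_matrix")
})

test_that("display table rounds half-up to 4 decimals", {
  fit <- topsis(rbind(c(1, 5), c(4, 2), c(3, 3)), c("benefit", "cost"))
  df <- as.data.frame(fit)
  expect_named(df, c("Alternative", "d_plus", "d_minus", "R", "Rank"))
  expect_equal(df$R, unname(round(fit$closeness + 1e-15, 4)),
               tolerance = 1e-9)
  # explicit half-up behaviour at the .00005 boundary
  expect_equal(saltstress:::round_half_up(0.86285, 4), 0.8629)
  expect_equal(saltstress:::round_half_up(0.12345, 4), 0.1235)
})
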