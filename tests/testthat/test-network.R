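sample_names <- paste0("s", 1:9)

profile_matrix <- function(...) {
  m <- rbind(...)
  colnames(m) <- sample_names[seq_len(ncol(m))]
  m
}

test_that("perfect linear relations produce signed edges", {
  x <- 1:9
  a <- profile_matrix(m1 = x)
  b <- profile_matrix(g1 = 2 * x + 1, g2 = -x + 3)
  ed <- correlation_network(a, b)
  expect_equal(nrow(ed), 2L)
  pos <- ed[ed$node_b == "g1", ]
  expect_equal(pos$r, 1, tolerance = 1e-12)
  expect_equal(pos$sign, "positive")
  neg <- ed[ed$node_b == "g2", ]
  expect_equal(neg$r, -1, tolerance = 1e-12)
  expect_equal(neg$sign, "negative")
  expect_true(all(ed$p < 0.05))
})

test_that("the r-squared threshold is applied as printed", {
  # construct a pair with r exactly 0.89: r^2 = 0.7921 < 0.8
  set.seed(42)
  x <- rnorm(9)
  xs <- (x - mean(x)) / sd(x)
  e <- residuals(lm(rnorm(9) ~ xs))
  es <- (e - mean(e)) / sd(e)
  target <- 0.89
  y <- target * xs + sqrt(1 - target^2) * es
  expect_lt(abs(cor(x, y) - target), 1e-12)
  ed <- correlation_network(profile_matrix(m1 = x), profile_matrix(g1 = y))
  expect_equal(nrow(ed), 0L)  # 0.7921 < 0.8 despite p < 0.05
  ed_loose <- correlation_network(profile_matrix(m1 = x),
                                  profile_matrix(g1 = y),
                                  threshold_r2 = 0.75)
  expect_equal(nrow(ed_loose), 1L)
})

test_that("r and p match the covariance-formula oracle", {
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(9); y <- 0.9 * x + rnorm(9, sd = 0.3)
    ed <- correlation_network(profile_matrix(a = x), profile_matrix(b = y),
                              threshold_r2 = 0, threshold_p = 1)
    r_oracle <- oracle_pearson(x, y)
    expect_equal(ed$r, r_oracle, tolerance = 1e-12)
    expect_equal(ed$r2, r_oracle^2, tolerance = 1e-12)
    # p from the exact t transform, df = n - 2
    tval <- r_oracle * sqrt(7 / (1 - r_oracle^2))
    expect_equal(ed$p, 2 * pt(-abs(tval), 7), tolerance = 1e-12)
    expect_equal(ed$p, cor.test(x, y)$p.value, tolerance = 1e-9)
  }
})

test_that("edge sets are symmetric in the argument order", {
  set.seed(3)
  a <- matrix(rnorm(27), 3, 9,
              dimnames = list(paste0("m", 1:3), sample_names))
  base <- a[1, ] + rnorm(9, sd = 0.1)
  b <- rbind(g1 = base, g2 = rnorm(9), g3 = -base + rnorm(9, sd = 0.1))
  colnames(b) <- sample_names
  ed_ab <- correlation_network(a, b, threshold_r2 = 0.5)
  ed_ba <- correlation_network(b, a, threshold_r2 = 0.5)
  key_ab <- sort(paste(ed_ab$node_a, ed_ab$node_b, round(ed_ab$r, 10)))
  key_ba <- sort(paste(ed_ba$node_b, ed_ba$node_a, round(ed_ba$r, 10)))
  expect_equal(key_ab, key_ba)
})

test_that("lowering the r2 threshold never removes an edge", {
  set.seed(5)
  a <- matrix(rnorm(45), 5, 9,
              dimnames = list(paste0("m", 1:5), sample_names))
  b <- a + matrix(rnorm(45, sd = 0.5), 5, 9)
  prev <- NULL
  for (r2 in c(0.9, 0.8, 0.6, 0.3)) {
    ed <- correlation_network(a, b, threshold_r2 = r2, threshold_p = 0.2)
    key <- paste(ed$node_a, ed$node_b)
    if (!is.null(prev)) expect_true(all(prev %in% key))
    prev <- key
  }
})

test_that("constant profiles and mismatched samples are handled", {
  a <- profile_matrix(m1 = rep(1, 9), m2 = 1:9)
  b <- profile_matrix(g1 = 2 * (1:9))
  expect_warning(ed <- correlation_network(a, b), "constant")
  expect_equal(ed$node_a, "m2")
  b_bad <- b; colnames(b_bad) <- rev(sample_names)
  expect_error(correlation_network(a, b_bad), "match")
  expect_error(correlation_network(a[, 1:2], b[, 1:2, drop = FALSE]),
               "at least 3")
})

test_that("node summaries add positive and negative degrees", {
  ed <- data.frame(
    node_a = c("m1", "m1", "m1", "m2"), role_a = "DF",
    node_b = c("g1", "g2", "g3", "g1"), role_b = "DEG",
    r = c(0.95, 0.99, -0.97, 0.96), r2 = c(0.95, 0.99, 0.97, 0.96)^2,
    p = 1e-4, sign = c("positive", "positive", "negative", "positive"),
    stringsAsFactors = FALSE)
  ns <- node_summary(ed)
  m1 <- ns[ns$node == "m1", ]
  expect_equal(m1$degree, 3L)
  expect_equal(m1$positive, 2L)
  expect_equal(m1$negative, 1L)
  expect_equal(ns$degree, ns$positive + ns$negative)
  expect_equal(nrow(node_summary(flavomix:::empty_edges())), 0L)
})

test_that("a planted hub reaches full degree at negligible noise", {
  set.seed(9)
  hub <- rnorm(9)
  genes <- do.call(rbind, lapply(1:5, function(i) hub * (1 + 0.01 * i)))
  rownames(genes) <- paste0("g", 1:5)
  colnames(genes) <- sample_names
  ed <- correlation_network(profile_matrix(hub = hub), genes)
  expect_equal(node_summary(ed)$degree[1], 5L)
})

test_that("orthogonalized random profiles yield almost no chords", {
  # null simulation: expected edges per pair tested stays far below the
  # nominal level at the joint r2/p thresholds (100 seeds)
  edges <- 0L; pairs <- 0L
  for (s in 1:100) {
    set.seed(s)
    tf <- matrix(rnorm(18), 2, 9)
    enz <- matrix(rnorm(18), 2, 9)
    rownames(tf) <- c("MYB:g1", "bHLH:g2")
    rownames(enz) <- c("FLS", "DFR")
    ed <- tf_enzyme_chords(tf, enz)
    edges <- edges + nrow(ed)
    pairs <- pairs + 4L
  }
  expect_lt(edges / pairs, 0.05)
})

test_that("negating a profile flips only the sign of its chords", {
  set.seed(12)
  x <- rnorm(9)
  tf <- profile_matrix(`MYB:g1` = x)
  enz <- profile_matrix(FLS = x + rnorm(9, sd = 0.05))
  ed_pos <- tf_enzyme_chords(tf, enz)
  ed_neg <- tf_enzyme_chords(-tf, enz)
  expect_equal(ed_pos$sign, "positive")
  expect_equal(ed_neg$sign, "negative")
  expect_equal(ed_neg$r, -ed_pos$r, tolerance = 1e-12)
  expect_equal(ed_neg$p, ed_pos$p, tolerance = 1e-12)
  expect_equal(ed_pos$role_a, "TF")
  expect_equal(ed_pos$role_b, "enzyme")
})
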