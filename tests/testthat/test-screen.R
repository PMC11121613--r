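toy_matrix <- function(fcs, base = 100) {
  # 3 + 3 samples; group B means are base * fc, zero within-group noise
  m <- rbind(vapply(fcs, function(f) rep(c(base, base * f), each = 3),
                    numeric(6)))
  m <- t(m)
  rownames(m) <- paste0("feat", seq_along(fcs))
  colnames(m) <- c("A1", "A2", "A3", "B1", "B2", "B3")
  m
}

test_that("fold change is the ratio of linear-scale group means", {
  m <- toy_matrix(c(2, 0.5, 1))
  fc <- fold_change(m, rep(c("A", "B"), each = 3), c("A", "B"))
  expect_equal(fc$fc, c(2, 0.5, 1))
  expect_equal(fc$log2fc, log2(fc$fc), tolerance = 1e-9)
  # zero denominator flagged as NA
  m0 <- rbind(z = c(0, 0, 0, 1, 1, 1))
  colnames(m0) <- colnames(m)
  expect_true(is.na(fold_change(m0, rep(c("A", "B"), each = 3),
                                c("A", "B"))$fc))
})

test_that("DF selection applies the VIP and FC thresholds as printed", {
  m <- toy_matrix(c(1.5, 3.0, 0.67, 1.4, 0.67, 2.0))
  g <- rep(c("A", "B"), each = 3)
  vip <- c(feat1 = 1.2, feat2 = 0.9, feat3 = 1.1, feat4 = 1.5,
           feat5 = 1.0, feat6 = 1.01)
  hits <- screen_dfs(m, g, c("A", "B"), vip)
  # feat1: VIP 1.2 & FC = 1.5 (inclusive boundary) -> selected, up
  expect_true("feat1" %in% hits$feature_id)
  expect_equal(hits$direction[hits$feature_id == "feat1"], "up")
  # feat2: FC 3.0 but VIP 0.9 -> rejected; feat5: VIP exactly 1 -> rejected
  expect_false(any(c("feat2", "feat5") %in% hits$feature_id))
  # feat3: FC boundary 0.67 inclusive -> selected, down
  expect_equal(hits$direction[hits$feature_id == "feat3"], "down")
  # feat4: FC 1.4 inside the dead band -> rejected
  expect_false("feat4" %in% hits$feature_id)
  expect_true("feat6" %in% hits$feature_id)
  expect_equal(hits$log2fc, log2(hits$fc), tolerance = 1e-9)
  expect_true(all((hits$fc > 1) == (hits$direction == "up")))
})

test_that("raising either threshold never adds DF hits", {
  sim <- simulate_metabolome(
    study_design(seed = 21), n_features = 300, n_flavonoids = 80,
    planted = planted_spec(list(MvsN = c(up = 20, down = 10))))
  sel <- sim$groups$group %in% c("M", "N")
  vip <- compute_vip(fit_opls(t(sim$matrix[, sel]),
                              sim$groups$group[sel]))
  base <- nrow(screen_dfs(sim$matrix, sim$groups, c("M", "N"), vip))
  for (vt in c(1, 1.2, 1.5, 2)) {
    for (fu in c(1.5, 2, 3)) {
      n <- nrow(screen_dfs(sim$matrix, sim$groups, c("M", "N"), vip,
                           vip_threshold = vt, fc_up = fu,
                           fc_down = 0.67 * 1.5 / fu))
      expect_lte(n, base)
      base_v <- nrow(screen_dfs(sim$matrix, sim$groups, c("M", "N"), vip,
                                vip_threshold = vt))
      expect_lte(n, base_v)
    }
  }
})

test_that("DEG screening recovers planted genes and honours the FC rule", {
  sp <- planted_spec(list(MvsN = c(up = 15, down = 10)), log2fc = 3)
  sim <- simulate_transcriptome(study_design(seed = 8), n_genes = 400,
                                planted = sp)
  hits <- screen_degs(sim$matrix, sim$groups, c("M", "N"))
  truth_ids <- sim$truth$feature_id[sim$truth$true_log2fc_MvsN != 0]
  expect_gt(length(intersect(hits$feature_id, truth_ids)) /
              length(truth_ids), 0.8)
  expect_true(all(hits$evidence < 0.05))
  expect_true(all(abs(hits$log2fc) >= 1))
  expect_true(all((hits$log2fc > 0) == (hits$direction == "up")))
  # literal rule admits any fold change with q < threshold
  lit <- screen_degs(sim$matrix, sim$groups, c("M", "N"),
                     fc_rule = "literal")
  expect_gte(nrow(lit), nrow(hits))
  expect_error(screen_degs(-sim$matrix, sim$groups, c("M", "N")),
               "nonnegative")
})

test_that("all-zero genes are skipped with a warning", {
  sim <- simulate_transcriptome(study_design(seed = 4), n_genes = 50)
  sim$matrix[3, ] <- 0
  expect_warning(hits <- screen_degs(sim$matrix, sim$groups, c("M", "N")),
                 "zero variance")
  expect_false("gene_00003" %in% hits$feature_id)
})

test_that("under the complete null BH keeps the false-positive rate at q", {
  # 100 seeds, no planted effects: mean false-discovery proportion must
  # not exceed the q threshold (plus Monte Carlo slack)
  fdp <- vapply(1:100, function(s) {
    sim <- simulate_transcriptome(study_design(seed = 5000 + s),
                                  n_genes = 120)
    hits <- screen_degs(sim$matrix, sim$groups, c("M", "N"))
    as.numeric(nrow(hits) > 0)
  }, 1)
  expect_lte(mean(fdp), 0.05 + 2 * sqrt(0.05 * 0.95 / 100))
})

test_that("venn partitions id sets", {
  v <- venn(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(v$n_shared, 2L)
  expect_equal(v$n_only_a, 1L)
  expect_equal(v$n_only_b, 1L)
  expect_setequal(v$shared, c("b", "c"))
  expect_equal(venn(c("x", "y"), c("p", "q"))$n_shared, 0L)
  same <- venn(c("a", "b"), c("b", "a"))
  expect_equal(same$n_shared, 2L)
  expect_equal(same$n_only_a + same$n_only_b, 0L)
})

test_that("class tallies conserve hit counts", {
  hits <- data.frame(
    feature_id = paste0("f", 1:5),
    comparison = "MvsN",
    fc = c(2, 3, 0.5, 0.4, 2.2),
    log2fc = log2(c(2, 3, 0.5, 0.4, 2.2)),
    direction = c("up", "up", "down", "down", "up"),
    evidence = 1.5,
    class = c("flavones", "flavones", "flavonols", "flavonols", NA),
    stringsAsFactors = FALSE)
  tt <- tally_by_class(hits)
  expect_equal(tt$up[tt$class == "flavones"], 2L)
  expect_equal(tt$down[tt$class == "flavonols"], 2L)
  expect_equal(tt$total[tt$class == "other"], 1L)
  expect_equal(sum(tt$total), nrow(hits))
  empty <- tally_by_class(hits[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("planted class-specific effects tally exactly at negligible noise", {
  sp <- planted_spec(list(MvsN = c(up = 6, down = 3)))
  sim <- simulate_metabolome(study_design(seed = 13), n_features = 80,
                             n_flavonoids = 40, planted = sp, cv = 0.005)
  sel <- sim$groups$group %in% c("M", "N")
  vip <- compute_vip(fit_opls(t(sim$matrix[, sel]),
                              sim$groups$group[sel]))
  hits <- screen_dfs(sim$matrix, sim$groups, c("M", "N"), vip,
                     class_table = sim$truth)
  tt <- tally_by_class(hits)
  truth_up <- table(sim$truth$class[sim$truth$true_log2fc_MvsN > 0])
  for (cl in names(truth_up)) {
    expect_equal(tt$up[tt$class == cl], unname(truth_up[cl]))
  }
  expect_equal(sum(tt$total), 9L)
})
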