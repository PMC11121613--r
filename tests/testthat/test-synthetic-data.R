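test_that("study design validates its invariants", {
  d <- study_design()
  expect_equal(d$groups, c("M", "N", "Q"))
  expect_equal(nrow(d$samples), 9L)
  expect_error(study_design(groups = c("M", "M", "Q")), "unique")
  expect_error(study_design(replicates_per_group = 1), "at least 2")
})

test_that("OJIP generator is deterministic and landmark-faithful", {
  d <- study_design(seed = 42)
  p <- ojip_params(noise_sd = 0.02)
  tr1 <- simulate_ojip(p, d)
  tr2 <- simulate_ojip(p, d)
  expect_identical(tr1, tr2)
  expect_true(all(tr1$fluorescence > 0))

  # noise-free trace agrees with the independently written closed form
  p0 <- ojip_params(noise_sd = 0, phase_weights = c(0.5, 0.3, 0.2))
  tr <- simulate_ojip(p0, d)
  one <- tr[tr$sample_id == "M1", ]
  analytic <- oracle_rise(2e-3, p0$f_o, p0$f_m, p0$phase_weights,
                          p0$phase_timescales)
  lms <- extract_landmarks(one)
  vj <- (lms$F_J - lms$F_O) / (lms$F_P - lms$F_O)
  vj_analytic <- (analytic - p0$f_o) / (p0$f_m - p0$f_o)
  expect_lt(abs(vj - vj_analytic), 0.05)
  # starts near f_o, saturates near f_m
  expect_lt(abs(one$fluorescence[1] - p0$f_o) / p0$f_o, 0.1)
  expect_lt(abs(max(one$fluorescence) - p0$f_m) / p0$f_m, 0.05)

  expect_error(ojip_params(phase_weights = c(0.5, 0.5, 0.5)), "sum")
  expect_error(ojip_params(phase_timescales = c(1e-2, 1e-3, 1e-1)),
               "increasing")
})

test_that("identical group parameters give a flat difference curve", {
  d <- study_design()
  tr <- simulate_ojip(ojip_params(noise_sd = 0), d)
  dw <- delta_curves(tr, "M", "N", "Wt")
  expect_true(all(abs(dw$value) < 1e-12))
  expect_equal(dw$delta_j, 0, tolerance = 1e-12)
  expect_equal(dw$delta_k, 0, tolerance = 1e-12)
})

test_that("metabolome carries the flavonoid class structure", {
  sim <- simulate_metabolome(study_design())
  expect_equal(dim(sim$matrix), c(2148L, 9L))
  expect_equal(sum(sim$truth$class != "non-flavonoid"), 487L)
  expect_true(all(sim$matrix > 0))
  # subclass proportions: flavones 41%, flavonols 29%, flavanones 9%
  cls <- table(sim$truth$class[sim$truth$class != "non-flavonoid"])
  expect_equal(unname(cls["flavones"]), floor(0.41 * 487))
  expect_equal(unname(cls["flavonols"]), floor(0.29 * 487))
  expect_error(
    simulate_metabolome(study_design(), class_proportions = c(a = 0.9, b = 0.3)),
    "at most 1")
  expect_error(simulate_metabolome(study_design(), n_features = 10,
                                   n_flavonoids = 20), "exceed")
})

test_that("zero noise and no planted effects give equal group means", {
  sim <- simulate_metabolome(study_design(), n_features = 40,
                             n_flavonoids = 10, cv = 0)
  g <- sim$groups$group
  for (grp in c("N", "Q")) {
    expect_equal(rowMeans(sim$matrix[, g == "M"]),
                 rowMeans(sim$matrix[, g == grp]))
  }
})

test_that("planted fold changes land exactly in the noise-free matrix", {
  sp <- planted_spec(list(MvsN = c(up = 5, down = 3),
                          NvsQ = c(up = 2, down = 4)), n_shared = 2)
  sim <- simulate_metabolome(study_design(), n_features = 60,
                             n_flavonoids = 30, planted = sp, cv = 0)
  fc_mn <- fold_change(sim$matrix, sim$groups, c("M", "N"))
  fc_nq <- fold_change(sim$matrix, sim$groups, c("N", "Q"))
  expect_equal(fc_mn$log2fc, sim$truth$true_log2fc_MvsN, tolerance = 1e-12)
  expect_equal(fc_nq$log2fc, sim$truth$true_log2fc_NvsQ, tolerance = 1e-12)
  # the shared features are up in MvsN and down in NvsQ
  shared <- sim$truth$true_log2fc_MvsN > 0 & sim$truth$true_log2fc_NvsQ < 0
  expect_equal(sum(shared), 2L)
})

test_that("transcriptome generator is deterministic and planted log2FC is exact", {
  d <- study_design(seed = 7)
  sp <- planted_spec(list(NvsQ = c(up = 1, down = 0)), log2fc = 0.5)
  sim1 <- simulate_transcriptome(d, n_genes = 30, planted = sp, cv = 0)
  sim2 <- simulate_transcriptome(d, n_genes = 30, planted = sp, cv = 0)
  expect_identical(sim1$matrix, sim2$matrix)
  fc <- fold_change(sim1$matrix, sim1$groups, c("N", "Q"))
  planted_row <- which(sim1$truth$true_log2fc_NvsQ != 0)
  expect_equal(fc$log2fc[planted_row], 0.5, tolerance = 1e-12)
  expect_true(all(fc$log2fc[-planted_row] == 0))
})

test_that("truth tables round-trip through TSV losslessly", {
  sp <- planted_spec(list(MvsN = c(up = 4, down = 2)))
  sim <- simulate_metabolome(study_design(), n_features = 30,
                             n_flavonoids = 12, planted = sp)
  path <- withr::local_tempfile(fileext = ".tsv")
  flavomix:::write_tsv(sim$truth, path)
  back <- flavomix:::read_tsv(path)
  expect_equal(back, sim$truth)
})

test_that("annotations honour family sizes and pathway structure", {
  met <- sprintf("met_%04d", 1:300)
  gen <- sprintf("gene_%05d", 1:1200)
  ann <- simulate_annotations(met, gen)
  expect_equal(sum(ann$tf$tf_family == "MYB"), 154L)
  expect_equal(sum(ann$tf$tf_family == "AP2-EREBP"), 93L)
  expect_equal(anyDuplicated(ann$tf$gene_id), 0L)
  expect_true(all(c("ko00941", "ko00944") %in% ann$pathways$pathway_id))
  expect_true(all(ann$pathways$id %in% c(met, gen)))
  expect_error(simulate_annotations(met, gen[1:100]), "exceed")
  expect_error(simulate_annotations(met, gen, pathway_spec = list()),
               "empty")
})

test_that("preferred ids are steered into the flavonoid pathways", {
  met <- sprintf("met_%04d", 1:300)
  gen <- sprintf("gene_%05d", 1:1200)
  prefer <- met[5:14]
  ann <- simulate_annotations(met, gen, prefer_ids = prefer)
  members <- ann$pathways$id[ann$pathways$pathway_id == "ko00941"]
  expect_true(all(prefer %in% members))
})

test_that("null DF selection rate matches the product of marginal pass rates", {
  # no planted effects: the joint VIP-and-FC pass rate should agree loosely
  # with independence of the two filters (50 seeds)
  n_seeds <- 50
  joint <- vip_rate <- fc_rate <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    sim <- simulate_metabolome(study_design(seed = 1000 + s),
                               n_features = 200, n_flavonoids = 50)
    sel <- sim$groups$group %in% c("M", "N")
    m <- fit_opls(t(sim$matrix[, sel]), sim$groups$group[sel])
    vip <- compute_vip(m)
    fcs <- fold_change(sim$matrix, sim$groups, c("M", "N"))
    pass_vip <- vip[fcs$feature_id] > 1
    pass_fc <- fcs$fc >= 1.5 | fcs$fc <= 0.67
    vip_rate[s] <- mean(pass_vip)
    fc_rate[s] <- mean(pass_fc)
    joint[s] <- mean(pass_vip & pass_fc)
  }
  expect_lt(abs(mean(joint) - mean(vip_rate) * mean(fc_rate)), 0.01)
  expect_lt(mean(joint), 0.02)  # near-empty selection under the null
})
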