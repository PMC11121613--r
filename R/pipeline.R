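#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end synthetic run: design, data
#' sizes, planted effects, OJIP treatment parameters and screening
#' thresholds. Defaults reproduce the study conditions the pipeline
#' emulates: a 3 x 3 design (M = PAR, N = UV-B, Q = UV-B + ABA), 2148
#' metabolites of which 487 are flavonoids, 47,598 genes, planted
#' differential-flavonoid splits of 83 up / 30 down (MvsN) and 18 up /
#' 30 down (NvsQ) sharing 17 features, planted differential-gene splits of
#' 1288/627 and 18/130 sharing 10 genes, and UV-B-induced J-step and
#' K-band effects that are partly reversed under ABA. The configuration is
#' a plain list and round-trips through YAML via [write_config()] /
#' [read_config()].
#'
#' @param seed Master seed for every random stream.
#' @param groups,replicates Design layout.
#' @param n_features,n_flavonoids,n_genes Omics matrix sizes.
#' @param cv Replicate coefficient of variation of both omics layers.
#' @param planted_dfs,planted_degs Named lists of `c(up=, down=)` planted
#'   counts per comparison (flavonoid features / genes).
#' @param df_shared,deg_shared Features shared between the first
#'   comparison's up set and the second's down set.
#' @param df_log2fc,deg_log2fc Absolute planted log2 fold changes.
#' @param ojip Named list per group of `j_step_shift` and `k_band_amp`
#'   values for the transient generator.
#' @param ojip_noise_sd Multiplicative noise level of the transients.
#' @param thresholds List of screening thresholds: `vip`, `fc_up`,
#'   `fc_down`, `q`, `lfc`, `r2`, `p`, `q2`.
#' @param contrasts List of `c(control, treatment)` comparisons.
#' @param out_dir Optional output directory for stage TSVs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       groups = c("M", "N", "Q"), replicates = 3L,
                       n_features = 2148L, n_flavonoids = 487L,
                       n_genes = 47598L, cv = 0.1,
                       planted_dfs = list(MvsN = c(up = 83, down = 30),
                                          NvsQ = c(up = 18, down = 30)),
                       df_shared = 17L, df_log2fc = 2,
                       planted_degs = list(MvsN = c(up = 1288, down = 627),
                                           NvsQ = c(up = 18, down = 130)),
                       deg_shared = 10L, deg_log2fc = 3,
                       ojip = list(M = list(j_step_shift = 1,
                                            k_band_amp = 0),
                                   N = list(j_step_shift = 1.4,
                                            k_band_amp = 400),
                                   Q = list(j_step_shift = 1.2,
                                            k_band_amp = 150)),
                       ojip_noise_sd = 0.02,
                       thresholds = list(vip = 1, fc_up = 1.5,
                                         fc_down = 0.67, q = 0.05,
                                         lfc = 1, r2 = 0.8, p = 0.05,
                                         q2 = 0.5),
                       contrasts = list(c("M", "N"), c("N", "Q")),
                       out_dir = NULL) {
  needed <- c("vip", "fc_up", "fc_down", "q", "lfc", "r2", "p", "q2")
  if (!all(needed %in% names(thresholds))) {
    stop("thresholds must name ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (any(unlist(thresholds) <= 0)) {
    stop("thresholds must be positive", call. = FALSE)
  }
  as_counts <- function(lst) {
    lapply(lst, function(v) stats::setNames(as.integer(v), names(v)))
  }
  planted_dfs <- as_counts(planted_dfs)
  planted_degs <- as_counts(planted_degs)
  structure(
    list(seed = as.integer(seed), groups = as.character(groups),
         replicates = as.integer(replicates),
         n_features = as.integer(n_features),
         n_flavonoids = as.integer(n_flavonoids),
         n_genes = as.integer(n_genes), cv = cv,
         planted_dfs = planted_dfs, df_shared = as.integer(df_shared),
         df_log2fc = df_log2fc,
         planted_degs = planted_degs, deg_shared = as.integer(deg_shared),
         deg_log2fc = deg_log2fc,
         ojip = ojip, ojip_noise_sd = ojip_noise_sd,
         thresholds = thresholds,
         contrasts = lapply(contrasts, as.character),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config` object.
#' @param path File path for the YAML serialization.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  raw <- unclass(config)
  # named atomic vectors lose their names in YAML; store them as maps
  raw$planted_dfs <- lapply(raw$planted_dfs, as.list)
  raw$planted_degs <- lapply(raw$planted_degs, as.list)
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$contrasts <- lapply(raw$contrasts, as.character)
  for (nm in names(raw$planted_dfs)) {
    raw$planted_dfs[[nm]] <- unlist(raw$planted_dfs[[nm]])
  }
  for (nm in names(raw$planted_degs)) {
    raw$planted_degs[[nm]] <- unlist(raw$planted_degs[[nm]])
  }
  do.call(run_config, raw)
}

# short stable fingerprint of a config (FNV-1a over its YAML text)
config_hash <- function(config) {
  s <- yaml::as.yaml(unclass(config))
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

stage_error <- function(stage, e) {
  stop(sprintf("pipeline stage '%s' failed: %s", stage,
               conditionMessage(e)), call. = FALSE)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes, in dependency order: data simulation (OJIP transients, PAM
#' records, metabolome, transcriptome, annotations), PAM group statistics,
#' JIP-test difference curves, OPLS-DA with cross-validated Q2 and VIP per
#' contrast, differential-feature screening (DFs and DEGs) with Venn
#' intersections and class tallies, pathway enrichment and mapping, and
#' DF-DEG / TF-enzyme correlation networks. All randomness derives from
#' the config seed, so a given configuration reproduces byte-identical
#' outputs. When `config$out_dir` is set, stage tables are written there
#' as TSV.
#'
#' @param config A [run_config()].
#' @return An object of class `run_report`: per-stage results, the count
#'   ledger (one row per comparison and omics layer with up/down/total),
#'   OPLS validity verdicts, planted truth tables, and a provenance block
#'   (seed, config hash, package version).
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  th <- config$thresholds
  design <- study_design(config$groups, config$replicates, config$seed)
  cmp_labels <- vapply(config$contrasts, comparison_label, "")

  ## simulate
  sim <- tryCatch({
    ojip_pars <- lapply(config$ojip, function(o) {
      ojip_params(j_step_shift = o$j_step_shift,
                  k_band_amp = o$k_band_amp,
                  noise_sd = config$ojip_noise_sd)
    })
    met <- simulate_metabolome(
      design, config$n_features, config$n_flavonoids,
      planted = planted_spec(config$planted_dfs, config$df_shared,
                             config$df_log2fc),
      cv = config$cv)
    rna <- simulate_transcriptome(
      design, config$n_genes,
      planted = planted_spec(config$planted_degs, config$deg_shared,
                             config$deg_log2fc),
      cv = config$cv)
    lfc_cols <- function(truth) {
      grep("^true_log2fc_", names(truth), value = TRUE)
    }
    planted_ids <- function(truth) {
      truth$feature_id[rowSums(abs(
        as.matrix(truth[, lfc_cols(truth), drop = FALSE]))) > 0]
    }
    ann <- simulate_annotations(
      rownames(met$matrix), rownames(rna$matrix),
      prefer_ids = c(planted_ids(met$truth), planted_ids(rna$truth)),
      seed = config$seed)
    list(traces = simulate_ojip(ojip_pars, design),
         pam = simulate_pam(design), met = met, rna = rna, ann = ann)
  }, error = function(e) stage_error("simulate", e))

  ## pam
  pam <- tryCatch({
    rec <- pam_parameters(sim$pam)
    list(records = rec,
         fv_fm = summarize_groups(rec, "fv_fm"),
         y_ii = summarize_groups(rec, "y_ii"),
         Fo = summarize_groups(rec, "Fo"))
  }, error = function(e) stage_error("pam", e))

  ## ojip
  ojip <- tryCatch({
    out <- list()
    for (ct in config$contrasts) {
      lbl <- comparison_label(ct)
      out[[lbl]] <- list(
        Vt = delta_curves(sim$traces, ct[1], ct[2], "Vt"),
        Wt = delta_curves(sim$traces, ct[1], ct[2], "Wt"))
    }
    out
  }, error = function(e) stage_error("ojip", e))

  ## opls (per contrast, metabolome)
  opls <- tryCatch({
    out <- list()
    for (ct in config$contrasts) {
      lbl <- comparison_label(ct)
      sel <- sim$met$groups$group %in% ct
      Xt <- t(sim$met$matrix[, sel, drop = FALSE])
      yv <- sim$met$groups$group[sel]
      model <- fit_opls(Xt, yv)
      q2 <- cross_validated_q2(Xt, yv, seed = config$seed)
      out[[lbl]] <- list(model = model, q2 = q2,
                         validity = validate_model(q2, th$q2))
    }
    out
  }, error = function(e) stage_error("opls", e))

  ## screen
  screens <- tryCatch({
    dfs <- list(); degs <- list(); tallies <- list()
    for (ct in config$contrasts) {
      lbl <- comparison_label(ct)
      dfs[[lbl]] <- screen_dfs(
        sim$met$matrix, sim$met$groups, ct,
        vip = compute_vip(opls[[lbl]]$model),
        vip_threshold = th$vip, fc_up = th$fc_up, fc_down = th$fc_down,
        class_table = sim$met$truth)
      degs[[lbl]] <- screen_degs(
        sim$rna$matrix, sim$rna$groups, ct,
        q_threshold = th$q, lfc_threshold = th$lfc)
      tallies[[lbl]] <- tally_by_class(dfs[[lbl]])
    }
    vn <- list(
      dfs = venn(dfs[[cmp_labels[1]]]$feature_id,
                 dfs[[cmp_labels[2]]]$feature_id),
      degs = venn(degs[[cmp_labels[1]]]$feature_id,
                  degs[[cmp_labels[2]]]$feature_id))
    list(dfs = dfs, degs = degs, tallies = tallies, venn = vn)
  }, error = function(e) stage_error("screen", e))

  ## enrich
  enrich <- tryCatch({
    res <- list()
    for (lbl in cmp_labels) {
      res[[lbl]] <- hypergeom_enrich(
        screens$dfs[[lbl]]$feature_id,
        sim$ann$pathways[sim$ann$pathways$id %in% rownames(sim$met$matrix), ],
        rownames(sim$met$matrix))
    }
    maps <- list()
    for (lbl in cmp_labels) {
      maps[[lbl]] <- map_to_pathways(screens$dfs[[lbl]]$feature_id,
                                     screens$degs[[lbl]]$feature_id,
                                     sim$ann$pathways)
    }
    list(dfs = res, pathway_map = maps)
  }, error = function(e) stage_error("enrich", e))

  ## network (flavonoid-pathway hits only, as in a targeted integration)
  network <- tryCatch({
    flav_path <- sim$ann$pathways[sim$ann$pathways$pathway_id %in%
                                    c("ko00941", "ko00944"), "id"]
    df_ids <- intersect(unique(unlist(lapply(screens$dfs,
                                             `[[`, "feature_id"))),
                        flav_path)
    deg_ids <- intersect(unique(unlist(lapply(screens$degs,
                                              `[[`, "feature_id"))),
                         flav_path)
    edges <- if (length(df_ids) && length(deg_ids)) {
      correlation_network(sim$met$matrix[df_ids, , drop = FALSE],
                          sim$rna$matrix[deg_ids, , drop = FALSE],
                          threshold_r2 = th$r2, threshold_p = th$p)
    } else empty_edges()
    # differential TF genes against pathway enzyme genes
    tf_deg <- intersect(sim$ann$tf$gene_id,
                        unique(unlist(lapply(screens$degs,
                                             `[[`, "feature_id"))))
    chords <- if (length(tf_deg) && length(deg_ids)) {
      tfm <- sim$rna$matrix[tf_deg, , drop = FALSE]
      rownames(tfm) <- paste0(
        sim$ann$tf$tf_family[match(tf_deg, sim$ann$tf$gene_id)], ":", tf_deg)
      tf_enzyme_chords(tfm, sim$rna$matrix[deg_ids, , drop = FALSE],
                       threshold_r2 = th$r2, threshold_p = th$p)
    } else empty_edges()
    list(df_deg = edges, tf_enzyme = chords,
         nodes = node_summary(edges))
  }, error = function(e) stage_error("network", e))

  ## ledger
  ledger <- do.call(rbind, lapply(cmp_labels, function(lbl) {
    rbind(
      data.frame(comparison = lbl, layer = "DF",
                 up = sum(screens$dfs[[lbl]]$direction == "up"),
                 down = sum(screens$dfs[[lbl]]$direction == "down"),
                 total = nrow(screens$dfs[[lbl]]),
                 stringsAsFactors = FALSE),
      data.frame(comparison = lbl, layer = "DEG",
                 up = sum(screens$degs[[lbl]]$direction == "up"),
                 down = sum(screens$degs[[lbl]]$direction == "down"),
                 total = nrow(screens$degs[[lbl]]),
                 stringsAsFactors = FALSE))
  }))

  report <- structure(
    list(config = config,
         provenance = list(seed = config$seed,
                           config_hash = config_hash(config),
                           package_version =
                             as.character(utils::packageVersion("flavomix")),
                           r_version = R.version.string),
         pam = pam, ojip = ojip, opls = opls, screens = screens,
         enrich = enrich, network = network,
         truth = list(metabolome = sim$met$truth,
                      transcriptome = sim$rna$truth),
         ledger = ledger),
    class = "run_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed", x$provenance$seed, ", config",
      x$provenance$config_hash, ")\n\nCount ledger:\n")
  print(x$ledger)
  for (lbl in names(x$opls)) {
    v <- x$opls[[lbl]]$validity
    cat(sprintf("OPLS-DA %s: Q2 = %.3f (%s)\n", lbl, v$q2,
                if (v$valid) "valid" else "not valid"))
  }
  invisible(x)
}

#' Write the stage tables of a run report as TSV
#'
#' @param report A [run_all()] report.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in c("fv_fm", "y_ii", "Fo")) {
    write_tsv(report$pam[[p]], file.path(dir, paste0("pam_", p, ".tsv")))
  }
  for (lbl in names(report$ojip)) {
    for (kind in c("Vt", "Wt")) {
      d <- report$ojip[[lbl]][[kind]]
      write_tsv(data.frame(time_s = d$time_s, value = d$value),
                file.path(dir, sprintf("delta_%s_%s.tsv", kind, lbl)))
    }
  }
  opls_tab <- do.call(rbind, lapply(names(report$opls), function(lbl) {
    o <- report$opls[[lbl]]
    data.frame(comparison = lbl, R2Y = o$model$R2Y, Q2 = o$q2,
               valid = o$validity$valid, stringsAsFactors = FALSE)
  }))
  write_tsv(opls_tab, file.path(dir, "opls_summary.tsv"))
  for (lbl in names(report$screens$dfs)) {
    write_tsv(report$screens$dfs[[lbl]],
              file.path(dir, paste0("df_hits_", lbl, ".tsv")))
    write_tsv(report$screens$degs[[lbl]],
              file.path(dir, paste0("deg_hits_", lbl, ".tsv")))
    write_tsv(report$screens$tallies[[lbl]],
              file.path(dir, paste0("df_tally_", lbl, ".tsv")))
    write_tsv(report$enrich$dfs[[lbl]],
              file.path(dir, paste0("enrichment_", lbl, ".tsv")))
  }
  write_tsv(report$network$df_deg, file.path(dir, "network_df_deg.tsv"))
  write_tsv(report$network$tf_enzyme,
            file.path(dir, "network_tf_enzyme.tsv"))
  write_tsv(report$ledger, file.path(dir, "report_ledger.tsv"))
  invisible(dir)
}

#' Verify the count arithmetic of a run report
#'
#' Checks that every ledger row satisfies up + down = total, that Venn
#' counts do not exceed the originating set sizes, and that class tallies
#' sum to the hit counts. Accepts either a full [run_all()] report or a
#' plain ledger data frame (`up`, `down`, `total`), e.g. printed splits
#' from a publication.
#'
#' @param report A `run_report` or a ledger data frame.
#' @return A list `pass` (logical) and `violations` (data frame of failed
#'   checks, empty when all pass).
#' @examples
#' ledger_check(data.frame(up = 83, down = 30, total = 113))$pass  # TRUE
#' @export
ledger_check <- function(report) {
  violations <- data.frame(check = character(0), detail = character(0),
                           stringsAsFactors = FALSE)
  add <- function(check, detail) {
    violations <<- rbind(violations,
                         data.frame(check = check, detail = detail,
                                    stringsAsFactors = FALSE))
  }
  ledger <- if (inherits(report, "run_report")) report$ledger else report
  if (!all(c("up", "down", "total") %in% names(ledger))) {
    stop("ledger needs columns up, down, total", call. = FALSE)
  }
  bad <- which(ledger$up + ledger$down != ledger$total)
  for (i in bad) {
    add("up+down=total",
        sprintf("row %d: %d + %d != %d", i, ledger$up[i], ledger$down[i],
                ledger$total[i]))
  }
  if (inherits(report, "run_report")) {
    for (layer in c("dfs", "degs")) {
      vn <- report$screens$venn[[layer]]
      sizes <- vapply(report$screens[[layer]],
                      function(h) length(unique(h$feature_id)), 1L)
      if (vn$n_shared > min(sizes)) {
        add("venn<=set", sprintf("%s: shared %d > min set %d", layer,
                                 vn$n_shared, min(sizes)))
      }
    }
    for (lbl in names(report$screens$tallies)) {
      tt <- report$screens$tallies[[lbl]]
      if (sum(tt$total) != nrow(report$screens$dfs[[lbl]])) {
        add("tally=hits", sprintf("%s: tally %d != hits %d", lbl,
                                  sum(tt$total),
                                  nrow(report$screens$dfs[[lbl]])))
      }
    }
  }
  list(pass = nrow(violations) == 0L, violations = violations)
}
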