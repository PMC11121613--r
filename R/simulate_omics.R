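#' Specify planted differential effects
#'
#' Describes which features carry true group contrasts in the simulated
#' omics matrices. Effects are expressed per comparison (`"AvsB"` means the
#' fold change of group B over group A) as counts of up- and down-regulated
#' features at a common absolute log2 fold change. When two comparisons are
#' given, `n_shared` features are planted as up in the first comparison and
#' down in the second — the pattern of metabolites that rise under a stress
#' and fall again under a mitigating treatment.
#'
#' @param contrasts Named list; names are comparisons like `"MvsN"`, values
#'   are vectors `c(up = , down = )` of planted feature counts.
#' @param n_shared Number of features shared between the first comparison's
#'   up set and the second comparison's down set (0 if fewer than two
#'   comparisons).
#' @param log2fc Absolute true log2 fold change planted per effect.
#' @return An object of class `planted_spec`.
#' @examples
#' planted_spec(list(MvsN = c(up = 83, down = 30),
#'                   NvsQ = c(up = 18, down = 30)), n_shared = 17)
#' @export
planted_spec <- function(contrasts, n_shared = 0L, log2fc = 2) {
  stopifnot(is.list(contrasts), length(contrasts) >= 1L)
  if (is.null(names(contrasts)) || any(names(contrasts) == "")) {
    stop("contrasts must be a named list (names like 'MvsN')", call. = FALSE)
  }
  for (nm in names(contrasts)) {
    v <- contrasts[[nm]]
    if (!all(c("up", "down") %in% names(v)) || any(v < 0)) {
      stop("each contrast needs nonnegative 'up' and 'down' counts",
           call. = FALSE)
    }
    if (length(strsplit(nm, "vs")[[1]]) != 2L) {
      stop("comparison names must have the form 'AvsB'", call. = FALSE)
    }
  }
  n_shared <- as.integer(n_shared)
  if (n_shared > 0 && length(contrasts) < 2L) {
    stop("n_shared requires at least two contrasts", call. = FALSE)
  }
  if (n_shared > 0) {
    if (n_shared > contrasts[[1]]["up"] || n_shared > contrasts[[2]]["down"]) {
      stop("n_shared exceeds the relevant up/down counts", call. = FALSE)
    }
  }
  structure(list(contrasts = contrasts, n_shared = n_shared,
                 log2fc = log2fc),
            class = "planted_spec")
}

# Expand a planted_spec into a per-feature truth table over the eligible
# feature ids. Returns a data.frame feature_id + one true_log2fc_<cmp>
# column per comparison (0 where no effect is planted).
expand_planted <- function(planted, eligible_ids) {
  cmps <- names(planted$contrasts)
  truth <- data.frame(feature_id = eligible_ids, stringsAsFactors = FALSE)
  for (cmp in cmps) truth[[paste0("true_log2fc_", cmp)]] <- 0
  cursor <- 1L
  take <- function(n) {
    if (n == 0L) return(integer(0))
    if (cursor + n - 1L > length(eligible_ids)) {
      stop("not enough eligible features for the planted spec", call. = FALSE)
    }
    idx <- cursor:(cursor + n - 1L)
    cursor <<- cursor + n
    idx
  }
  c1 <- planted$contrasts[[1]]
  up1 <- take(c1["up"])
  down1 <- take(c1["down"])
  truth[[paste0("true_log2fc_", cmps[1])]][up1] <- planted$log2fc
  truth[[paste0("true_log2fc_", cmps[1])]][down1] <- -planted$log2fc
  if (length(cmps) >= 2L) {
    c2 <- planted$contrasts[[2]]
    shared <- utils::head(up1, planted$n_shared)
    down2 <- c(shared, take(c2["down"] - planted$n_shared))
    up2 <- take(c2["up"])
    truth[[paste0("true_log2fc_", cmps[2])]][down2] <- -planted$log2fc
    truth[[paste0("true_log2fc_", cmps[2])]][up2] <- planted$log2fc
  }
  truth
}

# Turn per-comparison true log2 fold changes into per-group mean multipliers.
# Comparisons chain through the design groups ("MvsN" then "NvsQ" gives Q a
# multiplier 2^(lfc_MvsN + lfc_NvsQ)).
group_multipliers <- function(truth, groups) {
  mult <- matrix(1, nrow(truth), length(groups),
                 dimnames = list(truth$feature_id, groups))
  lfc_cols <- grep("^true_log2fc_", names(truth), value = TRUE)
  for (col in lfc_cols) {
    cmp <- sub("^true_log2fc_", "", col)
    ab <- strsplit(cmp, "vs")[[1]]
    if (!all(ab %in% groups)) next
    # the effect applies to the second group of the comparison and to every
    # group downstream of it in design order (so chained contrasts compose)
    j <- match(ab[2], groups)
    downstream <- groups[seq(j, length(groups))]
    mult[, downstream] <- mult[, downstream] * 2^truth[[col]]
  }
  mult
}

default_flavonoid_proportions <- function() {
  c(flavones = 0.41, flavonols = 0.29, flavanones = 0.09,
    chalcones = 0.05, flavanols = 0.05, anthocyanidins = 0.04,
    isoflavones = 0.03, dihydroflavonols = 0.02)
}

# Integer class counts from proportions, remainder labelled "other
# flavonoids"; counts always sum exactly to n.
class_counts <- function(proportions, n) {
  if (any(proportions < 0) || sum(proportions) > 1 + 1e-9) {
    stop("class proportions must be nonnegative and sum to at most 1",
         call. = FALSE)
  }
  counts <- floor(proportions * n)
  rest <- n - sum(counts)
  c(counts, `other flavonoids` = as.integer(rest))
}

#' Simulate a widely-targeted metabolome intensity matrix
#'
#' Generates a features-by-samples intensity matrix on a log-normal
#' baseline, with a flavonoid subset carrying subclass labels and optional
#' planted group contrasts. Planted features have their per-group means
#' scaled by `2^log2fc`; replicate noise is multiplicative lognormal so all
#' intensities stay positive. Planted effects are assigned to flavonoid
#' features (the screening target of the pipeline).
#'
#' @param design A [study_design()].
#' @param n_features Total number of metabolite features (default 2148).
#' @param n_flavonoids Number of features labelled with a flavonoid
#'   subclass (default 487).
#' @param class_proportions Named proportions of flavonoid subclasses
#'   (among the flavonoids); any remainder is labelled "other flavonoids".
#'   Defaults put flavones at 41%, flavonols at 29% and flavanones at 9%.
#' @param planted A [planted_spec()] or `NULL` for no planted effects.
#' @param cv Replicate coefficient of variation (lognormal sdlog); 0 gives
#'   noise-free group means.
#' @param baseline_meanlog,baseline_sdlog Log-scale location and spread of
#'   per-feature baseline intensities.
#'
#' @return A list with `matrix` (features x samples), `groups` (the sample
#'   table), and `truth` (feature_id, class, one `true_log2fc_<cmp>` column
#'   per planted comparison).
#' @examples
#' sim <- simulate_metabolome(study_design(), n_features = 50,
#'                            n_flavonoids = 12)
#' table(sim$truth$class != "non-flavonoid")
#' @export
simulate_metabolome <- function(design, n_features = 2148L,
                                n_flavonoids = 487L,
                                class_proportions =
                                  default_flavonoid_proportions(),
                                planted = NULL, cv = 0.1,
                                baseline_meanlog = 13,
                                baseline_sdlog = 1) {
  stopifnot(inherits(design, "study_design"))
  n_features <- as.integer(n_features)
  n_flavonoids <- as.integer(n_flavonoids)
  if (n_flavonoids > n_features) {
    stop("n_flavonoids cannot exceed n_features", call. = FALSE)
  }
  ids <- sprintf("met_%04d", seq_len(n_features))
  counts <- class_counts(class_proportions, n_flavonoids)
  classes <- c(rep(names(counts), counts),
               rep("non-flavonoid", n_features - n_flavonoids))
  truth <- data.frame(feature_id = ids, class = classes,
                      stringsAsFactors = FALSE)
  if (!is.null(planted)) {
    stopifnot(inherits(planted, "planted_spec"))
    flav_ids <- ids[classes != "non-flavonoid"]
    # spread planted effects across the flavonoid subclasses rather than
    # concentrating them in the first (largest) one
    set.seed(child_seed(design$seed, "planting"))
    flav_ids <- sample(flav_ids)
    pt <- expand_planted(planted, flav_ids)
    truth <- merge(truth, pt, by = "feature_id", all.x = TRUE, sort = FALSE)
    truth <- truth[match(ids, truth$feature_id), ]
    lfc_cols <- grep("^true_log2fc_", names(truth), value = TRUE)
    for (col in lfc_cols) truth[[col]][is.na(truth[[col]])] <- 0
  }
  set.seed(child_seed(design$seed, "metabolome"))
  baseline <- stats::rlnorm(n_features, baseline_meanlog, baseline_sdlog)
  mult <- group_multipliers(truth, design$groups)
  samp <- design$samples
  mat <- matrix(0, n_features, nrow(samp),
                dimnames = list(ids, samp$sample_id))
  for (j in seq_len(nrow(samp))) {
    mu <- baseline * mult[, samp$group[j]]
    noise <- if (cv > 0) exp(stats::rnorm(n_features, 0, cv)) else 1
    mat[, j] <- mu * noise
  }
  rownames(truth) <- NULL
  list(matrix = mat, groups = samp, truth = truth)
}

#' Simulate a transcriptome FPKM matrix
#'
#' Same generative scheme as [simulate_metabolome()] but on an FPKM scale
#' (log-normal baseline around tens of FPKM) and with planted effects drawn
#' over all genes. Useful defaults emulate a de novo assembly of a
#' non-model plant (tens of thousands of unigenes).
#'
#' @param design A [study_design()].
#' @param n_genes Number of genes (default 47598).
#' @param planted A [planted_spec()] or `NULL`.
#' @param cv Replicate coefficient of variation (lognormal sdlog).
#' @param baseline_meanlog,baseline_sdlog Baseline FPKM log-scale location
#'   and spread.
#' @return A list with `matrix` (genes x samples, FPKM), `groups`, and
#'   `truth` (gene ids in `feature_id`).
#' @export
simulate_transcriptome <- function(design, n_genes = 47598L,
                                   planted = NULL, cv = 0.1,
                                   baseline_meanlog = 3,
                                   baseline_sdlog = 1.2) {
  stopifnot(inherits(design, "study_design"))
  n_genes <- as.integer(n_genes)
  ids <- sprintf("gene_%05d", seq_len(n_genes))
  truth <- data.frame(feature_id = ids, stringsAsFactors = FALSE)
  if (!is.null(planted)) {
    stopifnot(inherits(planted, "planted_spec"))
    pt <- expand_planted(planted, ids)
    truth <- pt
  }
  set.seed(child_seed(design$seed, "transcriptome"))
  baseline <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
  mult <- group_multipliers(truth, design$groups)
  samp <- design$samples
  mat <- matrix(0, n_genes, nrow(samp),
                dimnames = list(ids, samp$sample_id))
  for (j in seq_len(nrow(samp))) {
    mu <- baseline * mult[, samp$group[j]]
    noise <- if (cv > 0) exp(stats::rnorm(n_genes, 0, cv)) else 1
    mat[, j] <- mu * noise
  }
  rownames(truth) <- NULL
  list(matrix = mat, groups = samp, truth = truth)
}

default_tf_family_sizes <- function() {
  c(MYB = 154, `AP2-EREBP` = 93, mTERF = 89, bHLH = 82, C3H = 75,
    NAC = 70, WRKY = 64, bZIP = 58, GRAS = 52, ARF = 47)
}

default_pathway_spec <- function() {
  list(
    ko00941 = list(name = "Flavonoid biosynthesis",
                   n_metabolites = 40, n_genes = 30),
    ko00944 = list(name = "Flavone and flavonol biosynthesis",
                   n_metabolites = 25, n_genes = 10),
    ko00940 = list(name = "Phenylpropanoid biosynthesis",
                   n_metabolites = 30, n_genes = 60),
    ko00480 = list(name = "Glutathione metabolism",
                   n_metabolites = 20, n_genes = 40)
  )
}

#' Simulate annotation tables (TF families and pathway membership)
#'
#' Assigns transcription-factor family labels to a subset of genes (each
#' gene at most one family) and KEGG-style pathway memberships to
#' metabolites and genes. `prefer_ids` lets callers steer chosen ids (for
#' example, planted differential features) into the flavonoid pathways so
#' that downstream enrichment has a known signal.
#'
#' @param metabolite_ids,gene_ids Character vectors of feature/gene ids
#'   present in the simulated matrices.
#' @param tf_family_sizes Named integer vector of family sizes. The default
#'   puts MYB at 154 members, followed by AP2-EREBP (93), mTERF (89),
#'   bHLH (82) and C3H (75).
#' @param pathway_spec Named list keyed by pathway id, each entry a list
#'   with `name`, `n_metabolites`, `n_genes`.
#' @param prefer_ids Ids to place preferentially into `ko00941`/`ko00944`.
#' @param seed Integer seed for the membership draws.
#'
#' @return A list with `tf` (`gene_id`, `tf_family`) and `pathways`
#'   (`id`, `pathway_id`, `pathway_name`).
#' @export
simulate_annotations <- function(metabolite_ids, gene_ids,
                                 tf_family_sizes = default_tf_family_sizes(),
                                 pathway_spec = default_pathway_spec(),
                                 prefer_ids = character(0),
                                 seed = 1L) {
  if (sum(tf_family_sizes) > length(gene_ids)) {
    stop("TF family sizes exceed the number of genes", call. = FALSE)
  }
  if (length(pathway_spec) == 0L) {
    stop("pathway_spec must not be empty", call. = FALSE)
  }
  set.seed(child_seed(seed, "annotations"))
  tf_genes <- sample(gene_ids, sum(tf_family_sizes))
  tf <- data.frame(gene_id = tf_genes,
                   tf_family = rep(names(tf_family_sizes), tf_family_sizes),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(tf$gene_id) > 0L) {
    stop("duplicate gene-to-family assignment", call. = FALSE)
  }
  used_prefer <- character(0)
  pick <- function(pool, prefer, n) {
    n <- min(n, length(pool))
    pref <- setdiff(intersect(prefer, pool), used_prefer)
    chosen <- utils::head(pref, n)
    used_prefer <<- c(used_prefer, chosen)
    if (length(chosen) < n) {
      rest <- setdiff(pool, chosen)
      chosen <- c(chosen, sample(rest, n - length(chosen)))
    }
    chosen
  }
  rows <- list()
  for (pid in names(pathway_spec)) {
    ps <- pathway_spec[[pid]]
    prefer <- if (pid %in% c("ko00941", "ko00944")) prefer_ids else character(0)
    mem_m <- pick(metabolite_ids, prefer, ps$n_metabolites)
    mem_g <- pick(gene_ids, prefer, ps$n_genes)
    rows[[pid]] <- data.frame(id = c(mem_m, mem_g), pathway_id = pid,
                              pathway_name = ps$name,
                              stringsAsFactors = FALSE)
  }
  pathways <- do.call(rbind, rows)
  rownames(pathways) <- NULL
  list(tf = tf, pathways = pathways)
}
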