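#' Per-feature fold change between two groups
#'
#' Linear-scale fold change of group means for a comparison `"AvsB"`:
#' FC = mean(B)/mean(A), with log2FC = log2(FC). Features whose denominator
#' group mean is zero are flagged (`NA` fold change) and excluded by the
#' screening functions with a warning.
#'
#' @param mat Features-by-samples numeric matrix.
#' @param groups Sample table (`sample_id`, `group`) or a group vector
#'   aligned with the matrix columns.
#' @param contrast Length-2 character vector `c(A, B)`; the fold change is
#'   B over A.
#' @return Data frame `feature_id`, `mean_a`, `mean_b`, `fc`, `log2fc`.
#' @examples
#' m <- rbind(g1 = c(10, 10, 20, 20))
#' colnames(m) <- c("s1", "s2", "s3", "s4")
#' fold_change(m, c("A", "A", "B", "B"), c("A", "B"))
#' @export
fold_change <- function(mat, groups, contrast) {
  mat <- as.matrix(mat)
  g <- if (is.data.frame(groups)) groups$group else as.character(groups)
  if (length(g) != ncol(mat)) {
    stop("groups must align with matrix columns", call. = FALSE)
  }
  if (length(contrast) != 2L || !all(contrast %in% g)) {
    stop("contrast must name two groups present in the data", call. = FALSE)
  }
  mean_a <- rowMeans(mat[, g == contrast[1], drop = FALSE])
  mean_b <- rowMeans(mat[, g == contrast[2], drop = FALSE])
  fc <- ifelse(mean_a > 0, mean_b / mean_a, NA_real_)
  data.frame(feature_id = rownames(mat), mean_a = mean_a, mean_b = mean_b,
             fc = fc, log2fc = log2(fc), stringsAsFactors = FALSE,
             row.names = NULL)
}

comparison_label <- function(contrast) paste0(contrast[1], "vs", contrast[2])

#' Screen differential metabolites by VIP and fold change
#'
#' A feature is selected when VIP > `vip_threshold` (strict) and its
#' linear-scale fold change satisfies FC >= `fc_up` or FC <= `fc_down`
#' (inclusive). The VIP vector should come from a valid
#' (Q2 > 0.5) OPLS-DA model fitted on the same contrast.
#'
#' @param mat Intensity matrix (features x samples).
#' @param groups Sample table or group vector.
#' @param contrast `c(control, treatment)`; FC is treatment over control.
#' @param vip Named VIP vector covering the matrix features (names are
#'   matched; features absent from `vip` are not selectable).
#' @param vip_threshold,fc_up,fc_down Selection thresholds (defaults 1,
#'   1.5, 0.67).
#' @param class_table Optional annotation data frame (`feature_id`,
#'   `class`) used to label hits.
#' @return Data frame of hits: `feature_id`, `comparison`, `fc`, `log2fc`,
#'   `direction` (`"up"` iff FC > 1), `evidence` (the VIP), `class`.
#' @export
screen_dfs <- function(mat, groups, contrast, vip, vip_threshold = 1,
                       fc_up = 1.5, fc_down = 0.67, class_table = NULL) {
  fcs <- fold_change(mat, groups, contrast)
  if (anyNA(fcs$fc)) {
    warning(sum(is.na(fcs$fc)),
            " feature(s) with zero denominator group mean excluded")
  }
  v <- vip[match(fcs$feature_id, names(vip))]
  sel <- !is.na(fcs$fc) & !is.na(v) & v > vip_threshold &
    (fcs$fc >= fc_up | fcs$fc <= fc_down)
  hits <- data.frame(
    feature_id = fcs$feature_id[sel],
    comparison = rep(comparison_label(contrast), sum(sel)),
    fc = fcs$fc[sel],
    log2fc = fcs$log2fc[sel],
    direction = ifelse(fcs$fc[sel] > 1, "up", "down"),
    evidence = unname(v[sel]),
    stringsAsFactors = FALSE
  )
  hits$class <- if (!is.null(class_table)) {
    class_table$class[match(hits$feature_id, class_table$feature_id)]
  } else NA_character_
  hits
}

# vectorized per-row Welch t-test of two groups on a matrix
welch_rows <- function(mat, idx_a, idx_b) {
  na <- length(idx_a); nb <- length(idx_b)
  ma <- rowMeans(mat[, idx_a, drop = FALSE])
  mb <- rowMeans(mat[, idx_b, drop = FALSE])
  va <- apply(mat[, idx_a, drop = FALSE], 1, stats::var)
  vb <- apply(mat[, idx_b, drop = FALSE], 1, stats::var)
  se2 <- va / na + vb / nb
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  data.frame(t = tstat, df = df, p_value = p)
}

#' Screen differentially expressed genes
#'
#' Per-gene two-sided Welch t-test on log2(FPKM + 1) between the two
#' contrast groups, Benjamini-Hochberg adjustment across genes, and
#' selection by q-value and fold-change rule. The default fold-change rule
#' requires |log2FC| >= `lfc_threshold` (with direction by sign);
#' `fc_rule = "literal"` instead keeps any gene with FC != 1, the literal
#' reading of "FC > 1" with direction by sign of the change.
#'
#' @param fpkm FPKM matrix (genes x samples), nonnegative.
#' @param groups Sample table or group vector.
#' @param contrast `c(control, treatment)`; FC is treatment over control.
#' @param q_threshold BH-adjusted p-value cutoff (default 0.05).
#' @param fc_rule `"abs_log2fc"` (default) or `"literal"`.
#' @param lfc_threshold Minimum |log2FC| under the default rule.
#' @return Data frame of hits with `feature_id`, `comparison`, `fc`,
#'   `log2fc`, `direction`, `evidence` (the q-value), `p_value`.
#' @export
screen_degs <- function(fpkm, groups, contrast, q_threshold = 0.05,
                        fc_rule = c("abs_log2fc", "literal"),
                        lfc_threshold = 1) {
  fc_rule <- match.arg(fc_rule)
  fpkm <- as.matrix(fpkm)
  if (any(fpkm < 0)) stop("FPKM values must be nonnegative", call. = FALSE)
  g <- if (is.data.frame(groups)) groups$group else as.character(groups)
  idx_a <- which(g == contrast[1]); idx_b <- which(g == contrast[2])
  if (length(idx_a) < 2L || length(idx_b) < 2L) {
    stop("each contrast group needs at least two replicates", call. = FALSE)
  }
  lmat <- log2(fpkm + 1)
  # genes with zero variance in both groups carry no testable signal
  va <- apply(lmat[, idx_a, drop = FALSE], 1, stats::var)
  vb <- apply(lmat[, idx_b, drop = FALSE], 1, stats::var)
  testable <- (va + vb) > 0
  if (any(!testable)) {
    warning(sum(!testable), " gene(s) with zero variance skipped")
  }
  wt <- welch_rows(lmat[testable, , drop = FALSE], idx_a, idx_b)
  q <- stats::p.adjust(wt$p_value, method = "BH")
  fcs <- fold_change(fpkm[testable, , drop = FALSE], g, contrast)
  pass_fc <- switch(fc_rule,
                    abs_log2fc = abs(fcs$log2fc) >= lfc_threshold,
                    literal = fcs$fc != 1)
  sel <- !is.na(fcs$fc) & !is.na(q) & q < q_threshold & pass_fc
  data.frame(
    feature_id = fcs$feature_id[sel],
    comparison = rep(comparison_label(contrast), sum(sel)),
    fc = fcs$fc[sel],
    log2fc = fcs$log2fc[sel],
    direction = ifelse(fcs$log2fc[sel] > 0, "up", "down"),
    evidence = q[sel],
    p_value = wt$p_value[sel],
    stringsAsFactors = FALSE
  )
}

#' Two-set Venn partition
#'
#' Shared and unique memberships of two id sets (the "Wayne diagram"
#' counts of differential-feature comparisons).
#'
#' @param set_a,set_b Character vectors of ids (duplicates ignored).
#' @return A list with `n_shared`, `n_only_a`, `n_only_b`, and the
#'   corresponding membership vectors `shared`, `only_a`, `only_b`.
#' @examples
#' venn(c("a", "b", "c"), c("b", "c", "d"))$n_shared   # 2
#' @export
venn <- function(set_a, set_b) {
  set_a <- unique(as.character(set_a)); set_b <- unique(as.character(set_b))
  shared <- intersect(set_a, set_b)
  list(n_shared = length(shared),
       n_only_a = length(setdiff(set_a, set_b)),
       n_only_b = length(setdiff(set_b, set_a)),
       shared = shared,
       only_a = setdiff(set_a, set_b),
       only_b = setdiff(set_b, set_a))
}

#' Tally screening hits by class and direction
#'
#' Contingency table of hit classes (flavonoid subclass, TF family, ...)
#' against direction of change. Hits without an annotation are counted
#' under `"other"`.
#'
#' @param hits Hit table from [screen_dfs()] or [screen_degs()].
#' @param class_table Optional (`feature_id`, `class`) annotation; if
#'   omitted the hits' own `class` column is used.
#' @return Data frame `class`, `up`, `down`, `total`.
#' @export
tally_by_class <- function(hits, class_table = NULL) {
  if (nrow(hits) == 0L) {
    return(data.frame(class = character(0), up = integer(0),
                      down = integer(0), total = integer(0)))
  }
  cls <- if (!is.null(class_table)) {
    class_table$class[match(hits$feature_id, class_table$feature_id)]
  } else if ("class" %in% names(hits)) hits$class else NA_character_
  cls[is.na(cls)] <- "other"
  tab <- table(class = cls,
               direction = factor(hits$direction, levels = c("up", "down")))
  out <- data.frame(class = rownames(tab),
                    up = as.integer(tab[, "up"]),
                    down = as.integer(tab[, "down"]),
                    stringsAsFactors = FALSE)
  out$total <- out$up + out$down
  rownames(out) <- NULL
  out
}
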