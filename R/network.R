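#' Signed Pearson correlation network between two feature sets
#'
#' Tests every cross pair of profiles from two matrices sharing the same
#' ordered samples. Pearson r is computed per pair; the two-sided p-value
#' comes from the exact t transform t = r * sqrt((n-2)/(1-r^2)) with n-2
#' degrees of freedom. An edge is kept iff r^2 >= `threshold_r2` and
#' p < `threshold_p` (defaults reproduce the common r^2 >= 0.8, p < 0.05
#' rule, i.e. |r| >= 0.894). Constant profiles are skipped with a warning.
#' No multiple-testing correction is applied across edges.
#'
#' @param matrix_a,matrix_b Features-by-samples matrices with identical
#'   sample columns (same order; checked by name when present).
#' @param threshold_r2 Minimum squared correlation (default 0.8).
#' @param threshold_p Maximum two-sided p-value (default 0.05).
#' @param role_a,role_b Node role labels for the edge table (e.g. "DF",
#'   "DEG", "TF", "enzyme").
#' @return Edge data frame: `node_a`, `role_a`, `node_b`, `role_b`, `r`,
#'   `r2`, `p`, `sign` (`"positive"` iff r > 0).
#' @examples
#' a <- rbind(m1 = 1:9); b <- rbind(g1 = 2 * (1:9) + 1)
#' correlation_network(a, b)$sign   # "positive"
#' @export
correlation_network <- function(matrix_a, matrix_b, threshold_r2 = 0.8,
                                threshold_p = 0.05,
                                role_a = "DF", role_b = "DEG") {
  matrix_a <- as.matrix(matrix_a); matrix_b <- as.matrix(matrix_b)
  if (ncol(matrix_a) != ncol(matrix_b)) {
    stop("matrices must share the same samples", call. = FALSE)
  }
  if (!is.null(colnames(matrix_a)) && !is.null(colnames(matrix_b)) &&
      !identical(colnames(matrix_a), colnames(matrix_b))) {
    stop("sample columns must match in the same order", call. = FALSE)
  }
  n <- ncol(matrix_a)
  if (n < 3L) stop("need at least 3 shared samples", call. = FALSE)
  if (is.null(rownames(matrix_a))) {
    rownames(matrix_a) <- paste0("a_", seq_len(nrow(matrix_a)))
  }
  if (is.null(rownames(matrix_b))) {
    rownames(matrix_b) <- paste0("b_", seq_len(nrow(matrix_b)))
  }
  const_a <- apply(matrix_a, 1, stats::sd) == 0
  const_b <- apply(matrix_b, 1, stats::sd) == 0
  if (any(const_a) || any(const_b)) {
    warning(sum(const_a) + sum(const_b),
            " constant profile(s) skipped in correlation network")
    matrix_a <- matrix_a[!const_a, , drop = FALSE]
    matrix_b <- matrix_b[!const_b, , drop = FALSE]
  }
  if (nrow(matrix_a) == 0L || nrow(matrix_b) == 0L) {
    return(empty_edges())
  }
  r <- stats::cor(t(matrix_a), t(matrix_b))
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  p[r^2 >= 1] <- 0  # perfectly collinear profiles
  keep <- which(r^2 >= threshold_r2 & p < threshold_p, arr.ind = TRUE)
  if (nrow(keep) == 0L) return(empty_edges())
  out <- data.frame(
    node_a = rownames(matrix_a)[keep[, 1]], role_a = role_a,
    node_b = rownames(matrix_b)[keep[, 2]], role_b = role_b,
    r = r[keep], r2 = r[keep]^2, p = p[keep],
    sign = ifelse(r[keep] > 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$node_a, out$node_b), ]
  rownames(out) <- NULL
  out
}

empty_edges <- function() {
  data.frame(node_a = character(0), role_a = character(0),
             node_b = character(0), role_b = character(0),
             r = numeric(0), r2 = numeric(0), p = numeric(0),
             sign = character(0), stringsAsFactors = FALSE)
}

#' Per-node degree summary of a correlation network
#'
#' @param edges Edge table from [correlation_network()].
#' @return Data frame `node`, `role`, `degree`, `positive`, `negative`,
#'   sorted by decreasing degree.
#' @export
node_summary <- function(edges) {
  if (nrow(edges) == 0L) {
    return(data.frame(node = character(0), role = character(0),
                      degree = integer(0), positive = integer(0),
                      negative = integer(0)))
  }
  nodes <- data.frame(node = c(edges$node_a, edges$node_b),
                      role = c(edges$role_a, edges$role_b),
                      sign = rep(edges$sign, 2),
                      stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(nodes, nodes$node), function(d) {
    data.frame(node = d$node[1], role = d$role[1],
               degree = nrow(d),
               positive = sum(d$sign == "positive"),
               negative = sum(d$sign == "negative"),
               stringsAsFactors = FALSE)
  }))
  agg <- agg[order(-agg$degree, agg$node), ]
  rownames(agg) <- NULL
  agg
}

#' TF-family to enzyme-gene correlation chords
#'
#' Correlation edges between transcription-factor gene expression and the
#' expression of flavonoid-pathway enzyme genes, with nodes labelled by TF
#' family and enzyme symbol. A thin wrapper around
#' [correlation_network()] with roles `"TF"` and `"enzyme"`; row names of
#' the inputs should carry the family/symbol labels (e.g. "MYB" rows vs
#' "FLS", "DFR", "PGT1" rows).
#'
#' @param tf_expression TF-gene expression matrix (genes x samples), row
#'   names labelled by TF gene or family.
#' @param enzyme_expression Enzyme-gene expression matrix, row names
#'   labelled by enzyme symbol.
#' @inheritParams correlation_network
#' @return Edge data frame as in [correlation_network()].
#' @export
tf_enzyme_chords <- function(tf_expression, enzyme_expression,
                             threshold_r2 = 0.8, threshold_p = 0.05) {
  correlation_network(tf_expression, enzyme_expression,
                      threshold_r2 = threshold_r2,
                      threshold_p = threshold_p,
                      role_a = "TF", role_b = "enzyme")
}
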