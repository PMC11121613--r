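#' Hypergeometric pathway over-representation
#'
#' Upper-tail hypergeometric test per pathway: with a background of N
#' features, K of them annotated to the pathway, and a selected set of
#' size n containing k pathway members, p = P(X >= k) for
#' X ~ Hypergeometric(N, K, n). P-values are Benjamini-Hochberg adjusted
#' across pathways and results are sorted by p.
#'
#' @param selected Character vector of selected feature/gene ids (must be
#'   a subset of `background`).
#' @param annotation Data frame (`id`, `pathway_id`, `pathway_name`);
#'   every annotated id must belong to `background`.
#' @param background Character vector of all detected ids of the relevant
#'   omics layer (the enrichment universe).
#' @return Data frame `pathway_id`, `pathway_name`, `k`, `n`, `K`, `N`,
#'   `p_value`, `adjusted_p`, sorted by `p_value`.
#' @examples
#' bg <- paste0("f", 1:10)
#' ann <- data.frame(id = bg[1:5], pathway_id = "ko00941",
#'                   pathway_name = "Flavonoid biosynthesis")
#' hypergeom_enrich(bg[1:4], ann, bg)   # p = 5/210
#' @export
hypergeom_enrich <- function(selected, annotation, background) {
  background <- unique(as.character(background))
  selected <- unique(as.character(selected))
  if (length(background) == 0L) stop("empty background", call. = FALSE)
  if (is.null(annotation) || nrow(annotation) == 0L) {
    stop("no annotation available for enrichment", call. = FALSE)
  }
  if (!all(selected %in% background)) {
    stop("selected ids must be a subset of the background", call. = FALSE)
  }
  if (!all(annotation$id %in% background)) {
    stop("every annotated id must belong to the background", call. = FALSE)
  }
  n_bg <- length(background)
  n_sel <- length(selected)
  paths <- unique(annotation[, c("pathway_id", "pathway_name")])
  res <- do.call(rbind, lapply(seq_len(nrow(paths)), function(i) {
    members <- unique(annotation$id[annotation$pathway_id ==
                                      paths$pathway_id[i]])
    K <- length(members)
    k <- length(intersect(selected, members))
    p <- if (K == 0L) 1 else
      stats::phyper(k - 1, K, n_bg - K, n_sel, lower.tail = FALSE)
    data.frame(pathway_id = paths$pathway_id[i],
               pathway_name = paths$pathway_name[i],
               k = k, n = n_sel, K = K, N = n_bg, p_value = p,
               stringsAsFactors = FALSE)
  }))
  res$adjusted_p <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value), ]
  rownames(res) <- NULL
  res
}

#' Map screening hits onto pathways
#'
#' Per-pathway membership counts and id lists for differential metabolites
#' and differential genes (the joint pathway-mapping summary of a
#' metabolome-transcriptome integration). Hits absent from the annotation
#' are counted as unmapped and reported via a message.
#'
#' @param df_ids Character vector of differential-metabolite ids.
#' @param deg_ids Character vector of differential-gene ids.
#' @param annotation Data frame (`id`, `pathway_id`, `pathway_name`).
#' @return Data frame `pathway_id`, `pathway_name`, `n_dfs`, `n_degs`,
#'   `dfs`, `degs` (semicolon-joined id lists).
#' @export
map_to_pathways <- function(df_ids, deg_ids, annotation) {
  if (is.null(annotation) || nrow(annotation) == 0L) {
    stop("no annotation available for pathway mapping", call. = FALSE)
  }
  df_ids <- unique(as.character(df_ids))
  deg_ids <- unique(as.character(deg_ids))
  unmapped <- setdiff(c(df_ids, deg_ids), annotation$id)
  if (length(unmapped) > 0L) {
    message(length(unmapped), " hit id(s) not present in the annotation")
  }
  if (length(df_ids) + length(deg_ids) == 0L) {
    return(data.frame(pathway_id = character(0),
                      pathway_name = character(0),
                      n_dfs = integer(0), n_degs = integer(0),
                      dfs = character(0), degs = character(0)))
  }
  paths <- unique(annotation[, c("pathway_id", "pathway_name")])
  out <- do.call(rbind, lapply(seq_len(nrow(paths)), function(i) {
    members <- annotation$id[annotation$pathway_id == paths$pathway_id[i]]
    dfs <- intersect(df_ids, members)
    degs <- intersect(deg_ids, members)
    data.frame(pathway_id = paths$pathway_id[i],
               pathway_name = paths$pathway_name[i],
               n_dfs = length(dfs), n_degs = length(degs),
               dfs = paste(dfs, collapse = ";"),
               degs = paste(degs, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
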