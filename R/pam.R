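#' Maximum quantum efficiency of PSII photochemistry, Fv/Fm
#'
#' Fv/Fm = (Fm - Fo)/Fm, the dark-adapted maximum efficiency of photosystem
#' II photochemistry. Vectorized over records.
#'
#' @param fo Minimal (dark-adapted) fluorescence, a.u.
#' @param fm Maximal fluorescence after a saturating pulse, a.u.
#' @return Fv/Fm in `[0, 1]`.
#' @examples
#' compute_fvfm(0.2, 1.0)   # 0.8
#' @export
compute_fvfm <- function(fo, fm) {
  if (any(fm <= 0)) stop("Fm must be positive", call. = FALSE)
  if (any(fo < 0)) stop("Fo must be nonnegative", call. = FALSE)
  if (any(fo > fm)) stop("Fo cannot exceed Fm", call. = FALSE)
  (fm - fo) / fm
}

#' Actual efficiency of PSII photochemistry, Y(II)
#'
#' Y(II) = (Fm' - F)/Fm', the operating efficiency of PSII in the light,
#' from the light-adapted maximal fluorescence Fm' and the steady-state
#' fluorescence F.
#'
#' @param f Steady-state fluorescence in the light, a.u.
#' @param fm_prime Light-adapted maximal fluorescence, a.u.
#' @return Y(II) in `[0, 1]`.
#' @examples
#' compute_yii(0.41, 0.5)   # 0.18
#' @export
compute_yii <- function(f, fm_prime) {
  if (any(fm_prime <= 0)) stop("Fm' must be positive", call. = FALSE)
  if (any(f < 0)) stop("F must be nonnegative", call. = FALSE)
  if (any(f > fm_prime)) stop("F cannot exceed Fm'", call. = FALSE)
  (fm_prime - f) / fm_prime
}

#' Derived PAM parameters per record
#'
#' Adds `fv_fm` and `y_ii` columns to a PAM record table
#' (`sample_id`, `group`, `Fo`, `Fm`, `Fm_prime`, `F`).
#'
#' @param records PAM record data frame, as produced by [simulate_pam()] or
#'   read from an instrument export.
#' @return The records with `fv_fm` and `y_ii` appended.
#' @export
pam_parameters <- function(records) {
  needed <- c("sample_id", "group", "Fo", "Fm", "Fm_prime", "F")
  if (!all(needed %in% names(records))) {
    stop("records must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  records$fv_fm <- compute_fvfm(records$Fo, records$Fm)
  records$y_ii <- compute_yii(records$F, records$Fm_prime)
  records
}

# Compact-letter display by insert-and-absorb (Piepho-style): maintain a
# set of letter columns; every significant pair must end up sharing no
# column, every non-significant pair keeps at least one common column.
# Letters are assigned alphabetically in group order.
compact_letters <- function(groups, sig_pairs) {
  cols <- list(groups)
  for (k in seq_len(nrow(sig_pairs))) {
    a <- sig_pairs$a[k]; b <- sig_pairs$b[k]
    new_cols <- list()
    for (col in cols) {
      if (a %in% col && b %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # drop empty columns and absorb columns that are subsets of another
    new_cols <- new_cols[lengths(new_cols) > 0L]
    keep <- rep(TRUE, length(new_cols))
    for (i in seq_along(new_cols)) {
      for (j in seq_along(new_cols)) {
        if (i == j || !keep[i] || !keep[j]) next
        if (all(new_cols[[i]] %in% new_cols[[j]]) &&
            (length(new_cols[[i]]) < length(new_cols[[j]]) || i > j)) {
          keep[i] <- FALSE
        }
      }
    }
    cols <- new_cols[keep]
  }
  # order columns by the first group they contain, then letter them
  first_idx <- vapply(cols, function(col) min(match(col, groups)), 1)
  cols <- cols[order(first_idx)]
  letters_out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(cols)) {
    for (g in cols[[i]]) {
      letters_out[g] <- paste0(letters_out[g], letters[i])
    }
  }
  letters_out
}

#' Group summaries with significance letters
#'
#' Per-group mean and standard deviation of a PAM parameter, with a
#' compact-letter display from one-way ANOVA followed by Tukey's HSD at
#' alpha = 0.05 (configurable). Groups that share no letter differ
#' significantly under the post-hoc test.
#'
#' @param records PAM records; run through [pam_parameters()] first if the
#'   derived columns are missing.
#' @param parameter Column to summarize: `"fv_fm"`, `"y_ii"` or `"Fo"`
#'   (any numeric column of `records` works).
#' @param alpha Significance level for the post-hoc test.
#' @return A data frame `group`, `mean`, `sd`, `n`, `letter`, in design
#'   group order.
#' @examples
#' rec <- pam_parameters(simulate_pam(study_design()))
#' summarize_groups(rec, "fv_fm")
#' @export
summarize_groups <- function(records, parameter = "fv_fm", alpha = 0.05) {
  if (!all(c("fv_fm", "y_ii") %in% names(records)) &&
      parameter %in% c("fv_fm", "y_ii")) {
    records <- pam_parameters(records)
  }
  if (!parameter %in% names(records)) {
    stop("unknown parameter column: ", parameter, call. = FALSE)
  }
  values <- records[[parameter]]
  groups <- records$group
  group_letters_tab <- group_letters(values, groups, alpha = alpha)
  agg <- do.call(rbind, lapply(split(values, groups), function(v) {
    data.frame(mean = mean(v), sd = stats::sd(v), n = length(v))
  }))
  agg$group <- rownames(agg)
  out <- merge(agg, group_letters_tab, by = "group", sort = FALSE)
  out <- out[match(unique(groups), out$group),
             c("group", "mean", "sd", "n", "letter")]
  rownames(out) <- NULL
  out
}

#' Compact-letter display for a one-way layout
#'
#' One-way ANOVA followed by Tukey's HSD; groups whose pairwise Tukey
#' p-value falls below `alpha` receive disjoint letter sets. Letters are
#' assigned alphabetically in the order groups first appear.
#'
#' @param values Numeric response.
#' @param groups Group labels (same length as `values`).
#' @param alpha Significance level.
#' @return A data frame `group`, `letter`.
#' @export
group_letters <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(tab < 2L)) {
    stop("every group needs at least two replicates", call. = FALSE)
  }
  glev <- unique(groups)
  fit <- stats::aov(values ~ factor(groups, levels = glev))
  # guard the degenerate all-identical case: zero residual variance makes
  # TukeyHSD p-values NaN; treat no pair as significant
  if (stats::sigma(fit) == 0) {
    sig <- data.frame(a = character(0), b = character(0))
  } else {
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)[[1]]
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    sig <- data.frame(
      a = vapply(pairs, `[`, "", 1),
      b = vapply(pairs, `[`, "", 2),
      stringsAsFactors = FALSE
    )[tk[, "p adj"] < alpha, , drop = FALSE]
  }
  letters_out <- compact_letters(glev, sig)
  data.frame(group = glev, letter = unname(letters_out[glev]),
             stringsAsFactors = FALSE)
}
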