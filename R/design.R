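#' Define the experimental design
#'
#' The study design is a replicated multi-group layout. The default mirrors a
#' three-treatment experiment on dark-adapted leaves: `M` = PAR control,
#' `N` = UV-B radiation, `Q` = UV-B plus exogenous abscisic acid, with three
#' biological replicates per treatment.
#'
#' @param groups Character vector of unique, ordered group labels.
#' @param replicates_per_group Number of biological replicates per group
#'   (at least 2).
#' @param seed Integer master seed; all simulators derive deterministic
#'   per-stream child seeds from it.
#'
#' @return An object of class `study_design`: a list with `groups`,
#'   `replicates_per_group`, `seed`, and the implied `samples` table
#'   (`sample_id`, `group`).
#' @examples
#' d <- study_design()
#' d$samples
#' @export
study_design <- function(groups = c("M", "N", "Q"),
                         replicates_per_group = 3L,
                         seed = 1L) {
  groups <- as.character(groups)
  if (anyDuplicated(groups) > 0L) {
    stop("group labels must be unique", call. = FALSE)
  }
  if (length(groups) < 2L) {
    stop("need at least two groups", call. = FALSE)
  }
  replicates_per_group <- as.integer(replicates_per_group)
  if (is.na(replicates_per_group) || replicates_per_group < 2L) {
    stop("replicates_per_group must be at least 2", call. = FALSE)
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  samples <- data.frame(
    sample_id = paste0(rep(groups, each = replicates_per_group),
                       seq_len(replicates_per_group)),
    group = rep(groups, each = replicates_per_group),
    stringsAsFactors = FALSE
  )
  structure(
    list(groups = groups,
         replicates_per_group = replicates_per_group,
         seed = seed,
         samples = samples),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", length(x$groups), "groups (",
      paste(x$groups, collapse = ", "), ") x",
      x$replicates_per_group, "replicates; seed", x$seed, "\n")
  invisible(x)
}

# Deterministic child seed for a named random stream. Keeps derived seeds
# within 32-bit integer range.
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.double(seed) * 7919 + h * 104729) %% 2147483647)
}

# log-linear interpolation of a transient at arbitrary times; OJIP data are
# log-sampled so interpolation is linear in log10(t)
interp_log_time <- function(time_s, values, at) {
  if (any(time_s <= 0)) stop("time grid must be positive", call. = FALSE)
  stats::approx(log10(time_s), values, xout = log10(at), rule = 1)$y
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}
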