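#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum (Mann-Whitney) test of location shift between two samples,
#' with two selectable p-value paths. `"exact"` enumerates every
#' assignment of the pooled midranks to the two groups (so it is exact
#' even under ties) and reports `2 * min(P(W <= w), P(W >= w))`, capped
#' at 1. `"normal"` uses the tie-corrected normal approximation with a
#' continuity correction of 1/2. `"auto"` picks the exact path whenever
#' `length(x) + length(y) <= 16`.
#'
#' @param x,y Non-empty numeric vectors.
#' @param mode One of `"auto"`, `"exact"`, `"normal"`.
#' @return Two-sided p-value in (0, 1].
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), mode = "exact")  # 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) {
    stop("`x` and `y` must be non-empty", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  nx <- length(x)
  ny <- length(y)
  n <- nx + ny
  if (mode == "auto") mode <- if (n <= 16) "exact" else "normal"
  r <- rank(c(x, y))                      # midranks
  w_obs <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  if (mode == "exact") {
    combos <- utils::combn(n, nx)
    w_all <- colSums(matrix(r[combos], nrow = nx))
    eps <- 1e-9
    p_le <- mean(w_all <= w_obs + eps)
    p_ge <- mean(w_all >= w_obs - eps)
    return(min(1, 2 * min(p_le, p_ge)))
  }
  tie_tab <- table(r)
  sigma2 <- nx * ny / 12 *
    ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)              # all pooled values identical
  z <- (w_obs - mu - sign(w_obs - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Log2 fold change of group means
#'
#' `log2((mean(x) + pseudocount) / (mean(y) + pseudocount))`. The
#' pseudocount stabilises low-count genes; with `pseudocount = 0` the
#' function is antisymmetric in its arguments.
#'
#' @param x,y Non-negative numeric vectors (numerator group first).
#' @param pseudocount Non-negative shift added to both means.
#' @return Log2 fold change (real).
#' @export
log2_fold_change <- function(x, y, pseudocount = 0) {
  if (any(x < 0) || any(y < 0)) {
    stop("values must be non-negative", call. = FALSE)
  }
  if (pseudocount < 0) stop("`pseudocount` must be >= 0", call. = FALSE)
  mx <- mean(x) + pseudocount
  my <- mean(y) + pseudocount
  if (mx == 0 && my == 0) {
    stop("fold change undefined: both means zero and pseudocount = 0",
         call. = FALSE)
  }
  log2(mx / my)
}

#' Differential-expression screen by Wilcoxon test and fold change
#'
#' Per-gene two-group screen: a Wilcoxon rank-sum p-value and a log2 fold
#' change of (optionally CPM-normalised) group means, flagged against
#' strict thresholds `p_value < p_threshold` and
#' `|log2fc| > fc_threshold`. No multiple-testing correction is applied
#' by default; `adjust = "BH"` adds a Benjamini-Hochberg column and flags
#' on it instead.
#'
#' @param counts Non-negative numeric matrix, genes x samples, with row
#'   and column names.
#' @param groups Character vector of group labels, one per column;
#'   exactly two distinct labels with at least two samples each.
#' @param case,control Which label is the numerator / denominator of the
#'   fold change. Defaults to `"tumor"` vs `"normal"` when those labels
#'   are present, otherwise the first and second distinct label.
#' @param p_threshold,fc_threshold Strict cutoffs (defaults 0.05 and 2).
#' @param normalize `"cpm"` (counts per million, default) or `"none"`.
#' @param pseudocount Added to group means before the log ratio
#'   (default 1).
#' @param mode Wilcoxon p-value path, see [wilcoxon_rank_sum()].
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A data frame (one row per gene): `gene_id`, `log2fc`,
#'   `p_value`, optional `p_adj`, `is_deg`, `direction`
#'   (`"up"`/`"down"`/`"none"`).
#' @export
screen_degs <- function(counts, groups, case = NULL, control = NULL,
                        p_threshold = 0.05, fc_threshold = 2,
                        normalize = c("cpm", "none"), pseudocount = 1,
                        mode = c("normal", "exact", "auto"),
                        adjust = c("none", "BH")) {
  normalize <- match.arg(normalize)
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("`counts` must be a numeric matrix", call. = FALSE)
  }
  if (length(groups) != ncol(counts)) {
    stop("`groups` must have one label per column of `counts`",
         call. = FALSE)
  }
  labs <- unique(groups)
  if (length(labs) != 2) {
    stop("exactly two group labels required", call. = FALSE)
  }
  if (is.null(case)) {
    case <- if ("tumor" %in% labs) "tumor" else labs[1]
  }
  if (is.null(control)) control <- setdiff(labs, case)
  if (!case %in% labs || !control %in% labs) {
    stop(sprintf("group label '%s' absent from `groups`",
                 setdiff(c(case, control), labs)[1]), call. = FALSE)
  }
  if (sum(groups == case) < 2 || sum(groups == control) < 2) {
    stop("need at least two samples per group", call. = FALSE)
  }
  expr <- counts
  if (normalize == "cpm") {
    lib <- colSums(counts)
    if (any(lib == 0)) stop("zero library size column", call. = FALSE)
    expr <- sweep(counts, 2, lib, "/") * 1e6
  }
  idx_case <- which(groups == case)
  idx_ctrl <- which(groups == control)
  p_value <- apply(expr, 1, function(v) {
    wilcoxon_rank_sum(v[idx_case], v[idx_ctrl], mode = mode)
  })
  log2fc <- apply(expr, 1, function(v) {
    log2_fold_change(v[idx_case], v[idx_ctrl], pseudocount = pseudocount)
  })
  out <- data.frame(gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
                    log2fc = log2fc, p_value = p_value,
                    stringsAsFactors = FALSE, row.names = NULL)
  p_flag <- out$p_value
  if (adjust == "BH") {
    out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
    p_flag <- out$p_adj
  }
  out$is_deg <- p_flag < p_threshold & abs(out$log2fc) > fc_threshold
  out$direction <- ifelse(!out$is_deg, "none",
                          ifelse(out$log2fc > 0, "up", "down"))
  out
}
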