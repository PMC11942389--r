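#' Edge share of a component
#'
#' The fraction of all network edges incident to one compound:
#' \eqn{\omega_i = C_i / T_{edge}} where \eqn{C_i} is the compound's
#' degree and \eqn{T_{edge}} the total edge count. Edge shares sum to 1
#' over the compounds of any network.
#'
#' @param net A [build_ct_network()] object.
#' @param i Component id.
#' @return Edge share in (0, 1].
#' @export
compute_omega <- function(net, i) {
  stopifnot(inherits(net, "ct_network"))
  if (!i %in% names(net$Ci)) {
    stop(sprintf("unknown component id '%s'", i), call. = FALSE)
  }
  if (net$Tedge == 0) stop("empty network", call. = FALSE)
  unname(net$Ci[[i]] / net$Tedge)
}

#' Herb-balance affinity of a component
#'
#' \eqn{A_i = \omega_i + |(C_{Ai} + C_{Bi}) / (C_{Ai} - C_{Bi})|}, where
#' \eqn{C_{Ai}} and \eqn{C_{Bi}} are the compound's degree attributed to
#' herb A and herb B. For a single-herb compound the ratio term is 1, so
#' \eqn{A_i = \omega_i + 1}. When \eqn{C_{Ai} = C_{Bi}} (a compound
#' claimed by both herbs with equal attributed degree) the ratio is
#' undefined; the denominator is clamped to 1 so the term becomes
#' \eqn{C_{Ai} + C_{Bi}}, which stays finite and grows with the shared
#' degree. A message is emitted whenever this rule fires.
#'
#' @inheritParams compute_omega
#' @return Affinity (positive real).
#' @export
compute_affinity <- function(net, i) {
  stopifnot(inherits(net, "ct_network"))
  if (!i %in% names(net$CAi)) {
    stop(sprintf("unknown component id '%s'", i), call. = FALSE)
  }
  ca <- net$CAi[[i]]
  cb <- net$CBi[[i]]
  if (ca + cb < 1) {
    stop(sprintf("component '%s' has no herb-attributed degree", i),
         call. = FALSE)
  }
  ratio <- if (ca == cb) {
    message(sprintf(
      "compute_affinity: CAi = CBi = %d for '%s'; denominator clamped to 1",
      ca, i))
    ca + cb
  } else {
    abs((ca + cb) / (ca - cb))
  }
  compute_omega(net, i) + ratio
}

#' Network effect of a component
#'
#' \eqn{NE_i = C_i \times A_i \times \sum_{j \in N(i)} P_j}: the
#' compound's degree, times its affinity, times the summed degrees of the
#' targets it touches. High values flag compounds that are themselves
#' well connected and hit well-connected (multi-compound) targets.
#'
#' @inheritParams compute_omega
#' @return Network effect (positive real).
#' @export
compute_ne <- function(net, i) {
  stopifnot(inherits(net, "ct_network"))
  if (!i %in% names(net$Ci)) {
    stop(sprintf("unknown component id '%s'", i), call. = FALSE)
  }
  tgt <- net$edges$target_id[net$edges$component_id == i]
  if (length(tgt) == 0) {
    stop(sprintf("component '%s' has no targets", i), call. = FALSE)
  }
  unname(net$Ci[[i]] * compute_affinity(net, i) * sum(net$Pj[tgt]))
}

#' Contribution index of every component
#'
#' Ranks the compounds of a component-target network by their
#' contribution index (CI), a percentage built from two topology
#' summaries: the network-effect share \eqn{NE_i / \sum NE} and the
#' degree share \eqn{C_i / \sum C}. Under the default `"mean"`
#' normalization
#' \deqn{CI_i = 100 \cdot (NE_i/\sum NE + C_i/\sum C)/2,}
#' so the indices of all compounds sum to exactly 100 and the cumulative
#' CI of the top k compounds reads directly as a percentage of the whole
#' network. Two alternative readings of the combining formula are kept
#' for comparison: `"literal"` (\eqn{NE_i/\sum NE + 100\,C_i/\sum C},
#' summing to 101) and `"sum"`
#' (\eqn{100\,(NE_i/\sum NE + C_i/\sum C)}, summing to 200).
#'
#' @param net A [build_ct_network()] object.
#' @param normalization `"mean"` (default), `"literal"`, or `"sum"`.
#' @return A data frame sorted by decreasing CI (ties broken by
#'   component id): `component_id`, `omega_e`, `affinity`, `ne`, `ci`,
#'   `rank`, `cumulative_ci`.
#' @examples
#' comp <- data.frame(component_id = c("X", "Y"), herb = c("A", "B"))
#' edg <- data.frame(component_id = c("X", "X", "Y"),
#'                   target_id = c("t1", "t2", "t2"))
#' compute_ci(build_ct_network(comp, edg))  # CI ~ (72.81, 27.19)
#' @export
compute_ci <- function(net, normalization = c("mean", "literal", "sum")) {
  stopifnot(inherits(net, "ct_network"))
  normalization <- match.arg(normalization)
  ids <- names(net$Ci)
  if (length(ids) == 0) stop("network has no components", call. = FALSE)
  omega <- vapply(ids, function(i) compute_omega(net, i), numeric(1))
  aff <- vapply(ids, function(i) compute_affinity(net, i), numeric(1))
  ne <- vapply(ids, function(i) compute_ne(net, i), numeric(1))
  ne_share <- ne / sum(ne)
  deg_share <- net$Ci / sum(net$Ci)
  ci <- switch(normalization,
    mean = 100 * (ne_share + deg_share) / 2,
    literal = ne_share + 100 * deg_share,
    sum = 100 * (ne_share + deg_share)
  )
  out <- data.frame(component_id = ids, omega_e = unname(omega),
                    affinity = unname(aff), ne = unname(ne),
                    ci = unname(ci), stringsAsFactors = FALSE,
                    row.names = NULL)
  out <- out[order(-out$ci, out$component_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$cumulative_ci <- cumsum(out$ci)
  rownames(out) <- NULL
  out
}

#' Cumulative contribution of the top k components
#'
#' @param results Output of [compute_ci()].
#' @param k Number of top-ranked compounds, `1 <= k <= nrow(results)`.
#' @return Summed CI (percent) of the k top-ranked compounds.
#' @export
top_k_cumulative <- function(results, k) {
  if (!is.data.frame(results) || !all(c("ci", "rank") %in% names(results))) {
    stop("`results` must come from compute_ci()", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > nrow(results) ||
      k != floor(k)) {
    stop("`k` must be an integer in [1, number of components]",
         call. = FALSE)
  }
  sum(results$ci[results$rank <= k])
}
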