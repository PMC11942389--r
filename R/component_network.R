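#' Filter compounds by oral bioavailability and drug-likeness
#'
#' Keeps compounds with `ob >= ob_min` and `dl >= dl_min`; both cutoffs
#' are inclusive. The defaults (OB >= 30 percent, DL >= 0.18) are the
#' conventional ADME screen applied to TCMSP-style herbal compound
#' tables.
#'
#' @param records Data frame with at least columns `ob` (percent) and
#'   `dl` (unitless).
#' @param ob_min,dl_min Inclusive minimum oral bioavailability and
#'   drug-likeness.
#' @return The retained rows of `records` (possibly empty), in input
#'   order.
#' @export
filter_components <- function(records, ob_min = 30, dl_min = 0.18) {
  if (!is.data.frame(records)) {
    stop("`records` must be a data frame", call. = FALSE)
  }
  if (nrow(records) == 0) return(records)
  if (!all(c("ob", "dl") %in% names(records))) {
    stop("`records` needs `ob` and `dl` columns", call. = FALSE)
  }
  if (any(records$ob < 0) || any(records$dl < 0)) {
    stop("`ob` and `dl` must be non-negative", call. = FALSE)
  }
  records[records$ob >= ob_min & records$dl >= dl_min, , drop = FALSE]
}

# Herb attribution strings: "A", "B", or both (any of "A,B", "AB", "A;B").
parse_herbs <- function(herb) {
  has_a <- grepl("A", herb, fixed = TRUE)
  has_b <- grepl("B", herb, fixed = TRUE)
  if (any(!has_a & !has_b)) {
    stop("each component must belong to herb A, herb B, or both",
         call. = FALSE)
  }
  cbind(A = has_a, B = has_b)
}

#' Build the component-target bipartite network
#'
#' Assembles the C-T network and its degree statistics: per-component
#' degree `Ci`, per-target degree `Pj`, total edge count `Tedge`, and the
#' herb-attributed component degrees `CAi`/`CBi`. A compound claimed by
#' both herbs contributes its full degree to both `CAi` and `CBi`.
#' Duplicate edges (the same component-target pair reported by several
#' prediction sources) are counted once, with a message; components left
#' without any edge are dropped with a warning since downstream
#' contribution scores are undefined on isolated nodes.
#'
#' @param components Data frame with columns `component_id` and `herb`
#'   (`"A"`, `"B"`, or `"A,B"`); extra columns (e.g. `ob`, `dl`) are kept.
#' @param edges Data frame with columns `component_id` and `target_id`.
#' @return An object of class `ct_network`: a list with `components`,
#'   `edges` (deduplicated), `targets`, `Tedge`, and named degree vectors
#'   `Ci`, `Pj`, `CAi`, `CBi`.
#' @examples
#' comp <- data.frame(component_id = c("X", "Y"), herb = c("A", "B"))
#' edg <- data.frame(component_id = c("X", "X", "Y"),
#'                   target_id = c("t1", "t2", "t2"))
#' net <- build_ct_network(comp, edg)
#' net$Tedge  # 3
#' @export
build_ct_network <- function(components, edges) {
  if (!all(c("component_id", "herb") %in% names(components))) {
    stop("`components` needs `component_id` and `herb` columns",
         call. = FALSE)
  }
  if (!all(c("component_id", "target_id") %in% names(edges))) {
    stop("`edges` needs `component_id` and `target_id` columns",
         call. = FALSE)
  }
  if (anyDuplicated(components$component_id)) {
    stop("duplicate component ids in `components`", call. = FALSE)
  }
  unknown <- setdiff(edges$component_id, components$component_id)
  if (length(unknown) > 0) {
    stop(sprintf("edge references unknown component id(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  key <- paste(edges$component_id, edges$target_id, sep = "\r")
  ndup <- sum(duplicated(key))
  if (ndup > 0) {
    message(sprintf("build_ct_network: %d duplicate edge(s) removed", ndup))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  edges <- edges[order(edges$component_id, edges$target_id), , drop = FALSE]
  rownames(edges) <- NULL

  isolated <- setdiff(components$component_id, edges$component_id)
  if (length(isolated) > 0) {
    warning(sprintf("dropping %d component(s) with no target edge: %s",
                    length(isolated), paste(isolated, collapse = ", ")),
            call. = FALSE)
    components <- components[!components$component_id %in% isolated, ,
                             drop = FALSE]
  }
  if (nrow(edges) == 0) stop("network has no edges", call. = FALSE)
  components <- components[order(components$component_id), , drop = FALSE]
  rownames(components) <- NULL

  comp_ids <- components$component_id
  targets <- sort(unique(edges$target_id))
  Ci <- table(factor(edges$component_id, levels = comp_ids))
  Pj <- table(factor(edges$target_id, levels = targets))
  Ci <- stats::setNames(as.integer(Ci), comp_ids)
  Pj <- stats::setNames(as.integer(Pj), targets)
  herbs <- parse_herbs(components$herb)
  CAi <- ifelse(herbs[, "A"], Ci, 0L)
  CBi <- ifelse(herbs[, "B"], Ci, 0L)
  names(CAi) <- names(CBi) <- comp_ids

  structure(
    list(components = components, edges = edges, targets = targets,
         Tedge = nrow(edges), Ci = Ci, Pj = Pj, CAi = CAi, CBi = CBi),
    class = "ct_network"
  )
}

#' @export
print.ct_network <- function(x, ...) {
  cat(sprintf("ct_network: %d components, %d targets, %d edges\n",
              length(x$Ci), length(x$Pj), x$Tedge))
  invisible(x)
}

#' Intersect compound targets with disease genes
#'
#' Exact set intersection with a deterministic, lexicographically sorted
#' result (the overlap a Venn diagram of predicted targets and
#' differential genes would report).
#'
#' @param component_targets,disease_genes Character vectors (treated as
#'   sets).
#' @return Sorted character vector of shared identifiers.
#' @export
intersect_targets <- function(component_targets, disease_genes) {
  sort(unique(intersect(as.character(component_targets),
                        as.character(disease_genes))))
}
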