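# Shared fixtures: the hand-worked toy network, a random-network factory
# and an independent brute-force contribution-index oracle.

# Two compounds, three edges: X (herb A) -> {t1, t2}, Y (herb B) -> {t2}.
toy_network <- function() {
  build_ct_network(
    data.frame(component_id = c("X", "Y"), herb = c("A", "B")),
    data.frame(component_id = c("X", "X", "Y"),
               target_id = c("t1", "t2", "t2"))
  )
}

# Small random bipartite network; every component gets >= 1 edge. Herb
# can be "A", "B" or shared "A,B".
random_network_tables <- function(n_comp, n_targ, seed) {
  set.seed(seed)
  ids <- sprintf("c%02d", seq_len(n_comp))
  targ <- sprintf("t%02d", seq_len(n_targ))
  herb <- sample(c("A", "B", "A,B"), n_comp, replace = TRUE,
                 prob = c(0.45, 0.45, 0.1))
  edges <- do.call(rbind, lapply(seq_len(n_comp), function(i) {
    k <- sample(seq_len(min(4, n_targ)), 1)
    data.frame(component_id = ids[i], target_id = sample(targ, k),
               stringsAsFactors = FALSE)
  }))
  list(components = data.frame(component_id = ids, herb = herb,
                               stringsAsFactors = FALSE),
       edges = edges)
}

# Brute-force contribution index straight from the raw tables: no shared
# code with compute_ci() or build_ct_network().
oracle_ci <- function(components, edges) {
  edges <- unique(edges)
  ids <- sort(unique(edges$component_id))
  tedge <- nrow(edges)
  deg_c <- vapply(ids, function(i) sum(edges$component_id == i), 0)
  deg_t <- table(edges$target_id)
  herb <- stats::setNames(components$herb, components$component_id)
  ne <- numeric(length(ids))
  names(ne) <- ids
  for (i in ids) {
    ca <- if (grepl("A", herb[[i]])) deg_c[[i]] else 0
    cb <- if (grepl("B", herb[[i]])) deg_c[[i]] else 0
    w <- deg_c[[i]] / tedge
    r <- if (ca == cb) ca + cb else abs((ca + cb) / (ca - cb))
    tg <- edges$target_id[edges$component_id == i]
    ne[[i]] <- deg_c[[i]] * (w + r) * sum(deg_t[tg])
  }
  100 * (ne / sum(ne) + deg_c / sum(deg_c)) / 2
}
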