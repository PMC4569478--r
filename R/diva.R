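# Dispersal-vicariance (DIVA-style) event parsimony.
#
# Event grammar: at an internal node with range R, either a vicariance event
# splits R into two disjoint non-empty parts covering R (free), or, when R
# is a singleton, a duplication passes R to both daughters (free). Along
# each branch, the daughter's range may differ from its inherited part at a
# cost of 1 per region gained (dispersal) and 1 per region lost (extinction).
# Branch lengths are ignored: this is pure event parsimony, minimised
# exactly by dynamic programming over the range state space.

diva_states <- function(regions, maxareas) {
  n <- length(regions)
  masks <- seq_len(2^n - 1L)
  masks[range_size(masks) <= maxareas]
}

# symmetric difference popcount = dispersals + extinctions along a branch
branch_cost <- function(p, c) range_size(bitwXor(p, c))

#' Minimum dispersal+extinction cost of a DIVA reconstruction
#'
#' Exact bottom-up dynamic programming over all range assignments with at
#' most `maxareas` regions per node. Tip ranges are fixed to the observed
#' ranges; vicariance and duplication events are free; each region gained or
#' lost along a branch costs 1.
#'
#' @param tree rooted binary `phylo` (branch lengths ignored)
#' @param rd a `range_data`
#' @param maxareas maximum ancestral range size (default 3)
#' @return object of class `diva_dp`: list with `min_cost` and the DP
#'   tables needed by [enumerate_optimal_reconstructions()].
#' @export
diva_min_cost <- function(tree, rd, maxareas = 3L) {
  vr <- validate_inputs(tree, rd)
  if (!vr$ok) {
    stop("tree/range-matrix mismatch; missing in matrix: ",
         paste(vr$missing_in_matrix, collapse = ", "),
         "; missing in tree: ", paste(vr$missing_in_tree, collapse = ", "))
  }
  obs <- rd$ranges[tree$tip.label]
  if (any(range_size(obs) > maxareas)) {
    stop("maxareas (", maxareas, ") smaller than an observed tip range: ",
         paste(names(obs)[range_size(obs) > maxareas], collapse = ", "))
  }
  states <- diva_states(rd$regions, maxareas)
  ns <- length(states)
  sidx <- function(mask) match(mask, states)
  # pairwise branch-cost table between every (inherited part, child range)
  cost_tab <- outer(states, states, function(p, c) range_size(bitwXor(p, c)))

  nt <- ape::Ntip(tree)
  nnode <- nt + tree$Nnode
  po <- stats::reorder(tree, "postorder")
  edge <- po$edge
  node_child_edges <- split(seq_len(nrow(edge)), edge[, 1L])
  parents <- unique(edge[, 1L])

  C <- matrix(Inf, ns, nnode)     # C[s, v]: min cost of subtree v given range
  for (i in seq_len(nt)) C[sidx(obs[i]), i] <- 0
  B <- vector("list", nnode)      # B[[child]][p]: min over child ranges of
                                  # C[c, child] + cost(p -> c)
  splits <- split_catalog(states, maxareas)

  for (nd in parents) {
    ce <- node_child_edges[[as.character(nd)]]
    ch <- edge[ce, 2L]
    for (c1 in ch) {
      B[[c1]] <- apply(cost_tab + matrix(C[, c1], ns, ns, byrow = TRUE), 1L, min)
    }
    for (s in seq_len(ns)) {
      sp <- splits[[s]]
      C[s, nd] <- min(B[[ch[1L]]][sp$li] + B[[ch[2L]]][sp$ri])
    }
  }
  root_node <- nt + 1L
  structure(list(min_cost = min(C[, root_node]),
                 C = C, B = B, states = states, splits = splits,
                 cost_tab = cost_tab, tree = tree, rd = rd,
                 maxareas = as.integer(maxareas), edge = edge,
                 node_child_edges = node_child_edges, parents = parents,
                 root_node = root_node, ntip = nt),
            class = "diva_dp")
}

# For each state: the ordered (left, right) event outcomes allowed by the
# grammar — all ordered disjoint bipartitions for |R| >= 2 (vicariance),
# the identity pair for singletons (duplication). Indices into `states`.
split_catalog <- function(states, maxareas) {
  lapply(seq_along(states), function(s) {
    R <- states[s]
    if (range_size(R) == 1L) {
      return(list(left = R, right = R, li = s, ri = s,
                  type = "duplication"))
    }
    subs <- submasks_of(R)
    subs <- subs[subs != R]           # proper non-empty submasks
    left <- subs
    right <- bitwAnd(R, bitwNot(subs))
    list(left = left, right = right,
         li = match(left, states), ri = match(right, states),
         type = rep("vicariance", length(left)))
  })
}

#' @export
print.diva_dp <- function(x, ...) {
  cat("DIVA dynamic program: min cost =", x$min_cost,
      "over", length(x$states), "range states (maxareas =", x$maxareas, ")\n")
  invisible(x)
}

#' Enumerate all minimum-cost DIVA reconstructions
#'
#' Backtracks the DP tables of [diva_min_cost()] to list every co-optimal
#' reconstruction (node ranges + split events), in a deterministic order, up
#' to `cap`; sets attribute `truncated` if the cap was hit.
#'
#' @param dp a `diva_dp`
#' @param cap maximum number of reconstructions to return (default 10000)
#' @return list of reconstructions; each is a list with `node_range`
#'   (integer bitmask per node id), `node_split` (data.frame: node, left,
#'   right, type) and `cost`.
#' @export
enumerate_optimal_reconstructions <- function(dp, cap = 10000L) {
  if (cap <= 0L) stop("cap must be positive")
  states <- dp$states
  counter <- new.env(parent = emptyenv())
  counter$hit <- FALSE

  # returns list of partial reconstructions for subtree at `node` given its
  # assigned range index; each partial is list(ranges = named int, splits = df)
  descend <- function(node, s) {
    if (node <= dp$ntip) {
      return(list(list(ranges = stats::setNames(states[s], node),
                       splits = NULL)))
    }
    ce <- dp$node_child_edges[[as.character(node)]]
    ch <- dp$edge[ce, 2L]
    sp <- dp$splits[[s]]
    target <- dp$C[s, node]
    out <- list()
    for (k in seq_along(sp$li)) {
      if (dp$B[[ch[1L]]][sp$li[k]] + dp$B[[ch[2L]]][sp$ri[k]] > target + 1e-9) next
      kids <- vector("list", 2L)
      ok <- TRUE
      for (j in 1:2) {
        p <- if (j == 1L) sp$li[k] else sp$ri[k]
        cstates <- which(dp$C[, ch[j]] + dp$cost_tab[p, ] <=
                           dp$B[[ch[j]]][p] + 1e-9)
        sub <- list()
        for (cs in cstates) sub <- c(sub, descend(ch[j], cs))
        if (!length(sub)) { ok <- FALSE; break }
        kids[[j]] <- sub
      }
      if (!ok) next
      split_row <- data.frame(node = node, left = sp$left[k],
                              right = sp$right[k], type = sp$type[k],
                              stringsAsFactors = FALSE)
      for (a in kids[[1L]]) {
        for (b in kids[[2L]]) {
          out <- c(out, list(list(
            ranges = c(stats::setNames(states[s], node), a$ranges, b$ranges),
            splits = rbind(split_row, a$splits, b$splits))))
          if (length(out) > cap) { counter$hit <- TRUE; return(out[seq_len(cap)]) }
        }
      }
    }
    out
  }

  root_states <- which(abs(dp$C[, dp$root_node] - dp$min_cost) < 1e-9)
  recs <- list()
  for (s in root_states) {
    recs <- c(recs, descend(dp$root_node, s))
    if (length(recs) >= cap) { counter$hit <- length(recs) > cap || counter$hit
      recs <- recs[seq_len(min(length(recs), cap))]
      if (counter$hit) break }
  }
  recs <- lapply(recs, function(r) {
    ord <- order(as.integer(names(r$ranges)))
    list(node_range = r$ranges[ord],
         node_split = r$splits[order(r$splits$node), , drop = FALSE],
         cost = dp$min_cost)
  })
  attr(recs, "truncated") <- isTRUE(counter$hit)
  attr(recs, "regions") <- dp$rd$regions
  recs
}

#' Re-score a DIVA reconstruction
#'
#' Sums branch costs (regions gained + regions lost relative to the
#' inherited split part) over every edge; used to verify that enumerated
#' optima really achieve the DP minimum.
#'
#' @param rec one reconstruction from [enumerate_optimal_reconstructions()]
#' @param dp the `diva_dp` it came from
#' @return integer cost
#' @export
diva_rescore <- function(rec, dp) {
  total <- 0L
  for (i in seq_len(nrow(dp$edge))) {
    par <- dp$edge[i, 1L]; ch <- dp$edge[i, 2L]
    srow <- rec$node_split[rec$node_split$node == par, ]
    ce <- dp$node_child_edges[[as.character(par)]]
    part <- if (dp$edge[ce[1L], 2L] == ch) srow$left else srow$right
    total <- total + branch_cost(part, rec$node_range[[as.character(ch)]])
  }
  total
}

#' Score internal nodes as vicariant across co-optimal DIVA reconstructions
#'
#' A node's frequency is the fraction of optimal reconstructions in which
#' its split is a vicariance event; the indicator is `frequency > 0.5`
#' ("vicariance according to the most likely reconstruction", generalised to
#' a majority over co-optima). An exact 0.5 tie is flagged ambiguous, the
#' indicator is `FALSE`, and a warning is emitted.
#'
#' @param optima list from [enumerate_optimal_reconstructions()]
#' @return data.frame with columns `node`, `frequency`, `vicariant`,
#'   `ambiguous`
#' @export
score_node_vicariance_diva <- function(optima) {
  if (!length(optima)) stop("empty optimum set")
  costs <- vapply(optima, function(r) r$cost, numeric(1))
  if (length(unique(costs)) != 1L) stop("optima have mixed costs")
  nodes <- sort(unique(optima[[1L]]$node_split$node))
  freq <- vapply(nodes, function(nd) {
    mean(vapply(optima, function(r) {
      r$node_split$type[r$node_split$node == nd] == "vicariance"
    }, logical(1)))
  }, numeric(1))
  amb <- abs(freq - 0.5) < 1e-12
  if (any(amb)) {
    warning("vicariance frequency exactly 0.5 at node(s) ",
            paste(nodes[amb], collapse = ", "), "; scored non-vicariant")
  }
  data.frame(node = nodes, frequency = freq,
             vicariant = freq > 0.5 & !amb, ambiguous = amb)
}
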