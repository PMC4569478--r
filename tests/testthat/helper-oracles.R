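# Independent oracles used to validate the package's algorithms.
# These deliberately avoid the package's own computational paths: states,
# scenarios, rate matrices and transition probabilities are rebuilt from the
# model definition, P(t) comes from ape::matexpo, and likelihoods/costs are
# obtained by explicit enumeration over complete histories/assignments.

popcount <- function(x) {
  vapply(x, function(b) {
    k <- 0L
    while (b > 0L) { k <- k + b %% 2L; b <- b %/% 2L }
    as.integer(k)
  }, integer(1))
}

bits_in <- function(mask, n) which(bitwAnd(mask, 2L^(0:(n - 1L))) != 0L)

oracle_states <- function(n, K) {
  m <- seq_len(2^n - 1L)
  m[popcount(m) <= K]
}

# DEC scenario grammar, written straight from its definition
oracle_splits <- function(mask, n) {
  occ <- bits_in(mask, n)
  if (length(occ) == 1L) {
    return(data.frame(left = mask, right = mask, weight = 1))
  }
  pairs <- list()
  for (i in occ) {
    si <- 2L^(i - 1L)
    rest <- mask - si
    pairs <- c(pairs, list(c(si, rest), c(rest, si), c(si, mask), c(mask, si)))
  }
  pairs <- unique(pairs)
  data.frame(left = as.integer(vapply(pairs, `[`, numeric(1), 1L)),
             right = as.integer(vapply(pairs, `[`, numeric(1), 2L)),
             weight = 1 / length(pairs))
}

oracle_Q <- function(states, n, d, e, K, m = NULL) {
  if (is.null(m)) m <- matrix(1, n, n)
  full <- c(0L, states)  # empty state first, absorbing
  S <- length(full)
  Q <- matrix(0, S, S)
  for (a in 2:S) {
    R <- full[a]
    occ <- bits_in(R, n)
    if (length(occ) < K) {
      for (j in setdiff(seq_len(n), occ)) {
        b <- match(R + 2L^(j - 1L), full)
        if (!is.na(b)) Q[a, b] <- Q[a, b] + d * sum(m[occ, j])
      }
    }
    for (i in occ) {
      b <- match(R - 2L^(i - 1L), full)
      Q[a, b] <- Q[a, b] + e
    }
  }
  diag(Q) <- -rowSums(Q)
  list(Q = Q, full = full)
}

# Explicit-history DEC likelihood: enumerates every joint assignment of
# (ancestral state, scenario) over the internal nodes and sums path
# probabilities directly (vectorised over the assignment grid).
# `constrain` optionally fixes node v to one (state, scenario) triple:
# list(node =, anc =, left =, right =). tip_bits must be named by tip label.
oracle_dec_lik <- function(tree, tip_bits, n, d, e, K, m = NULL,
                           constrain = NULL) {
  states <- oracle_states(n, K)
  qq <- oracle_Q(states, n, d, e, K, m)
  nt <- ape::Ntip(tree)
  edge <- tree$edge
  elen <- tree$edge.length
  P <- lapply(seq_len(nrow(edge)), function(i) ape::matexpo(qq$Q * elen[i]))
  internal <- nt + seq_len(tree$Nnode)
  # one choice table per internal node: every (state, left, right, weight)
  choice <- do.call(rbind, lapply(states, function(s) {
    sp <- oracle_splits(s, n)
    cbind(anc = s, left = sp$left, right = sp$right, weight = sp$weight)
  }))
  anc_i <- match(choice[, "anc"], qq$full)
  left_i <- match(choice[, "left"], qq$full)
  right_i <- match(choice[, "right"], qq$full)
  rows_per_node <- lapply(internal, function(v) {
    if (!is.null(constrain) && v == constrain$node) {
      which(choice[, "anc"] == constrain$anc &
              choice[, "left"] == constrain$left &
              choice[, "right"] == constrain$right)
    } else {
      seq_len(nrow(choice))
    }
  })
  names(rows_per_node) <- internal
  grid <- as.matrix(do.call(expand.grid, rows_per_node))
  colnames(grid) <- as.character(internal)
  prob <- rep(1, nrow(grid))
  for (v in internal) {
    rows <- grid[, as.character(v)]
    prob <- prob * choice[rows, "weight"]
  }
  child_edges <- split(seq_len(nrow(edge)), edge[, 1L])
  for (v in internal) {
    ce <- child_edges[[as.character(v)]]
    rows_v <- grid[, as.character(v)]
    for (k in 1:2) {
      ch <- edge[ce[k], 2L]
      part_idx <- if (k == 1L) left_i[rows_v] else right_i[rows_v]
      target_idx <- if (ch <= nt) {
        rep(match(tip_bits[[tree$tip.label[ch]]], qq$full), nrow(grid))
      } else {
        anc_i[grid[, as.character(ch)]]
      }
      prob <- prob * P[[ce[k]]][cbind(part_idx, target_idx)]
    }
  }
  sum(prob)
}

# Exhaustive DIVA: enumerates every assignment of internal-node ranges,
# scores each with per-node minimal split costs, and returns the minimum
# plus the complete optimum set (ranges + all argmin splits) as canonical
# strings for set comparison.
oracle_diva <- function(tree, tip_bits, n, maxareas) {
  states <- oracle_states(n, maxareas)
  nt <- ape::Ntip(tree)
  edge <- tree$edge
  internal <- nt + seq_len(tree$Nnode)
  child_edges <- split(seq_len(nrow(edge)), edge[, 1L])
  splits_of <- lapply(states, function(R) {
    if (popcount(R) == 1L) return(cbind(left = R, right = R))
    subs <- Filter(function(s) s != R, oracle_submasks(R))
    cbind(left = subs, right = R - subs)
  })
  cost <- function(p, c) popcount(bitwXor(p, c))
  grid <- do.call(expand.grid, rep(list(seq_along(states)), length(internal)))
  best <- Inf
  optima <- list()
  for (g in seq_len(nrow(grid))) {
    assign <- states[as.integer(grid[g, ])]
    names(assign) <- internal
    total <- 0
    node_split_sets <- list()
    for (v in internal) {
      ce <- child_edges[[as.character(v)]]
      ch <- edge[ce, 2L]
      cr <- vapply(ch, function(c)
        if (c <= nt) tip_bits[[tree$tip.label[c]]]
        else assign[[as.character(c)]], integer(1))
      sp <- splits_of[[match(assign[[as.character(v)]], states)]]
      costs <- cost(sp[, "left"], cr[1L]) + cost(sp[, "right"], cr[2L])
      total <- total + min(costs)
      node_split_sets[[as.character(v)]] <-
        sp[costs == min(costs), , drop = FALSE]
      if (total > best) break
    }
    if (total > best) next
    if (total < best) { best <- total; optima <- list() }
    # expand per-node argmin splits into full reconstructions
    combos <- do.call(expand.grid,
                      lapply(node_split_sets, function(s) seq_len(nrow(s))))
    for (cc in seq_len(nrow(combos))) {
      desc <- vapply(internal, function(v) {
        s <- node_split_sets[[as.character(v)]][combos[cc, as.character(v)], ]
        sprintf("%d=%d:%d|%d", v, assign[[as.character(v)]], s[["left"]],
                s[["right"]])
      }, character(1))
      optima <- c(optima, list(paste(desc, collapse = ";")))
    }
  }
  list(min_cost = best, optima = sort(unlist(optima)))
}

oracle_submasks <- function(of) {
  out <- integer(0)
  s <- of
  repeat {
    out <- c(out, s)
    s <- bitwAnd(s - 1L, of)
    if (s == 0L) break
  }
  sort(out)
}

# Canonical string for a package DIVA reconstruction (internal nodes only),
# matching oracle_diva's encoding.
canon_reconstruction <- function(rec) {
  sp <- rec$node_split[order(rec$node_split$node), ]
  paste(sprintf("%d=%d:%d|%d", sp$node,
                rec$node_range[as.character(sp$node)], sp$left, sp$right),
        collapse = ";")
}

# Manual type-7 quantile (independent of stats::quantile's internals)
sort_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp
    lo <- floor(h)
    if (lo + 1 >= n) return(x[n])
    x[lo + 1] + (h - lo) * (x[lo + 2] - x[lo + 1])
  }, numeric(1))
}

# Rooted binary tree shapes (one labelled representative per shape),
# n = 2..5; DEC/DIVA quantities are equivariant under tip relabelling so
# these are the equivalence classes of small trees.
tree_shapes <- function(n) {
  txt <- switch(as.character(n),
    "2" = c("(t1:1,t2:1);"),
    "3" = c("((t1:1,t2:1):1,t3:2);"),
    "4" = c("((t1:1,t2:1):1,(t3:1,t4:1):1);",
            "(((t1:1,t2:1):1,t3:2):1,t4:3);"),
    "5" = c("((((t1:1,t2:1):1,t3:2):1,t4:3):1,t5:4);",
            "(((t1:1,t2:1):1,(t3:1,t4:1):1):1,t5:3);",
            "(((t1:1,t2:1):2,t3:3):1,(t4:2,t5:2):2);"),
    stop("no shapes for n = ", n))
  lapply(txt, function(s) ape::read.tree(text = s))
}

random_tip_bits <- function(n_tips, n_regions, max_size, seed) {
  set.seed(seed)
  masks <- oracle_states(n_regions, max_size)
  stats::setNames(sample(masks, n_tips, replace = TRUE),
                  paste0("t", seq_len(n_tips)))
}
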