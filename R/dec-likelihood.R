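# Shared pruning engine for the DEC likelihood.
#
# Computes per-node conditional likelihood vectors over the range state
# space with per-node rescaling (deep mtDNA-scale trees underflow doubles
# otherwise). At an internal node the cladogenetic convolution is
#   clv[R] = sum over scenarios (l, r, w) of R:
#              w * (P_left %*% clv_left)[l] * (P_right %*% clv_right)[r]
# and the total likelihood is the unweighted sum of root conditionals over
# non-empty states (no root-state prior, the LAGRANGE default).
dec_prune <- function(tree, rd, params, keep = FALSE,
                      root = c("flat-sum", "uniform-prior")) {
  root_mode <- match.arg(root)
  vr <- validate_inputs(tree, rd)
  if (!vr$ok) {
    stop("tree/range-matrix mismatch; missing in matrix: ",
         paste(vr$missing_in_matrix, collapse = ", "),
         "; missing in tree: ", paste(vr$missing_in_tree, collapse = ", "))
  }
  geom <- dec_geometry(rd$regions, params$K)
  space <- geom$space
  obs <- rd$ranges[tree$tip.label]
  too_big <- range_size(obs) > params$K
  if (any(too_big)) {
    stop("tip range larger than K for taxon: ",
         paste(names(obs)[too_big], collapse = ", "))
  }
  Q <- build_rate_matrix(space, params)
  prop <- make_propagator(Q)
  scen <- geom$scen
  flat <- geom$flat

  nt <- ape::Ntip(tree)
  nnode <- nt + tree$Nnode
  S <- length(space$masks)
  po <- stats::reorder(tree, "postorder")
  edge <- po$edge
  elen <- po$edge.length

  clv <- matrix(0, S, nnode)
  logs <- numeric(nnode)
  for (i in seq_len(nt)) clv[state_index(space, obs[i]), i] <- 1

  ne <- nrow(edge)
  downs <- vector("list", ne)
  Ps <- if (keep) vector("list", ne) else NULL
  node_child_edges <- split(seq_len(ne), edge[, 1L])
  parents <- unique(edge[, 1L])  # postorder guarantees children first

  for (nd in parents) {
    ce <- node_child_edges[[as.character(nd)]]
    if (length(ce) != 2L) stop("internal node ", nd, " is not binary")
    dvals <- vector("list", 2L)
    lsc <- 0
    for (k in 1:2) {
      ch <- edge[ce[k], 2L]
      P <- prop(elen[ce[k]])
      dvals[[k]] <- as.vector(P %*% clv[, ch])
      lsc <- lsc + logs[ch]
      downs[[ce[k]]] <- dvals[[k]]
      if (keep) Ps[[ce[k]]] <- P
    }
    v <- numeric(S)
    contrib <- flat$w * dvals[[1L]][flat$li] * dvals[[2L]][flat$ri]
    agg <- rowsum(contrib, flat$anc)
    v[as.integer(rownames(agg))] <- agg
    mx <- max(v)
    if (mx <= 0 || !is.finite(mx)) {
      return(list(loglik = -Inf, space = space))
    }
    clv[, nd] <- v / mx
    logs[nd] <- lsc + log(mx)
  }

  root_node <- nt + 1L
  nonempty <- space$masks != 0L
  lik <- sum(clv[nonempty, root_node])
  if (root_mode == "uniform-prior") lik <- lik / sum(nonempty)
  list(loglik = log(lik) + logs[root_node],
       clv = clv, logs = logs, downs = downs, Ps = Ps,
       edge = edge, elen = elen, node_child_edges = node_child_edges,
       parents = parents, space = space, scen = scen, flat = flat,
       prop = prop, root_node = root_node, ntip = nt)
}

# State space + scenario tables depend only on (region set, K); cache them
# so repeated likelihood evaluations during optimisation skip the
# combinatorial setup.
.dec_geom_cache <- new.env(parent = emptyenv())

dec_geometry <- function(regions, K) {
  key <- paste(c(unclass(regions), K), collapse = "\r")
  hit <- .dec_geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  space <- build_state_space(regions, K)
  scen <- scenario_tables(space)
  out <- list(space = space, scen = scen, flat = flatten_scenarios(scen))
  .dec_geom_cache[[key]] <- out
  out
}

# One flat table of (ancestral state index, left/right state index, weight,
# type) over all non-empty states; drives vectorised convolutions.
flatten_scenarios <- function(scen) {
  rows <- Filter(Negate(is.null), scen)
  anc <- unlist(lapply(seq_along(scen), function(s) {
    if (is.null(scen[[s]])) integer(0) else rep.int(s, nrow(scen[[s]]))
  }))
  tab <- do.call(rbind, rows)
  list(anc = anc, li = tab$li, ri = tab$ri, w = tab$weight,
       left = tab$left, right = tab$right, type = tab$type)
}

#' DEC log-likelihood of a range matrix on a dated tree
#'
#' Felsenstein pruning over the DEC range state space with the cladogenetic
#' convolution at internal nodes; computed with per-node rescaling and
#' returned as a natural log.
#'
#' @param tree rooted binary dated `phylo`
#' @param rd a `range_data` (see [read_range_matrix()])
#' @param params a [dec_params()]
#' @param root root convention: `"flat-sum"` (default; unweighted sum of
#'   root conditionals over non-empty states) or `"uniform-prior"`.
#' @return log-likelihood (scalar; `-Inf` if the data are impossible)
#' @export
dec_loglik <- function(tree, rd, params, root = "flat-sum") {
  res <- dec_prune(tree, rd, params, keep = FALSE, root = root)
  if (!is.finite(res$loglik) && res$loglik > 0) stop("non-finite likelihood")
  res$loglik
}

#' Marginal probabilities of cladogenetic scenarios at every internal node
#'
#' For each internal node v and each range-inheritance scenario s, the
#' relative probability is the likelihood of the whole data set with the
#' split at v constrained to s, divided by the unconstrained likelihood.
#' Computed by a two-pass (rootward conditional likelihoods, then tipward
#' "outside" partial likelihoods) algorithm, so one upward and one downward
#' sweep suffice for all nodes. Scenario probabilities at each node sum to 1.
#'
#' @inheritParams dec_loglik
#' @return a data.frame of class `dec_scenarios` with columns `node`
#'   (ape node id), `ancestral`, `left`, `right` (range bitmasks),
#'   `ancestral_label`, `left_label`, `right_label`, `type`, `rel_prob`.
#'   The tree's root is node `ape::Ntip(tree) + 1`.
#' @export
ancestral_split_probs <- function(tree, rd, params) {
  pr <- dec_prune(tree, rd, params, keep = TRUE)
  if (!is.finite(pr$loglik)) stop("zero total likelihood; data impossible under model")
  space <- pr$space
  S <- length(space$masks)
  flat <- pr$flat
  edge <- pr$edge

  # outside pass: A[, v] = partial likelihood of data outside clade v given
  # the range of v at its own split; flat weighting over non-empty roots.
  A <- matrix(0, S, pr$ntip + tree$Nnode)
  A[space$masks != 0L, pr$root_node] <- 1
  preorder <- rev(pr$parents)
  for (u in preorder) {
    ce <- pr$node_child_edges[[as.character(u)]]
    for (k in 1:2) {
      ch <- edge[ce[k], 2L]
      if (ch <= pr$ntip) next
      sib_down <- pr$downs[[ce[if (k == 1L) 2L else 1L]]]
      own_part <- if (k == 1L) flat$li else flat$ri
      sib_part <- if (k == 1L) flat$ri else flat$li
      vals <- A[flat$anc, u] * flat$w * sib_down[sib_part]
      g <- numeric(S)
      agg <- rowsum(vals, own_part)
      g[as.integer(rownames(agg))] <- agg
      Av <- as.vector(crossprod(pr$Ps[[ce[k]]], g))
      mx <- max(Av)
      A[, ch] <- if (mx > 0) Av / mx else Av
    }
  }

  out <- vector("list", length(pr$parents))
  for (i in seq_along(pr$parents)) {
    v <- pr$parents[i]
    ce <- pr$node_child_edges[[as.character(v)]]
    num <- A[flat$anc, v] * flat$w *
      pr$downs[[ce[1L]]][flat$li] * pr$downs[[ce[2L]]][flat$ri]
    tot <- sum(num)
    if (tot <= 0) stop("zero constrained likelihood at node ", v)
    keep <- num > 0
    out[[i]] <- data.frame(
      node = v,
      ancestral = space$masks[flat$anc][keep],
      left = flat$left[keep], right = flat$right[keep],
      type = flat$type[keep], rel_prob = num[keep] / tot,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$ancestral_label <- range_label(res$ancestral, space$regions)
  res$left_label <- range_label(res$left, space$regions)
  res$right_label <- range_label(res$right, space$regions)
  res <- res[order(res$node, -res$rel_prob), ]
  rownames(res) <- NULL
  attr(res, "regions") <- space$regions
  attr(res, "loglik") <- pr$loglik
  class(res) <- c("dec_scenarios", "data.frame")
  res
}

#' Maximum-likelihood estimation of DEC dispersal and extinction rates
#'
#' Maximises [dec_loglik()] over `(d, e)` by bounded quasi-Newton (L-BFGS-B
#' on log-rates) from four deterministic starting points
#' `(d, e) in {0.001, 0.1}^2`, plus an optional user start. Ties are broken
#' by the first start found.
#'
#' @param tree rooted binary dated `phylo`
#' @param rd a `range_data`
#' @param K maximum range size
#' @param m optional dispersal constraint matrix
#' @param init optional extra starting point `c(d0, e0)`
#' @param bounds rate bounds, default `c(1e-8, 10)`
#' @return object of class `dec_fit`: list with `d`, `e`, `loglik`,
#'   `params` (a `dec_params`), `starts` (per-start results) and
#'   `convergence` (0 = at least one start converged).
#' @export
fit_dec <- function(tree, rd, K, m = NULL, init = NULL, bounds = c(1e-8, 10)) {
  if (any(bounds <= 0) || bounds[1] >= bounds[2]) stop("bounds must be positive, increasing")
  starts <- as.matrix(expand.grid(d = c(0.001, 0.1), e = c(0.001, 0.1)))
  if (!is.null(init)) {
    if (length(init) != 2L || any(init <= 0)) stop("init must be positive c(d0, e0)")
    starts <- rbind(starts, init)
  }
  starts <- pmin(pmax(starts, bounds[1]), bounds[2])
  nll <- function(lp) {
    p <- exp(lp)
    ll <- dec_loglik(tree, rd, dec_params(p[1], p[2], K, m))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  lo <- log(bounds[1]); hi <- log(bounds[2])
  runs <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    runs[[i]] <- tryCatch(
      stats::optim(log(starts[i, ]), nll, method = "L-BFGS-B",
                   lower = lo, upper = hi,
                   control = list(factr = 1e9, maxit = 200)),
      error = function(e) list(value = Inf, par = log(starts[i, ]),
                               convergence = 99, message = conditionMessage(e)))
  }
  vals <- vapply(runs, function(r) r$value, numeric(1))
  if (all(!is.finite(vals) | vals >= 1e10)) {
    stop("optimizer failed to converge from every start; best loglik = ",
         -min(vals))
  }
  best <- which.min(vals)
  par <- exp(runs[[best]]$par)
  start_tab <- data.frame(start_d = starts[, 1], start_e = starts[, 2],
                          d = vapply(runs, function(r) exp(r$par[1]), numeric(1)),
                          e = vapply(runs, function(r) exp(r$par[2]), numeric(1)),
                          loglik = -vals,
                          convergence = vapply(runs, function(r)
                            as.integer(r$convergence %||% 99L), integer(1)))
  structure(list(d = unname(par[1]), e = unname(par[2]),
                 loglik = -vals[best],
                 params = dec_params(par[1], par[2], K, m),
                 starts = start_tab,
                 convergence = runs[[best]]$convergence),
            class = "dec_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dec_fit <- function(x, ...) {
  cat("DEC maximum-likelihood fit\n")
  cat(sprintf("  d (dispersal)  = %.6g\n", x$d))
  cat(sprintf("  e (extinction) = %.6g\n", x$e))
  cat(sprintf("  log-likelihood = %.6f\n", x$loglik))
  cat("  starts tried   =", nrow(x$starts), "\n")
  invisible(x)
}
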