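# Forward simulation: Yule trees and DEC range histories with a logged,
# replayable event history. These are the fixtures that make every other
# module verifiable without external data.

seed_mod <- 2147483647  # 2^31 - 1; keeps derived seeds inside R's integer range

derive_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(seed) %% seed_mod
  salts <- c(7919, 104729, 1299709, 15485863)
  for (i in seq_along(ks)) {
    s <- (s * 48271 + salts[(i - 1L) %% length(salts) + 1L] * as.double(ks[i])) %% seed_mod
  }
  as.integer(s)
}

#' Simulate a dated Yule (pure-birth) tree
#'
#' Constant-rate birth process conditioned on the number of tips: starting
#' from the root's two daughter lineages, each lineage splits at rate
#' `birth_rate`; after the (n-1)-th split, one further exponential waiting
#' time is appended so extant tips sit strictly below the last split. The
#' result is ultrametric and byte-identical across runs with the same seed.
#'
#' @param n_tips number of tips, >= 2
#' @param birth_rate speciation rate per lineage per time unit, > 0
#' @param seed integer seed
#' @return an ultrametric binary `phylo` with tips `t1..tn`
#' @export
simulate_yule <- function(n_tips, birth_rate = 1, seed = 1L) {
  if (n_tips < 2L) stop("n_tips must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  set.seed(derive_seed(seed, 1))
  birth <- c(0, 0)          # per-lineage origin times; root at time 0
  split_time <- c(NA_real_, NA_real_)
  kids <- list(NULL, NULL)
  active <- c(1L, 2L)
  t <- 0
  while (length(active) < n_tips) {
    k <- length(active)
    t <- t + stats::rexp(1, k * birth_rate)
    idx <- active[sample.int(k, 1L)]
    split_time[idx] <- t
    c1 <- length(birth) + 1L; c2 <- c1 + 1L
    birth <- c(birth, t, t)
    split_time <- c(split_time, NA_real_, NA_real_)
    kids[[idx]] <- c(c1, c2)
    kids <- c(kids, list(NULL, NULL))
    active <- c(setdiff(active, idx), c1, c2)
  }
  present <- t + stats::rexp(1, n_tips * birth_rate)
  tip_counter <- new.env(parent = emptyenv()); tip_counter$i <- 0L
  nwk <- function(l) {
    if (is.null(kids[[l]])) {
      tip_counter$i <- tip_counter$i + 1L
      sprintf("t%d:%.10f", tip_counter$i, present - birth[l])
    } else {
      len <- if (l <= 2L) split_time[l] else split_time[l] - birth[l]
      sprintf("(%s,%s):%.10f", nwk(kids[[l]][1L]), nwk(kids[[l]][2L]), len)
    }
  }
  txt <- sprintf("(%s,%s);", nwk(1L), nwk(2L))
  ape::read.tree(text = txt)
}

#' Linear-chain dispersal constraint matrix
#'
#' Default synthetic geography: regions arranged along a one-dimensional
#' corridor (an Australian-Wet-Tropics-like north-south chain), with
#' dispersal multiplier `adjacent` between neighbouring regions and
#' `distant` otherwise.
#'
#' @param regions a `region_set`
#' @param adjacent multiplier for neighbouring regions (default 1)
#' @param distant multiplier for non-neighbours (default 0.1)
#' @return numeric constraint matrix
#' @export
linear_chain_constraints <- function(regions, adjacent = 1, distant = 0.1) {
  n <- length(regions)
  m <- matrix(distant, n, n,
              dimnames = list(unclass(regions), unclass(regions)))
  for (i in seq_len(n - 1L)) {
    m[i, i + 1L] <- adjacent
    m[i + 1L, i] <- adjacent
  }
  diag(m) <- 1
  m
}

#' Forward-simulate a DEC range history on a dated tree
#'
#' Gillespie simulation of dispersal and extinction along every branch under
#' the anagenetic DEC rates; at each internal node a cladogenetic scenario
#' is drawn uniformly from [enumerate_splits()] of the lineage's current
#' range (or, with `cladogenesis = "vicariance"`, uniformly from the
#' vicariant scenarios only). A run in which any lineage's range becomes
#' empty — or, in vicariance mode, in which a splitting lineage holds a
#' singleton range — is rejected and retried on a fresh random substream.
#' Randomness is counter-based per branch: each (attempt, edge) pair gets
#' its own derived seed, so histories are reproducible edge by edge.
#'
#' @param tree rooted binary dated `phylo`
#' @param regions a `region_set`
#' @param params a [dec_params()] (its `m` may be `NULL` for unconstrained)
#' @param root_range non-empty bitmask with `range_size(root_range) <= K`
#' @param seed integer seed
#' @param max_retries attempts before giving up (default 1000)
#' @param cladogenesis `"dec"` (all scenario types) or `"vicariance"`
#' @return object of class `dec_simulation`: list with `tree`, `regions`,
#'   `params`, `root_range`, `tip_ranges` (a `range_data`), `events`
#'   (data.frame log), `seed`, `attempts`.
#' @export
simulate_dec_history <- function(tree, regions, params, root_range,
                                 seed = 1L, max_retries = 1000L,
                                 cladogenesis = c("dec", "vicariance")) {
  cladogenesis <- match.arg(cladogenesis)
  if (root_range == 0L) stop("root_range must be non-empty")
  if (range_size(root_range) > params$K) stop("root_range larger than K")
  n <- length(regions)
  m <- if (is.null(params$m)) matrix(1, n, n) else params$m
  nt <- ape::Ntip(tree)
  po <- stats::reorder(tree, "postorder")
  edge <- po$edge
  elen <- po$edge.length
  node_child_edges <- split(seq_len(nrow(edge)), edge[, 1L])
  depth <- tree_depths(tree)

  for (attempt in seq_len(max_retries)) {
    res <- sim_attempt(tree, edge, elen, node_child_edges, depth, n, m,
                       params, root_range, seed, attempt, cladogenesis, nt)
    if (!is.null(res)) {
      out <- structure(list(tree = tree, regions = regions, params = params,
                            root_range = root_range,
                            tip_ranges = range_data_from_bits(res$tip_bits,
                                                              regions),
                            events = res$events, seed = seed,
                            attempts = attempt),
                       class = "dec_simulation")
      return(out)
    }
  }
  stop("simulation rejected in all ", max_retries,
       " attempts (acceptance rate 0/", max_retries,
       "); lower e or enlarge the root range")
}

# One rejection-sampling attempt; returns NULL on rejection.
sim_attempt <- function(tree, edge, elen, node_child_edges, depth, n, m,
                        params, root_range, seed, attempt, cladogenesis, nt) {
  nnode <- nt + tree$Nnode
  root <- nt + 1L
  state_in <- rep(NA_integer_, nnode)   # range inherited at top of branch
  state_in[root] <- root_range
  ev <- list()
  add <- function(time, node, kind, before, after, left = NA_integer_,
                  right = NA_integer_, region = NA_integer_,
                  child_left = NA_integer_, child_right = NA_integer_) {
    ev[[length(ev) + 1L]] <<- data.frame(
      time = time, node = node, kind = kind, before = before, after = after,
      left = left, right = right, region = region,
      child_left = child_left, child_right = child_right,
      stringsAsFactors = FALSE)
  }

  # preorder: split at a node, then walk each child branch
  visit <- function(v) {
    R <- state_in[v]
    if (v > nt) {
      sc <- enumerate_splits(R, n)
      if (cladogenesis == "vicariance") {
        sc <- sc[sc$type == "vicariance", , drop = FALSE]
        if (nrow(sc) == 0L) return(FALSE)   # singleton cannot vicariate
      }
      set.seed(derive_seed(seed, attempt, v, 2))
      pick <- sc[sample.int(nrow(sc), 1L), ]
      ce <- node_child_edges[[as.character(v)]]
      ch <- edge[ce, 2L]
      add(depth[v], v, pick$type, before = R, after = NA_integer_,
          left = pick$left, right = pick$right,
          child_left = ch[1L], child_right = ch[2L])
      state_in[ch[1L]] <<- pick$left
      state_in[ch[2L]] <<- pick$right
      for (k in 1:2) {
        if (!walk_branch(ce[k])) return(FALSE)
        if (!visit(ch[k])) return(FALSE)
      }
    }
    TRUE
  }

  walk_branch <- function(eidx) {
    ch <- edge[eidx, 2L]
    len <- elen[eidx]
    t0 <- depth[edge[eidx, 1L]]
    R <- state_in[ch]
    set.seed(derive_seed(seed, attempt, eidx, 1))
    elapsed <- 0
    repeat {
      occ <- range_members(R, n)
      gain_rate <- numeric(0); gain_to <- integer(0)
      if (length(occ) < params$K) {
        for (j in setdiff(seq_len(n), occ)) {
          r <- params$d * sum(m[occ, j])
          if (r > 0) { gain_rate <- c(gain_rate, r); gain_to <- c(gain_to, j) }
        }
      }
      loss_rate <- rep(params$e, length(occ))
      rates <- c(gain_rate, loss_rate)
      tot <- sum(rates)
      if (tot <= 0) break
      dt <- stats::rexp(1, tot)
      if (elapsed + dt > len) break
      elapsed <- elapsed + dt
      pick <- sample.int(length(rates), 1L, prob = rates)
      if (pick <= length(gain_rate)) {
        j <- gain_to[pick]
        newR <- bitwOr(R, bitwShiftL(1L, j - 1L))
        add(t0 + elapsed, ch, "dispersal", before = R, after = newR, region = j)
      } else {
        i <- occ[pick - length(gain_rate)]
        newR <- bitwAnd(R, bitwNot(bitwShiftL(1L, i - 1L)))
        add(t0 + elapsed, ch, "extinction", before = R, after = newR, region = i)
        if (newR == 0L) return(FALSE)  # lineage extinct: reject the run
      }
      R <- newR
    }
    state_in[ch] <<- R
    TRUE
  }

  if (!visit(root)) return(NULL)
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(time = numeric(0), node = integer(0), kind = character(0),
               before = integer(0), after = integer(0), left = integer(0),
               right = integer(0), region = integer(0),
               child_left = integer(0), child_right = integer(0))
  tip_bits <- stats::setNames(state_in[seq_len(nt)], tree$tip.label)
  list(tip_bits = tip_bits, events = events)
}

#' Replay a simulated event log from the root state
#'
#' Re-applies every logged event (cladogenetic scenarios and per-region
#' dispersal/extinction toggles) starting from the root range and returns
#' the tip ranges it produces; used to verify that the log is a complete,
#' faithful record of the simulated history.
#'
#' @param sim a `dec_simulation`
#' @return named integer vector of tip-range bitmasks
#' @export
replay_history <- function(sim) {
  tree <- sim$tree
  nt <- ape::Ntip(tree)
  state <- rep(NA_integer_, nt + tree$Nnode)
  state[nt + 1L] <- sim$root_range
  ev <- sim$events
  for (i in seq_len(nrow(ev))) {
    row <- ev[i, ]
    if (row$kind %in% c("sympatry", "vicariance", "subset_sympatry")) {
      stopifnot(state[row$node] == row$before)
      state[row$child_left] <- row$left
      state[row$child_right] <- row$right
    } else if (row$kind == "dispersal") {
      state[row$node] <- bitwOr(state[row$node],
                                bitwShiftL(1L, row$region - 1L))
    } else if (row$kind == "extinction") {
      state[row$node] <- bitwAnd(state[row$node],
                                 bitwNot(bitwShiftL(1L, row$region - 1L)))
    }
  }
  stats::setNames(state[seq_len(nt)], tree$tip.label)
}

#' @export
print.dec_simulation <- function(x, ...) {
  cat("DEC forward simulation: ", ape::Ntip(x$tree), " tips, ",
      length(x$regions), " regions, d = ", x$params$d, ", e = ", x$params$e,
      ", K = ", x$params$K, "\n", sep = "")
  cat("  events logged:", nrow(x$events),
      "| attempts:", x$attempts, "\n")
  invisible(x)
}

#' Write a deterministic fixture bundle
#'
#' Generates and writes the standard validation fixtures: the 3-tip/2-region
#' worked case, the 4-tip DIVA case (`{A},{A},{B},{C}`), a 30-tip/8-region
#' forward-simulated DEC data set (K = 2, linear-chain geography), and a
#' 100-tree pseudo-posterior of 20-tip Yule trees for relative dating. A
#' `manifest.json` records the MD5 checksum of every file; identical seeds
#' give identical manifests.
#'
#' @param seed integer seed
#' @param dir output directory (created if needed)
#' @return the manifest, invisibly
#' @export
make_fixture_suite <- function(seed, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  put_tree <- function(tree, name) {
    p <- file.path(dir, name); write_tree(tree, p); paths <<- c(paths, p)
  }
  put_ranges <- function(rd, name) {
    p <- file.path(dir, name); write_range_matrix(rd, p); paths <<- c(paths, p)
  }

  # worked 3-tip / 2-region case
  tr3 <- ape::read.tree(text = "((t1:1,t2:1):1,t3:2);")
  rs2 <- region_set(c("A", "B"))
  rd3 <- range_data_from_bits(c(t1 = 1L, t2 = 1L, t3 = 2L), rs2)
  put_tree(tr3, "worked3_tree.nwk"); put_ranges(rd3, "worked3_ranges.tsv")

  # 4-tip DIVA case {A},{A},{B},{C}
  tr4 <- ape::read.tree(text = "(((t1:1,t2:1):1,t3:2):1,t4:3);")
  rs3 <- region_set(c("A", "B", "C"))
  rd4 <- range_data_from_bits(c(t1 = 1L, t2 = 1L, t3 = 2L, t4 = 4L), rs3)
  put_tree(tr4, "diva4_tree.nwk"); put_ranges(rd4, "diva4_ranges.tsv")

  # 30-tip, 8-region DEC simulation (K = 2), AWT-like linear chain
  rs8 <- region_set(paste0("R", 1:8))
  m8 <- linear_chain_constraints(rs8)
  pars <- dec_params(d = 0.1, e = 0.03, K = 2L, m = m8)
  tr30 <- simulate_yule(30L, birth_rate = 0.25, seed = derive_seed(seed, 30))
  sim <- simulate_dec_history(tr30, rs8, pars,
                              root_range = range_encode(c("R4", "R5"), rs8),
                              seed = derive_seed(seed, 31))
  put_tree(tr30, "dec30_tree.nwk")
  put_ranges(sim$tip_ranges, "dec30_ranges.tsv")
  pe <- file.path(dir, "dec30_events.tsv")
  utils::write.table(sim$events, pe, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, pe)

  # 100-tree pseudo-posterior (20-tip Yule trees, shared tip set)
  ptrees <- lapply(1:100, function(i)
    simulate_yule(20L, birth_rate = 0.15, seed = derive_seed(seed, 100, i)))
  pp <- file.path(dir, "posterior100.nwk")
  writeLines(vapply(ptrees, write_tree, character(1)), pp)
  paths <- c(paths, pp)

  manifest <- list(seed = seed,
                   files = as.list(stats::setNames(
                     unname(tools::md5sum(paths)), basename(paths))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
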