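#' DEC model parameters
#'
#' @param d dispersal rate, events per lineage per time unit (Myr on dated
#'   trees), `>= 0`.
#' @param e extinction (range-loss) rate per occupied region per time unit,
#'   `>= 0`.
#' @param K maximum range size (number of regions a lineage may occupy
#'   simultaneously); the DEC state space is restricted to ranges of size
#'   `<= K`.
#' @param m optional |regions| x |regions| matrix of non-negative dispersal
#'   multipliers (`NULL` = unconstrained, all ones). The diagonal is ignored.
#' @return a list of class `dec_params`
#' @export
dec_params <- function(d, e, K, m = NULL) {
  if (!is.finite(d) || d < 0) stop("d must be finite and >= 0")
  if (!is.finite(e) || e < 0) stop("e must be finite and >= 0")
  if (K < 1L) stop("K must be >= 1")
  if (!is.null(m)) {
    if (!is.matrix(m) || nrow(m) != ncol(m)) stop("m must be a square matrix")
    if (any(!is.finite(m)) || any(m < 0)) stop("m entries must be finite, >= 0")
  }
  structure(list(d = d, e = e, K = as.integer(K), m = m), class = "dec_params")
}

#' Build the DEC range state space
#'
#' States are the empty range (index 1) plus every non-empty subset of the
#' region set with at most `K` regions, ordered by size then by bitmask
#' value. With 8 regions and `K = 2` this gives 37 states
#' (1 empty + 8 singletons + 28 pairs).
#'
#' @param regions a [region_set()]
#' @param K maximum range size, `1 <= K <= |regions|`
#' @return a list of class `dec_state_space` with `masks` (integer bitmasks,
#'   empty first), `sizes`, `regions`, `K`.
#' @export
build_state_space <- function(regions, K) {
  n <- length(regions)
  K <- as.integer(K)
  if (K < 1L || K > n) stop("K must be between 1 and ", n)
  all_masks <- seq_len(2^n - 1L)
  sz <- range_size(all_masks)
  keep <- all_masks[sz <= K]
  ord <- order(sz[sz <= K], keep)
  masks <- c(0L, keep[ord])
  structure(list(masks = masks, sizes = c(0L, sz[sz <= K][ord]),
                 regions = regions, K = K),
            class = "dec_state_space")
}

#' @export
print.dec_state_space <- function(x, ...) {
  cat("DEC state space: ", length(x$masks), " states over ",
      length(x$regions), " regions (K = ", x$K, ")\n", sep = "")
  invisible(x)
}

state_index <- function(space, masks) match(masks, space$masks)

#' Anagenetic DEC rate matrix
#'
#' Builds the generator Q of the range CTMC: dispersal expands a range by one
#' region `j` at rate `d * sum_{i in R} m[i, j]` (only while `|R| < K`);
#' extinction drops any occupied region at rate `e`; the empty range is
#' absorbing (a lineage that loses its whole range is globally extinct).
#' Diagonal entries make every row sum to zero.
#'
#' @param space a `dec_state_space`
#' @param params a `dec_params` (its `K` must match the space)
#' @return dense numeric matrix, rows/cols labelled by range
#' @export
build_rate_matrix <- function(space, params) {
  n <- length(space$regions)
  if (!is.null(params$m) && !all(dim(params$m) == n)) {
    stop("constraint matrix dimension does not match the region set")
  }
  if (params$K != space$K) stop("params$K does not match state space K")
  m <- if (is.null(params$m)) matrix(1, n, n) else params$m
  masks <- space$masks
  S <- length(masks)
  Q <- matrix(0, S, S)
  labs <- range_label(masks, space$regions)
  dimnames(Q) <- list(labs, labs)
  for (s in 2:S) {
    R <- masks[s]
    occ <- range_members(R, n)
    # dispersal gains
    if (length(occ) < space$K) {
      for (j in setdiff(seq_len(n), occ)) {
        tgt <- state_index(space, bitwOr(R, bitwShiftL(1L, j - 1L)))
        Q[s, tgt] <- Q[s, tgt] + params$d * sum(m[occ, j])
      }
    }
    # extinction losses
    for (i in occ) {
      tgt <- state_index(space, bitwAnd(R, bitwNot(bitwShiftL(1L, i - 1L))))
      Q[s, tgt] <- Q[s, tgt] + params$e
    }
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

#' Transition probabilities over a branch
#'
#' `P(t) = exp(Q t)`, computed by eigendecomposition when the generator is
#' well-conditioned and by dense scaling-and-squaring ([Matrix::expm()])
#' otherwise. Rows are checked to sum to 1 within `1e-9`, then entries are
#' clipped into `[0, 1]`.
#'
#' @param Q generator from [build_rate_matrix()]
#' @param t branch length, `>= 0`
#' @return row-stochastic matrix
#' @export
transition_matrix <- function(Q, t) {
  if (t < 0) stop("branch length t must be >= 0")
  prop <- make_propagator(Q)
  prop(t)
}

# Returns a function(t) -> P(t). Eigendecomposition of Q is done once so
# per-branch evaluations are two small matrix products; falls back to
# Matrix::expm when Q is defective or the eigenbasis is ill-conditioned.
make_propagator <- function(Q) {
  S <- nrow(Q)
  dn <- dimnames(Q)
  use_eigen <- FALSE
  if (all(Q == 0)) {
    return(function(t) {
      P <- diag(S)
      dimnames(P) <- dn
      P
    })
  }
  # every P(t) is row-checked below, with expm as the per-call fallback, so
  # a defective or ill-conditioned eigenbasis degrades gracefully
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  Vinv <- NULL
  if (!is.null(eg)) {
    Vinv <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vinv)) use_eigen <- TRUE
  }
  check_clip <- function(P) {
    rs <- rowSums(P)
    if (any(abs(rs - 1) > 1e-9)) return(NULL)
    P[P < 0] <- 0
    P[P > 1] <- 1
    dimnames(P) <- dn
    P
  }
  expm_path <- function(t) {
    P <- check_clip(as.matrix(Matrix::expm(Q * t)))
    if (is.null(P)) stop("transition matrix rows deviate from 1 beyond 1e-9")
    P
  }
  if (use_eigen) {
    V <- eg$vectors; lam <- eg$values
    function(t) {
      P <- check_clip(Re(V %*% (exp(lam * t) * Vinv)))
      if (is.null(P)) expm_path(t) else P
    }
  } else {
    expm_path
  }
}

#' Enumerate cladogenetic range-inheritance scenarios
#'
#' DEC cladogenesis: a singleton ancestral range is inherited identically by
#' both daughters (sympatry). A widespread range `R` splits either by
#' vicariance — one daughter gets a single region `{i}`, the other the
#' remainder `R \ {i}` — or by subset sympatry — one daughter gets `{i}`,
#' the other the full `R`. Ordered left/right variants are distinct; after
#' de-duplication all scenarios at a node get equal weight (6 scenarios for
#' `|R| = 2`, `4 |R|` for `|R| > 2`).
#'
#' @param ancestral non-empty range bitmask
#' @param n_regions number of regions in the universe
#' @return data.frame with columns `left`, `right` (bitmasks), `type`
#'   (`sympatry`, `vicariance`, `subset_sympatry`) and `weight` (sums to 1)
#' @export
enumerate_splits <- function(ancestral, n_regions) {
  if (ancestral == 0L) stop("ancestral range must be non-empty")
  occ <- range_members(ancestral, n_regions)
  if (length(occ) == 1L) {
    return(data.frame(left = ancestral, right = ancestral,
                      type = "sympatry", weight = 1,
                      stringsAsFactors = FALSE))
  }
  left <- integer(0); right <- integer(0); type <- character(0)
  for (i in occ) {
    si <- bitwShiftL(1L, i - 1L)
    rest <- bitwAnd(ancestral, bitwNot(si))
    left <- c(left, si, rest, si, ancestral)
    right <- c(right, rest, si, ancestral, si)
    type <- c(type, "vicariance", "vicariance",
              "subset_sympatry", "subset_sympatry")
  }
  key <- paste(left, right)
  keep <- !duplicated(key)
  out <- data.frame(left = left[keep], right = right[keep],
                    type = type[keep], stringsAsFactors = FALSE)
  out$weight <- 1 / nrow(out)
  out
}

# Per-state scenario tables with precomputed state indices, reused by the
# pruning and two-pass algorithms. Element s is NULL for the empty state.
scenario_tables <- function(space) {
  n <- length(space$regions)
  out <- vector("list", length(space$masks))
  for (s in seq_along(space$masks)) {
    if (space$masks[s] == 0L) next
    sc <- enumerate_splits(space$masks[s], n)
    sc$li <- state_index(space, sc$left)
    sc$ri <- state_index(space, sc$right)
    out[[s]] <- sc
  }
  out
}
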