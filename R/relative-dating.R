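# Clade ages and relative-age summaries from posterior samples of dated
# trees. Ages are taken from the MRCA of a clade's tips whether or not the
# clade is monophyletic in a given tree; the monophyly rate is reported
# alongside so the two questions stay separate.

tree_depths <- function(tree) ape::node.depth.edgelength(tree)

check_ultrametric <- function(tree, tol = 1e-6) {
  d <- tree_depths(tree)
  tip_d <- d[seq_len(ape::Ntip(tree))]
  h <- max(tip_d)
  if (h <= 0) stop("tree has zero height")
  if ((max(tip_d) - min(tip_d)) / h > tol) {
    stop("tree is not ultrametric within relative tolerance ", tol,
         " (tip depth spread ", signif(max(tip_d) - min(tip_d), 4), ")")
  }
  h
}

#' Age of a clade's MRCA on a dated tree
#'
#' The age is the height of the MRCA of `tips` above the (contemporaneous)
#' tips, in the tree's time units. The tree must be ultrametric within a
#' relative tolerance of `tol`. Whether the tips form a monophyletic group
#' is recorded in the `"monophyletic"` attribute but not required.
#'
#' @param tree dated ultrametric `phylo`
#' @param tips character vector of >= 2 tip labels
#' @param tol relative ultrametricity tolerance
#' @return numeric age with attribute `monophyletic`
#' @export
node_age <- function(tree, tips, tol = 1e-6) {
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing)) {
    stop("tip(s) not in tree: ", paste(missing, collapse = ", "))
  }
  if (length(tips) < 2L) stop("a clade needs >= 2 tips")
  h <- check_ultrametric(tree, tol)
  mrca <- ape::getMRCA(tree, tips)
  age <- h - tree_depths(tree)[mrca]
  desc <- ape::extract.clade(tree, mrca)$tip.label
  attr(age, "monophyletic") <- setequal(desc, tips)
  age
}

# Empirical quantiles by direct order-statistic interpolation (the standard
# "type 7" estimator, written out so results are exact sort arithmetic):
# h = (n-1)p, q = x_(floor(h)+1) + (h - floor(h)) (x_(floor(h)+2) - x_(floor(h)+1))
empirical_quantiles <- function(x, probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * probs
  lo <- pmin(floor(h), n - 1)
  out <- xs[lo + 1]
  frac <- h - lo
  up <- frac > 0
  out[up] <- xs[lo[up] + 1] + frac[up] * (xs[lo[up] + 2] - xs[lo[up] + 1])
  out
}

#' Absolute and relative clade-age summaries over a posterior tree sample
#'
#' For every tree, computes the MRCA age of each target clade and its ratio
#' to the reference clade's age in that same tree; summarises both with the
#' median, quartiles and the empirical 2.5/97.5% quantiles (a reproducible
#' stand-in for a 95% credible interval), plus the fraction of trees in
#' which each clade is monophyletic.
#'
#' @param trees list of dated ultrametric `phylo` sharing one tip set
#' @param reference named list of length 1, or a character tip vector, for
#'   the reference clade
#' @param targets named list of character tip vectors
#' @param tol ultrametricity tolerance passed to [node_age()]
#' @return object of class `age_summary`: list with `summary` (data.frame:
#'   clade, monophyly_rate, then `age_*` and `rel_*` quantile columns),
#'   `ages` and `rel_ages` (tree x clade matrices), `reference_name`.
#' @export
relative_age_distribution <- function(trees, reference, targets, tol = 1e-6) {
  if (!length(trees)) stop("empty tree set")
  if (is.character(reference)) reference <- list(reference = reference)
  ref_name <- names(reference)[1L]
  ref_tips <- reference[[1L]]
  all_defs <- c(stats::setNames(list(ref_tips), ref_name), targets)
  nt <- length(trees)
  ages <- matrix(NA_real_, nt, length(all_defs),
                 dimnames = list(NULL, names(all_defs)))
  mono <- matrix(NA, nt, length(all_defs),
                 dimnames = list(NULL, names(all_defs)))
  for (i in seq_len(nt)) {
    for (j in seq_along(all_defs)) {
      a <- node_age(trees[[i]], all_defs[[j]], tol = tol)
      ages[i, j] <- a
      mono[i, j] <- attr(a, "monophyletic")
    }
    if (ages[i, ref_name] <= 0) {
      stop("reference clade has age 0 in tree ", i)
    }
  }
  rel <- ages / ages[, ref_name]
  qn <- c("lo95", "q25", "median", "q75", "hi95")
  qs_age <- t(apply(ages, 2L, empirical_quantiles))
  qs_rel <- t(apply(rel, 2L, empirical_quantiles))
  colnames(qs_age) <- paste0("age_", qn)
  colnames(qs_rel) <- paste0("rel_", qn)
  summary <- data.frame(clade = names(all_defs),
                        monophyly_rate = colMeans(mono),
                        qs_age, qs_rel,
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(summary = summary, ages = ages, rel_ages = rel,
                 reference_name = ref_name),
            class = "age_summary")
}

#' @export
print.age_summary <- function(x, ...) {
  cat("Clade ages over", nrow(x$ages), "trees (reference:",
      x$reference_name, ")\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Highest-posterior-density interval of clade ages
#'
#' Shortest interval containing `prob` of the per-tree ages; offered as an
#' alternative to the default empirical quantile interval.
#'
#' @param x numeric vector of per-tree ages
#' @param prob interval mass (default 0.95)
#' @return c(lower, upper)
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- max(2L, ceiling(prob * n))   # points the window must contain
  if (k >= n) return(c(x[1L], x[n]))
  widths <- x[k:n] - x[1:(n - k + 1L)]
  i <- which.min(widths)
  c(x[i], x[i + k - 1L])
}

#' Posterior probability that one clade is younger than another
#'
#' Fraction of trees in which the MRCA age of `clade_x` is strictly smaller
#' than that of `clade_y`.
#'
#' @param trees list of dated ultrametric `phylo`
#' @param clade_x,clade_y character tip vectors
#' @param tol ultrametricity tolerance
#' @return probability in `[0, 1]`
#' @export
split_order_probability <- function(trees, clade_x, clade_y, tol = 1e-6) {
  if (!length(trees)) stop("empty tree set")
  mean(vapply(trees, function(tr) {
    node_age(tr, clade_x, tol) < node_age(tr, clade_y, tol)
  }, logical(1)))
}
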