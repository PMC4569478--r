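# Whole-phylogeny vicariance summary: classify node solutions, sum the
# relative probabilities of vicariant DEC scenarios per node, combine with
# DIVA indicators, and aggregate over an analyst-chosen focal node set.

#' Classify a cladogenetic scenario as vicariance
#'
#' A node solution is vicariant when the ancestral range splits into two
#' mutually exclusive (disjoint, non-empty) daughter ranges — e.g. ancestral
#' `A+B+C` with daughters `A+B` and `C`. Singleton-ancestor sympatry and
#' subset sympatry (overlapping daughters) are not vicariance.
#'
#' @param ancestral,left,right range bitmasks (vectorised)
#' @return logical vector
#' @export
classify_split <- function(ancestral, left, right) {
  range_size(ancestral) > 1L & left != 0L & right != 0L &
    bitwAnd(left, right) == 0L
}

#' Vicariance probability of one node from its DEC scenarios
#'
#' Sums the relative probabilities of the node's scenarios that classify as
#' vicariance. Input probabilities must be normalised (sum to 1 within
#' `1e-9`).
#'
#' @param scenarios data.frame for a single node with columns `ancestral`,
#'   `left`, `right`, `rel_prob` (one node's slice of
#'   [ancestral_split_probs()] output)
#' @return probability in `[0, 1]`
#' @export
dec_node_vicariance_prob <- function(scenarios) {
  tot <- sum(scenarios$rel_prob)
  if (abs(tot - 1) > 1e-9) {
    stop("scenario probabilities are not normalised (sum = ", tot, ")")
  }
  vic <- classify_split(scenarios$ancestral, scenarios$left, scenarios$right)
  min(1, max(0, sum(scenarios$rel_prob[vic])))
}

#' Per-node DEC vicariance probabilities for all internal nodes
#'
#' @param scen a `dec_scenarios` table from [ancestral_split_probs()]
#' @return named numeric vector, names = internal node ids
#' @export
dec_vicariance_probs <- function(scen) {
  vapply(split(scen, scen$node), dec_node_vicariance_prob, numeric(1))
}

#' Resolve clade definitions to focal node ids
#'
#' Each clade definition (a named set of >= 2 tip labels) is resolved to the
#' MRCA of its tips. Definitions resolving to the same node are collapsed
#' with a warning.
#'
#' @param tree a `phylo`
#' @param clade_defs named list of character tip vectors
#' @return named integer vector of node ids
#' @export
select_focal_nodes <- function(tree, clade_defs) {
  if (!length(clade_defs)) stop("empty focal clade set")
  ids <- vapply(names(clade_defs), function(nm) {
    tips <- clade_defs[[nm]]
    missing <- setdiff(tips, tree$tip.label)
    if (length(missing)) {
      stop("clade '", nm, "' names unknown tip(s): ",
           paste(missing, collapse = ", "))
    }
    if (length(tips) < 2L) stop("clade '", nm, "' has fewer than 2 tips")
    ape::getMRCA(tree, tips)
  }, integer(1))
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)]
    warning("clade definitions collapse to the same node: ",
            paste(names(ids)[ids %in% dup], collapse = ", "))
    ids <- ids[!duplicated(ids)]
  }
  ids
}

#' Aggregate per-node vicariance evidence over a focal node set
#'
#' Counts focal nodes whose DEC vicariance probability exceeds
#' `dec_threshold` (default 0.5: vicariance is the most likely solution
#' class) and whose DIVA majority indicator is true; reports counts,
#' fractions, and a per-node table.
#'
#' @param dec_probs named numeric vector from [dec_vicariance_probs()]
#' @param diva_scores data.frame from [score_node_vicariance_diva()]
#' @param focal_nodes named integer vector from [select_focal_nodes()]
#' @param dec_threshold probability cut for calling a DEC node vicariant
#' @return object of class `vicariance_summary`: list with `table`
#'   (per-node), `dec_count`, `diva_count`, `n_focal`, `dec_fraction`,
#'   `diva_fraction`, `dec_threshold`.
#' @export
aggregate_vicariance <- function(dec_probs, diva_scores, focal_nodes,
                                 dec_threshold = 0.5) {
  if (!length(focal_nodes)) stop("empty focal node set")
  have_dec <- names(dec_probs)
  have_diva <- as.character(diva_scores$node)
  miss <- setdiff(as.character(focal_nodes), union(have_dec, have_diva))
  if (length(miss)) {
    stop("focal node(s) not found in the analysis tree: ",
         paste(miss, collapse = ", "))
  }
  key <- as.character(focal_nodes)
  dp <- dec_probs[key]
  ds <- diva_scores[match(focal_nodes, diva_scores$node), , drop = FALSE]
  tab <- data.frame(
    clade = if (is.null(names(focal_nodes))) key else names(focal_nodes),
    node = as.integer(focal_nodes),
    dec_vic_prob = unname(dp),
    dec_flag = unname(dp > dec_threshold),
    diva_freq = ds$frequency,
    diva_flag = ds$vicariant,
    diva_ambiguous = ds$ambiguous,
    stringsAsFactors = FALSE)
  n <- nrow(tab)
  structure(list(table = tab,
                 dec_count = sum(tab$dec_flag, na.rm = TRUE),
                 diva_count = sum(tab$diva_flag, na.rm = TRUE),
                 n_focal = n,
                 dec_fraction = sum(tab$dec_flag, na.rm = TRUE) / n,
                 diva_fraction = sum(tab$diva_flag, na.rm = TRUE) / n,
                 dec_threshold = dec_threshold),
            class = "vicariance_summary")
}

#' @export
print.vicariance_summary <- function(x, ...) {
  cat("Vicariance summary over", x$n_focal, "focal nodes\n")
  cat(sprintf("  DEC  (prob > %g): %d/%d (%.2f)\n", x$dec_threshold,
              x$dec_count, x$n_focal, x$dec_fraction))
  cat(sprintf("  DIVA (majority) : %d/%d (%.2f)\n",
              x$diva_count, x$n_focal, x$diva_fraction))
  invisible(x)
}

#' Write a vicariance summary as TSV
#'
#' Per-node rows followed by footer rows holding counts and fractions.
#'
#' @param x a `vicariance_summary`
#' @param path output file
#' @return the path, invisibly
#' @export
write_vicariance_summary <- function(x, path) {
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  footer <- c(sprintf("# dec_count\t%d\tof\t%d\tfraction\t%.6f",
                      x$dec_count, x$n_focal, x$dec_fraction),
              sprintf("# diva_count\t%d\tof\t%d\tfraction\t%.6f",
                      x$diva_count, x$n_focal, x$diva_fraction))
  cat(footer, file = path, sep = "\n", append = TRUE)
  invisible(path)
}
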