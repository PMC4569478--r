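#' Read a rooted phylogeny from Newick or Nexus
#'
#' Thin, validating wrapper around [ape::read.tree()] / [ape::read.nexus()].
#' The returned tree is an ape `phylo` object; node numbering follows ape's
#' deterministic convention (tips `1..n` in input order, internal nodes
#' `n+1..2n-1`), so two reads of the same file give identical id-to-clade
#' maps. Square-bracket comments and quoted labels are tolerated and
#' stripped by the underlying parsers.
#'
#' @param source a file path, or (for Newick) a character scalar holding the
#'   tree text itself.
#' @param dialect `"newick"` or `"nexus"`.
#' @param polytomy what to do with non-binary internal nodes: `"reject"`
#'   (default, error) or `"resolve"` (deterministic zero-length binary
#'   expansion via [ape::multi2di()], with a warning).
#' @return a rooted binary `phylo` with branch lengths.
#' @export
read_tree <- function(source, dialect = c("newick", "nexus"),
                      polytomy = c("reject", "resolve")) {
  dialect <- match.arg(dialect)
  polytomy <- match.arg(polytomy)
  is_path <- length(source) == 1L && !grepl("[(;]", source) && file.exists(source)
  tr <- if (dialect == "nexus") {
    if (!is_path) stop("nexus input must be a file path")
    tryCatch(ape::read.nexus(source), error = function(e) {
      stop("failed to parse nexus file '", source, "': ", conditionMessage(e))
    })
  } else {
    txt <- if (is_path) paste(readLines(source, warn = FALSE), collapse = "") else source
    check_newick_balance(txt)
    tryCatch(ape::read.tree(text = txt), error = function(e) {
      stop("failed to parse newick: ", conditionMessage(e))
    })
  }
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree, found ", length(tr))
    tr <- tr[[1L]]
  }
  if (is.null(tr) || !inherits(tr, "phylo")) stop("failed to parse tree input")
  validate_phylogeny(tr, polytomy = polytomy)
}

# Cheap structural check so unbalanced newick reports a character offset,
# which ape's parser does not.
check_newick_balance <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("newick parse error: unbalanced ')' at character offset ", i)
      }
    }
  }
  if (depth != 0L) {
    stop("newick parse error: ", depth, " unclosed '(' by character offset ",
         length(chars))
  }
  invisible(TRUE)
}

validate_phylogeny <- function(tr, polytomy = "reject", require_lengths = TRUE) {
  if (!ape::is.rooted(tr)) {
    stop("tree is unrooted; root it (e.g. with an outgroup) before analysis")
  }
  if (require_lengths && is.null(tr$edge.length)) {
    stop("tree has no branch lengths; dated branch lengths are required")
  }
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    stop("negative branch length(s) found")
  }
  if (!ape::is.binary(tr)) {
    if (polytomy == "reject") {
      stop("tree contains polytomies; rerun with polytomy = \"resolve\" ",
           "to expand them into zero-length binary nodes")
    }
    warning("polytomies resolved arbitrarily into zero-length binary nodes")
    tr <- ape::multi2di(tr, random = FALSE)
  }
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  tr
}

#' Write a phylogeny to Newick
#' @param tree a `phylo`
#' @param path output file; if `NULL`, the Newick string is returned
#' @return the path (invisibly) or the Newick string
#' @export
write_tree <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read a set of dated trees sharing one tip set
#'
#' Carrier for posterior samples of dated trees (e.g. a BEAST trees file).
#' Nexus `TRANSLATE` blocks are resolved by [ape::read.nexus()].
#'
#' @param source file path: newline-delimited Newick or a Nexus TREES block.
#' @param dialect `"newick-lines"` or `"nexus-trees"`.
#' @param discard_first drop this many leading trees (burn-in).
#' @return a list of `phylo` objects in file order.
#' @export
read_tree_set <- function(source, dialect = c("newick-lines", "nexus-trees"),
                          discard_first = 0L) {
  dialect <- match.arg(dialect)
  trees <- if (dialect == "nexus-trees") {
    ape::read.nexus(source)
  } else {
    ape::read.tree(source)
  }
  if (inherits(trees, "phylo")) trees <- list(trees)
  # extract through `[[` so a compressed multiPhylo's shared TipLabel
  # attribute is restored onto each tree
  trees <- lapply(seq_along(trees), function(i) trees[[i]])
  if (length(trees) == 0L) stop("no trees found in '", source, "'")
  if (discard_first > 0L) {
    if (discard_first >= length(trees)) stop("discard_first removes every tree")
    trees <- trees[-seq_len(discard_first)]
  }
  ref <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    tips <- sort(trees[[i]]$tip.label)
    if (!identical(tips, ref)) {
      diff <- c(setdiff(tips, ref), setdiff(ref, tips))
      stop("tree ", i, " has a different tip set; offending labels: ",
           paste(diff, collapse = ", "))
    }
  }
  lapply(trees, validate_phylogeny, polytomy = "reject", require_lengths = TRUE)
}

#' Read a taxon-by-region presence/absence matrix
#'
#' Expects TSV: a header row whose fields after the first are the region
#' codes (their order fixes the bit encoding), a first column of taxon names,
#' and 0/1 cells.
#'
#' @param source path to the TSV file.
#' @return a list of class `range_data` with elements `regions` (a
#'   [region_set()]), `presence` (integer 0/1 matrix, taxa in rows) and
#'   `ranges` (named integer vector of tip-range bitmasks).
#' @export
read_range_matrix <- function(source) {
  df <- utils::read.delim(source, header = TRUE, check.names = FALSE,
                          colClasses = "character", sep = "\t")
  if (ncol(df) < 2L) stop("range matrix needs a taxon column plus >= 1 region column")
  taxa <- trimws(df[[1L]])
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon name(s): ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  regions <- region_set(colnames(df)[-1L])
  pres <- as.matrix(df[, -1L, drop = FALSE])
  bad <- which(!(pres %in% c("0", "1")))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(pres))
    stop("non-0/1 cell at taxon '", taxa[rc[1L]], "', region '",
         unclass(regions)[rc[2L]], "': '", pres[bad[1L]], "'")
  }
  storage.mode(pres) <- "integer"
  rownames(pres) <- taxa
  colnames(pres) <- unclass(regions)
  empty <- rowSums(pres) == 0L
  if (any(empty)) {
    stop("taxon with empty range (all-zero row): ",
         paste(taxa[empty], collapse = ", "))
  }
  new_range_data(regions, pres)
}

new_range_data <- function(regions, presence) {
  ranges <- apply(presence, 1L, function(row) {
    range_encode(unclass(regions)[row == 1L], regions)
  })
  structure(list(regions = regions, presence = presence, ranges = ranges),
            class = "range_data")
}

#' Build range data directly from tip-range bitmasks
#' @param ranges named integer vector (names = taxa) of range bitmasks
#' @param regions the `region_set`
#' @return a `range_data` object
#' @export
range_data_from_bits <- function(ranges, regions) {
  if (is.null(names(ranges)) || anyDuplicated(names(ranges))) {
    stop("ranges must be uniquely named by taxon")
  }
  if (any(ranges == 0L)) {
    stop("observed tip ranges must be non-empty: ",
         paste(names(ranges)[ranges == 0L], collapse = ", "))
  }
  n <- length(regions)
  pres <- t(vapply(ranges, function(b) {
    as.integer(bitwAnd(b, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
  }, integer(n)))
  rownames(pres) <- names(ranges)
  colnames(pres) <- unclass(regions)
  new_range_data(regions, pres)
}

#' @export
print.range_data <- function(x, ...) {
  cat("Range data: ", nrow(x$presence), " taxa x ", length(x$regions),
      " regions (", paste(unclass(x$regions), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Write a range matrix back to TSV
#' @param rd a `range_data`
#' @param path output file
#' @param taxon_col header for the taxon column
#' @return the path, invisibly
#' @export
write_range_matrix <- function(rd, path, taxon_col = "taxon") {
  df <- data.frame(rownames(rd$presence), rd$presence,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(taxon_col, unclass(rd$regions))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square dispersal-constraint multiplier matrix
#'
#' TSV with region codes as header and first column; entries are non-negative
#' multipliers on the dispersal rate between region pairs. The diagonal is
#' ignored by the model.
#'
#' @param source path to the TSV file
#' @param regions the analysis `region_set`; rows/columns are matched (and
#'   reordered if necessary) to this order.
#' @return a numeric |regions| x |regions| matrix
#' @export
read_constraint_matrix <- function(source, regions) {
  df <- utils::read.delim(source, header = TRUE, check.names = FALSE, sep = "\t")
  rn <- trimws(as.character(df[[1L]]))
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- rn
  if (!setequal(rownames(m), unclass(regions)) ||
      !setequal(colnames(m), unclass(regions))) {
    stop("constraint matrix rows/columns do not match the region set")
  }
  m <- m[unclass(regions), unclass(regions), drop = FALSE]
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("constraint multipliers must be finite and >= 0")
  }
  m
}

#' All-ones constraint matrix (unconstrained dispersal)
#' @param regions a `region_set`
#' @return numeric matrix of ones with region dimnames
#' @export
constraint_matrix_ones <- function(regions) {
  n <- length(regions)
  matrix(1, n, n, dimnames = list(unclass(regions), unclass(regions)))
}

#' Cross-check a tree against a range matrix
#'
#' @param tree a `phylo`
#' @param rd a `range_data`
#' @return a list of class `validation_report` with `ok`,
#'   `missing_in_matrix` (tree tips without range rows) and
#'   `missing_in_tree` (matrix taxa absent from the tree).
#' @export
validate_inputs <- function(tree, rd) {
  tips <- tree$tip.label
  taxa <- rownames(rd$presence)
  rep <- list(ok = setequal(tips, taxa) && length(tips) == length(taxa),
              missing_in_matrix = setdiff(tips, taxa),
              missing_in_tree = setdiff(taxa, tips))
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) {
    cat("OK: tree tips and range-matrix taxa match 1:1\n")
  } else {
    if (length(x$missing_in_matrix)) {
      cat("Tips missing from range matrix:",
          paste(x$missing_in_matrix, collapse = ", "), "\n")
    }
    if (length(x$missing_in_tree)) {
      cat("Matrix taxa missing from tree:",
          paste(x$missing_in_tree, collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' Read clade definitions from TSV or JSON
#'
#' TSV format: two columns `clade` and `tip`, one row per (clade, tip) pair.
#' JSON format: an object mapping clade name to an array of tip labels.
#'
#' @param source path to the definitions file
#' @return a named list of character tip vectors
#' @export
read_clade_definitions <- function(source) {
  defs <- if (grepl("\\.json$", source, ignore.case = TRUE)) {
    lapply(jsonlite::read_json(source, simplifyVector = TRUE), as.character)
  } else {
    df <- utils::read.delim(source, header = TRUE, check.names = FALSE,
                            colClasses = "character", sep = "\t")
    if (!all(c("clade", "tip") %in% colnames(df))) {
      stop("clade definition TSV needs columns 'clade' and 'tip'")
    }
    split(trimws(df$tip), df$clade)
  }
  bad <- names(defs)[vapply(defs, length, integer(1)) < 2L]
  if (length(bad)) {
    stop("clade definition(s) with fewer than 2 tips: ",
         paste(bad, collapse = ", "))
  }
  defs
}
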