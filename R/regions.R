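#' Define an ordered set of biogeographic regions
#'
#' A region set fixes the universe and column order of every range in an
#' analysis. Ranges are encoded as integer bitmasks over the region positions,
#' so the order chosen here is binding for the lifetime of the analysis: bit
#' `i - 1` of a range corresponds to `codes[i]`.
#'
#' @param codes character vector of short region labels (e.g. the eight
#'   Australian Wet Tropics subregions `AU, CU, KU, LU, WU, BK, FU, CY`).
#'   Labels are whitespace-trimmed and case-sensitive.
#' @return an object of class `region_set` (a character vector of codes).
#' @examples
#' rs <- region_set(c("A", "B", "C"))
#' range_encode(c("A", "C"), rs)
#' @export
region_set <- function(codes) {
  codes <- trimws(as.character(codes))
  if (length(codes) == 0L) stop("region set must contain at least one region")
  if (any(!nzchar(codes))) stop("region codes must be non-empty strings")
  if (anyDuplicated(codes)) {
    stop("duplicate region codes: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "))
  }
  # R integers are 32-bit signed; bit 31 is the sign bit, so cap at 30.
  if (length(codes) > 30L) {
    stop("at most 30 regions are supported (integer bitmask capacity)")
  }
  structure(codes, class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("Region set (", length(x), " regions): ",
      paste(unclass(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of regions in a region set
#' @param regions a `region_set`
#' @return integer count
#' @export
n_regions <- function(regions) length(regions)

#' Encode a set of region codes as a range bitmask
#'
#' @param codes character vector of region codes (possibly empty)
#' @param regions the `region_set` fixing bit positions
#' @return integer bitmask; `0L` is the empty range
#' @export
range_encode <- function(codes, regions) {
  if (length(codes) == 0L) return(0L)
  pos <- match(codes, unclass(regions))
  if (anyNA(pos)) {
    stop("unknown region code(s): ", paste(codes[is.na(pos)], collapse = ", "))
  }
  bits <- 0L
  for (p in unique(pos)) bits <- bitwOr(bits, bitwShiftL(1L, p - 1L))
  bits
}

#' Decode a range bitmask into region codes
#' @param bits integer bitmask
#' @param regions the `region_set`
#' @return character vector of occupied region codes, in region-set order
#' @export
range_decode <- function(bits, regions) {
  unclass(regions)[range_members(bits, length(regions))]
}

#' Indices of regions present in a range
#' @param bits integer bitmask
#' @param n number of regions in the universe
#' @return integer vector of 1-based region positions
#' @export
range_members <- function(bits, n) {
  which(bitwAnd(bits, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
}

#' Number of occupied regions in one or more ranges
#' @param bits integer vector of bitmasks
#' @return integer vector of popcounts
#' @export
range_size <- function(bits) {
  vapply(bits, function(b) {
    k <- 0L
    while (b != 0L) {
      k <- k + bitwAnd(b, 1L)
      b <- bitwShiftR(b, 1L)
    }
    k
  }, integer(1))
}

#' Human-readable label for a range bitmask
#' @param bits integer vector of bitmasks
#' @param regions the `region_set`
#' @param empty label to use for the empty range
#' @return character vector like `"A+C"`
#' @export
range_label <- function(bits, regions, empty = "0") {
  vapply(bits, function(b) {
    if (b == 0L) empty else paste(range_decode(b, regions), collapse = "+")
  }, character(1))
}

# All non-empty subsets of `of` (a bitmask), as an integer vector.
# Enumerates submasks with the standard (s - 1) & of descent.
submasks_of <- function(of) {
  if (of == 0L) return(integer(0))
  out <- integer(0)
  s <- of
  repeat {
    out <- c(out, s)
    if (s == 0L) break
    s <- bitwAnd(s - 1L, of)
    if (s == 0L) break
  }
  sort(out)
}
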