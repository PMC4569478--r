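# Shared in-code fixtures.

fix_tree3 <- function() ape::read.tree(text = "((t1:1,t2:1):1,t3:2);")

fix_rd3 <- function() {
  range_data_from_bits(c(t1 = 1L, t2 = 1L, t3 = 2L), region_set(c("A", "B")))
}

fix_tree4 <- function() ape::read.tree(text = "(((t1:1,t2:1):1,t3:2):1,t4:3);")

fix_rd4 <- function() {
  range_data_from_bits(c(t1 = 1L, t2 = 1L, t3 = 2L, t4 = 4L),
                       region_set(c("A", "B", "C")))
}

# ultrametric pectinate (caterpillar) tree with unit internode spacing
caterpillar_tree <- function(n) {
  s <- "(t1:1,t2:1)"
  for (k in 3:n) s <- sprintf("(%s:1,t%d:%d)", s, k, k - 1L)
  ape::read.tree(text = paste0(s, ";"))
}

write_tsv_fixture <- function(lines) {
  p <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, p)
  p
}
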