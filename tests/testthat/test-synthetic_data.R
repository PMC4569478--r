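test_that("Yule simulation is ultrametric, sized and deterministic", {
  tr <- simulate_yule(2, 1, seed = 3)
  expect_equal(ape::Ntip(tr), 2)
  d <- ape::node.depth.edgelength(tr)
  expect_equal(d[1], d[2])

  a <- simulate_yule(15, 0.7, seed = 11)
  b <- simulate_yule(15, 0.7, seed = 11)
  expect_identical(write_tree(a), write_tree(b))
  expect_false(identical(write_tree(a), write_tree(simulate_yule(15, 0.7, 12))))
  expect_true(ape::is.ultrametric(a))
  expect_error(simulate_yule(1, 1), "n_tips")
  expect_error(simulate_yule(5, 0), "birth_rate")
})

test_that("Yule root ages match the closed-form expectation", {
  # root age = sum of Exp(k*lambda) waits while k lineages exist, k = 2..n
  # (the k = n stretch ends at the sampled present): E = (1/lambda) sum 1/k
  n <- 8; lambda <- 1; reps <- 600
  ages <- vapply(seq_len(reps), function(i) {
    max(ape::node.depth.edgelength(simulate_yule(n, lambda, seed = 5000 + i)))
  }, numeric(1))
  expected <- sum(1 / (2:n)) / lambda
  se <- stats::sd(ages) / sqrt(reps)
  expect_lt(abs(mean(ages) - expected), 3 * se)
})

test_that("degenerate rate settings freeze ranges as stated", {
  tr <- simulate_yule(8, 0.5, seed = 14)
  rs <- region_set(LETTERS[1:3])
  sim0 <- simulate_dec_history(tr, rs, dec_params(0, 0, 3),
                               root_range = 1L, seed = 9)
  expect_identical(nrow(sim0$events[!(sim0$events$kind %in%
    c("sympatry", "vicariance", "subset_sympatry")), ]), 0L)
  expect_true(all(sim0$tip_ranges$ranges == 1L))

  # d = 0, singleton root, e > 0: any accepted run kept every tip at the root
  # range (a loss would empty the range and force rejection)
  sim_e <- simulate_dec_history(tr, rs, dec_params(0, 0.05, 3),
                                root_range = 2L, seed = 10)
  expect_true(all(sim_e$tip_ranges$ranges == 2L))

  expect_error(simulate_dec_history(tr, rs, dec_params(0, 0, 3), 0L),
               "non-empty")
})

test_that("event-log replay reproduces tip ranges bit-for-bit", {
  rs <- region_set(paste0("R", 1:5))
  pars <- dec_params(0.15, 0.04, 3, linear_chain_constraints(rs))
  for (i in 1:5) {
    tr <- simulate_yule(12, 0.4, seed = 200 + i)
    sim <- simulate_dec_history(tr, rs, pars,
                                root_range = range_encode(c("R2", "R3"), rs),
                                seed = 300 + i)
    rep <- replay_history(sim)
    expect_identical(rep[names(sim$tip_ranges$ranges)], sim$tip_ranges$ranges)
  }
})

test_that("dispersal event counts match an independent Monte-Carlo oracle", {
  # independent straightforward implementation: per-branch thinning-free
  # Gillespie written against the rate definitions, no shared code
  oracle_counts <- function(tree, n, d, e, K, root, nrep) {
    counts <- numeric(nrep)
    nt <- ape::Ntip(tree)
    for (r in seq_len(nrep)) {
      total <- 0L
      walk <- function(node, range) {
        sp <- oracle_splits(range, n)
        pick <- sp[sample.int(nrow(sp), 1), ]
        kids <- tree$edge[tree$edge[, 1] == node, 2]
        parts <- c(pick$left, pick$right)
        for (k in 1:2) {
          ch <- kids[k]
          len <- tree$edge.length[which(tree$edge[, 2] == ch)]
          R <- parts[k]
          t <- 0
          repeat {
            occ <- which(bitwAnd(R, 2L^(0:(n - 1))) != 0L)
            gr <- if (length(occ) < K) d * (n - length(occ)) * length(occ) else 0
            lr <- e * length(occ)
            if (gr + lr <= 0) break
            t <- t + stats::rexp(1, gr + lr)
            if (t > len) break
            if (stats::runif(1) < gr / (gr + lr)) {
              total <<- total + 1L
              j <- sample(setdiff(seq_len(n), occ), 1)
              R <- bitwOr(R, 2L^(j - 1))
            } else {
              i <- if (length(occ) == 1) occ else sample(occ, 1)
              R <- bitwAnd(R, bitwNot(2L^(i - 1)))
              if (R == 0L) break
            }
          }
          if (R != 0L && ch > nt) walk(ch, R)
        }
      }
      walk(nt + 1L, root)
      counts[r] <- total
    }
    counts
  }
  tr <- caterpillar_tree(6)
  n <- 3; d <- 0.05; e <- 0.0
  set.seed(77)
  ocounts <- oracle_counts(tr, n, d, e, K = 3, root = 7L, nrep = 400)
  pars <- dec_params(d, e, 3)
  rs <- region_set(LETTERS[1:3])
  pcounts <- vapply(1:400, function(i) {
    sim <- simulate_dec_history(tr, rs, pars, root_range = 7L, seed = 9000 + i)
    sum(sim$events$kind == "dispersal")
  }, numeric(1))
  se <- sqrt(stats::var(ocounts) / 400 + stats::var(pcounts) / 400)
  expect_lt(abs(mean(ocounts) - mean(pcounts)), 3 * se)
})

test_that("vicariance-only mode draws only vicariant splits", {
  rs <- region_set(LETTERS[1:5])
  tr <- caterpillar_tree(5)
  sim <- simulate_dec_history(tr, rs, dec_params(0.001, 1e-4, 5),
                              root_range = 31L, seed = 4,
                              cladogenesis = "vicariance")
  clado <- sim$events[sim$events$kind %in%
                        c("sympatry", "vicariance", "subset_sympatry"), ]
  expect_true(all(clado$kind == "vicariance"))
  expect_true(all(bitwAnd(clado$left, clado$right) == 0L))
})

test_that("fixture bundles are deterministic, valid and refittable", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- make_fixture_suite(101, d1)
  m2 <- make_fixture_suite(101, d2)
  expect_identical(m1$files, m2$files)

  rd <- read_range_matrix(file.path(d1, "dec30_ranges.tsv"))
  expect_identical(length(rd$regions), 8L)
  tr <- read_tree(file.path(d1, "dec30_tree.nwk"))
  expect_true(validate_inputs(tr, rd)$ok)

  trees <- read_tree_set(file.path(d1, "posterior100.nwk"))
  expect_length(trees, 100)

  # MLE property on the generated data set: fitted loglik >= truth loglik
  fit <- fit_dec(tr, rd, K = 2, m = linear_chain_constraints(rd$regions))
  truth <- dec_loglik(tr, rd, dec_params(0.1, 0.03, 2,
                                         linear_chain_constraints(rd$regions)))
  expect_gte(fit$loglik, truth)
})
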