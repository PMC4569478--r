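test_that("state space enumerates all and only ranges up to K", {
  rs3 <- region_set(c("A", "B", "C"))
  expect_length(build_state_space(rs3, 3)$masks, 8)   # full powerset incl. empty
  expect_length(build_state_space(rs3, 2)$masks, 7)   # empty + 3 + 3
  rs8 <- region_set(paste0("R", 1:8))
  expect_length(build_state_space(rs8, 2)$masks, 37)  # 1 + 8 + 28
  expect_error(build_state_space(rs3, 0), "between")
  expect_error(build_state_space(rs3, 4), "between")
  sp <- build_state_space(rs3, 2)
  expect_identical(sp$masks[1], 0L)
  expect_true(all(diff(order(sp$sizes, sp$masks)) == 1))  # deterministic order
})

test_that("rate matrix follows the DEC generator definition", {
  rs <- region_set(c("A", "B"))
  sp <- build_state_space(rs, 2)
  Q <- build_rate_matrix(sp, dec_params(0.1, 0.05, 2))
  expect_equal(Q["A", "A+B"], 0.1)
  expect_equal(Q["A", "0"], 0.05)
  expect_equal(Q["A", "A"], -0.15)
  expect_equal(unname(Q["0", ]), rep(0, 4))          # empty absorbing
  expect_lt(max(abs(rowSums(Q))), 1e-12)

  m <- matrix(1, 2, 2); m[1, 2] <- 0
  Qc <- build_rate_matrix(sp, dec_params(0.1, 0.05, 2, m))
  expect_equal(Qc["A", "A+B"], 0)                    # constraint zeroes dispersal
  expect_gt(Qc["B", "A+B"], 0)
})

test_that("transition matrices are row-stochastic and match closed forms", {
  rs <- region_set(c("A", "B", "C"))
  sp <- build_state_space(rs, 3)
  Q <- build_rate_matrix(sp, dec_params(0.3, 0.2, 3))
  expect_equal(transition_matrix(Q, 0), diag(8), ignore_attr = TRUE)
  Q0 <- build_rate_matrix(sp, dec_params(0, 0, 3))
  expect_equal(transition_matrix(Q0, 5), diag(8), ignore_attr = TRUE)
  expect_error(transition_matrix(Q, -1), ">= 0")

  # pure-death single region: P(A -> A) = exp(-e t)
  sp1 <- build_state_space(region_set("A"), 1)
  Q1 <- build_rate_matrix(sp1, dec_params(0, 0.05, 1))
  expect_equal(transition_matrix(Q1, 2)["A", "A"], exp(-0.1), tolerance = 1e-9)

  set.seed(99)
  for (i in 1:5) {
    d <- runif(1, 0, 1); e <- runif(1, 0, 1); t <- runif(1, 0, 10)
    P <- transition_matrix(build_rate_matrix(sp, dec_params(d, e, 3)), t)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
    expect_true(all(P >= 0 & P <= 1))
  }
})

test_that("split enumeration matches the de-duplicated scenario grammar", {
  s1 <- enumerate_splits(1L, 3)
  expect_identical(nrow(s1), 1L)
  expect_identical(s1$type, "sympatry")
  expect_equal(s1$weight, 1)

  s2 <- enumerate_splits(3L, 2)          # {A,B}
  expect_identical(nrow(s2), 6L)
  expect_equal(unique(s2$weight), 1 / 6)
  got <- sort(paste(s2$left, s2$right))
  expect_identical(got, sort(c("1 2", "2 1", "1 3", "3 1", "2 3", "3 2")))

  s3 <- enumerate_splits(7L, 3)          # {A,B,C}
  expect_identical(nrow(s3), 12L)
  expect_identical(sum(s3$type == "vicariance"), 6L)
  expect_identical(sum(s3$type == "subset_sympatry"), 6L)
  expect_equal(sum(s3$weight), 1)

  expect_error(enumerate_splits(0L, 3), "non-empty")
})

test_that("degenerate likelihoods take their closed-form values", {
  rs <- region_set(c("A", "B"))
  tr <- ape::read.tree(text = "(t1:1,t2:1);")
  rd <- range_data_from_bits(c(t1 = 1L, t2 = 1L), rs)
  expect_equal(dec_loglik(tr, rd, dec_params(0, 0, 2)), 0)

  rd_big <- range_data_from_bits(c(t1 = 3L, t2 = 1L), rs)
  expect_error(dec_loglik(tr, rd_big, dec_params(0.1, 0.1, 1)), "t1")
})

test_that("pruning equals the explicit-history oracle on the 3-tip fixture", {
  bits <- c(t1 = 1L, t2 = 1L, t3 = 2L)
  ll <- dec_loglik(fix_tree3(), fix_rd3(), dec_params(0.2, 0.1, 2))
  oracle <- log(oracle_dec_lik(fix_tree3(), bits, 2, 0.2, 0.1, 2))
  expect_equal(ll, oracle, tolerance = 1e-10)
})

test_that("likelihood is invariant to region relabelling", {
  tr <- fix_tree4()
  rs <- region_set(c("A", "B", "C"))
  bits <- c(t1 = 1L, t2 = 3L, t3 = 2L, t4 = 4L)
  m <- matrix(c(1, 0.5, 0.2, 0.5, 1, 0.8, 0.2, 0.8, 1), 3, 3)
  p <- dec_params(0.15, 0.05, 3, m)
  ll <- dec_loglik(tr, range_data_from_bits(bits, rs), p)
  # permute regions (A,B,C) -> (C,A,B): bit i -> bit perm[i]
  perm <- c(3L, 1L, 2L)
  permute_bits <- function(b) {
    out <- 0L
    for (i in 1:3) if (bitwAnd(b, bitwShiftL(1L, i - 1L)) != 0L)
      out <- bitwOr(out, bitwShiftL(1L, perm[i] - 1L))
    out
  }
  bits_p <- vapply(bits, permute_bits, integer(1))
  m_p <- m
  for (i in 1:3) for (j in 1:3) m_p[perm[i], perm[j]] <- m[i, j]
  ll_p <- dec_loglik(tr, range_data_from_bits(bits_p, rs),
                     dec_params(0.15, 0.05, 3, m_p))
  expect_equal(ll, ll_p, tolerance = 1e-12)
})

test_that("zeroed dispersal multipliers never open new transitions", {
  rs <- region_set(c("A", "B", "C"))
  sp <- build_state_space(rs, 3)
  m <- matrix(1, 3, 3)
  P_free <- transition_matrix(build_rate_matrix(sp, dec_params(0.2, 0.1, 3, m)), 2)
  m0 <- m; m0[1, 2] <- 0
  P_con <- transition_matrix(build_rate_matrix(sp, dec_params(0.2, 0.1, 3, m0)), 2)
  from_A <- which(sp$masks == 1L)
  expect_true(all(which(P_con[from_A, ] > 1e-12) %in%
                    which(P_free[from_A, ] > 1e-12)))
})

test_that("ancestral split probabilities normalise and mirror symmetric data", {
  rs <- region_set(c("A", "B"))
  tr <- ape::read.tree(text = "(t1:1,t2:1);")
  rd <- range_data_from_bits(c(t1 = 1L, t2 = 2L), rs)
  scen <- ancestral_split_probs(tr, rd, dec_params(0.2, 0.1, 2))
  expect_equal(sum(scen$rel_prob), 1, tolerance = 1e-9)
  # mirror symmetry: swapping the tip data maps every scenario to its
  # left/right mirror with identical probability (equal branch lengths,
  # symmetric dispersal)
  rd_sw <- range_data_from_bits(c(t1 = 2L, t2 = 1L), rs)
  scen_sw <- ancestral_split_probs(tr, rd_sw, dec_params(0.2, 0.1, 2))
  pick <- function(s, l, r) s$rel_prob[s$ancestral == 3L &
                                         s$left == l & s$right == r]
  expect_equal(pick(scen, 1L, 2L), pick(scen_sw, 2L, 1L), tolerance = 1e-12)
  expect_equal(pick(scen, 3L, 2L), pick(scen_sw, 2L, 3L), tolerance = 1e-12)
  # every vicariance-type scenario has disjoint daughters (structural)
  vic <- scen[scen$type == "vicariance", ]
  expect_true(all(bitwAnd(vic$left, vic$right) == 0L))
})

test_that("ancestral split probabilities equal constrained oracle ratios", {
  bits <- c(t1 = 1L, t2 = 1L, t3 = 2L)
  p <- dec_params(0.2, 0.1, 2)
  scen <- ancestral_split_probs(fix_tree3(), fix_rd3(), p)
  tot <- oracle_dec_lik(fix_tree3(), bits, 2, 0.2, 0.1, 2)
  for (i in seq_len(nrow(scen))) {
    con <- list(node = scen$node[i], anc = scen$ancestral[i],
                left = scen$left[i], right = scen$right[i])
    expect_equal(scen$rel_prob[i],
                 oracle_dec_lik(fix_tree3(), bits, 2, 0.2, 0.1, 2,
                                constrain = con) / tot,
                 tolerance = 1e-9)
  }
  sums <- tapply(scen$rel_prob, scen$node, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("fit_dec finds the boundary MLE for eventless data", {
  tr <- fix_tree4()
  rs <- region_set(c("A", "B"))
  rd <- range_data_from_bits(c(t1 = 1L, t2 = 1L, t3 = 1L, t4 = 1L), rs)
  fit <- fit_dec(tr, rd, K = 2)
  expect_lt(fit$d, 1e-4)
  expect_lt(fit$e, 1e-4)
  expect_equal(fit$loglik, 0, tolerance = 1e-3)
})

test_that("fit_dec beats a coarse log-grid search oracle", {
  tr <- simulate_yule(10, 0.5, seed = 21)
  rs <- region_set(c("A", "B"))
  p_true <- dec_params(0.15, 0.05, 2)
  sim <- simulate_dec_history(tr, rs, p_true, root_range = 1L, seed = 22)
  fit <- fit_dec(tr, sim$tip_ranges, K = 2)
  grid <- exp(seq(log(1e-4), log(2), length.out = 20))
  grid_best <- -Inf
  for (d in grid) for (e in grid) {
    grid_best <- max(grid_best,
                     dec_loglik(tr, sim$tip_ranges, dec_params(d, e, 2)))
  }
  expect_gte(fit$loglik, grid_best - 1e-6)
  expect_gte(fit$loglik,
             dec_loglik(tr, sim$tip_ranges, p_true))  # MLE >= truth
})
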