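# Independent brute-force ESS condition checker used as the oracle.
brute_ess <- function(M, tol = 1e-9) {
  nt <- nrow(M)
  out <- logical(nt)
  for (t in seq_len(nt)) {
    stable <- TRUE
    for (m in seq_len(nt)) {
      if (m == t) next
      if (M[t, t] > M[m, t] + tol) next            # strict
      if (abs(M[t, t] - M[m, t]) <= tol && M[t, m] > M[m, m] + tol) next  # tie
      stable <- FALSE
      break
    }
    out[t] <- stable
  }
  out
}

test_that("symmetrization averages role means and yields a symmetric matrix", {
  rr <- data.frame(sender_type = c("a", "a", "b", "b", "a", "b"),
                   receiver_type = c("b", "b", "a", "a", "a", "b"),
                   reward = c(0.8, 0.8, 0.6, 0.6, 0.9, 0.5))
  po <- symmetrize(rr)
  expect_equal(po$matrix["a", "b"], (0.8 + 0.6) / 2)
  expect_equal(po$matrix["a", "a"], 0.9)
  expect_equal(po$matrix["b", "b"], 0.5)
  expect_identical(po$matrix, t(po$matrix))
  # role-symmetric input keeps the raw means
  rr2 <- data.frame(sender_type = c("a", "b"), receiver_type = c("b", "a"),
                    reward = c(0.7, 0.7))
  expect_error(symmetrize(rr2), "missing runs")  # no diagonal runs
  rr3 <- rbind(rr2, data.frame(sender_type = c("a", "b"),
                               receiver_type = c("a", "b"), reward = c(1, 0)))
  expect_equal(symmetrize(rr3)$matrix["a", "b"], 0.7)
})

test_that("ESS identification matches hand-derived cases", {
  # rows = focal type: r(own, opponent)
  M <- matrix(c(3, 0, 5, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("t1", "t2"), c("t1", "t2")))
  # t2 invades t1 (5 > 3); t2 resists t1 (1 > 0): unique ESS is t2
  expect_equal(find_ess(M)$ess_types, "t2")
  # identity payoff: every type strictly resists all mutants
  I4 <- diag(4)
  rownames(I4) <- colnames(I4) <- paste0("t", 1:4)
  expect_equal(find_ess(I4)$ess_types, paste0("t", 1:4))
  # Hawk-Dove: no pure ESS
  HD <- matrix(c(-1, 4, 0, 2), 2, 2, byrow = TRUE,
               dimnames = list(c("H", "D"), c("H", "D")))
  expect_equal(find_ess(HD)$ess_types, character(0))
  # tie-breaking branch: r(t1,t1) = r(t2,t1), decided by r(t1,t2) > r(t2,t2)
  TIE <- matrix(c(1, 3, 1, 2), 2, 2, byrow = TRUE,
                dimnames = list(c("t1", "t2"), c("t1", "t2")))
  rep <- find_ess(TIE)
  expect_equal(rep$ess_types, "t1")
  expect_equal(rep$conditions$branch[rep$conditions$type == "t1"], "tie-break")
})

test_that("find_ess agrees with the brute-force oracle on random matrices", {
  set.seed(7)
  for (i in 1:1000) {
    nt <- sample(2:6, 1)
    M <- matrix(runif(nt * nt), nt, nt)
    if (i %% 3 == 0) {
      # force some ties to exercise the tie-breaking branch
      M[sample(nt, 1), sample(nt, 1)] <- M[1, 1]
      diag(M)[sample(nt, 1)] <- M[1, 1]
    }
    dimnames(M) <- list(paste0("t", 1:nt), paste0("t", 1:nt))
    got <- find_ess(M)$ess_types
    stable <- which(brute_ess(M))
    want <- if (length(stable)) paste0("t", stable) else character(0)
    expect_identical(got, want)
  }
})

test_that("the ESS set is invariant under adding a constant to all payoffs", {
  set.seed(8)
  for (i in 1:50) {
    M <- matrix(runif(9), 3, 3)
    dimnames(M) <- list(letters[1:3], letters[1:3])
    expect_identical(find_ess(M)$ess_types, find_ess(M + 2.5)$ess_types)
  }
})

test_that("micro tournaments are structural and reproducible", {
  items <- sample_latents(2, seed = 81)
  sp <- make_split(items, 0.75, seed = 82)
  visions <- list(a = tiny_vision(1L), b = tiny_vision(2L))
  sc <- scenario_config("fixed_vision_emergence", epochs = 1, batch_size = 8,
                        batches_per_epoch = 1, eval_rounds = 30)
  po <- run_tournament(visions, sp, game_config(), sc, runs_per_pair = 2,
                       seed = 83)
  expect_equal(dim(po$matrix), c(2L, 2L))
  expect_identical(po$matrix, t(po$matrix))
  expect_true(all(po$matrix >= 0 & po$matrix <= 1))
  rr <- attr(po, "role_rewards")
  expect_equal(nrow(rr), 2 * 2 * 2)
  po2 <- run_tournament(visions, sp, game_config(), sc, runs_per_pair = 2,
                        seed = 83)
  expect_identical(po$matrix, po2$matrix)
})

test_that("significance mode only keeps CI-supported strict conditions", {
  # type a beats b clearly; runs are tight around the means
  rr <- data.frame(
    sender_type = rep(c("a", "a", "b", "b"), each = 6),
    receiver_type = rep(c("a", "b", "a", "b"), each = 6),
    reward = c(rnorm(6, 0.9, 0.005), rnorm(6, 0.7, 0.005),
               rnorm(6, 0.7, 0.005), rnorm(6, 0.5, 0.005)))
  po <- symmetrize(rr)
  rep1 <- find_ess(po, significance = TRUE, reps = 500, seed = 9)
  expect_equal(rep1$ess_types, "a")
  # overlapping samples: no significant ESS
  rr$reward <- rnorm(24, 0.7, 0.2)
  po2 <- symmetrize(rr)
  rep2 <- find_ess(po2, significance = TRUE, reps = 500, seed = 10)
  # point estimates may favor one type, but the CIs must not certify both
  expect_lte(length(rep2$ess_types), 1)
  expect_error(find_ess(diag(2), significance = TRUE), "samples")
})
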