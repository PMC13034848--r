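fake_run <- function(m_init, m_update, seed = 1L) {
  structure(list(seed = seed, m_init = m_init, m_update = m_update),
            class = "seed_run")
}

test_that("delta stacking is exact subtraction and rejects mismatched inits", {
  m0 <- matrix(rnorm(24 * 16), 24)
  runs <- lapply(1:3, function(s) fake_run(m0, m0 + s * 0.1, s))
  st <- delta_stack(runs)
  expect_equal(st$deltas[2, , ], matrix(0.2, 24, 16))
  expect_identical(st$seeds, 1:3)
  bad <- c(runs, list(fake_run(m0 + 1, m0, 4L)))
  expect_error(delta_stack(bad), "initial embedding")
})

test_that("vote fusion reproduces the worked five-seed example", {
  m0 <- matrix(0, 2, 16)
  deltas <- c(0.2, 0.4, 0.6, -0.1, -0.3)
  runs <- lapply(1:5, function(s) {
    mu <- m0; mu[1, 1] <- deltas[s]
    fake_run(m0, mu, s)
  })
  fu <- vote_fuse(delta_stack(runs))
  expect_identical(fu$T[1, 1], 1)
  expect_equal(fu$delta_fusion[1, 1], 0.4)  # mean of the three positives
  expect_identical(fu$support[1, 1], 3L)
  # all other cells: all five deltas are exactly 0 -> trend -1, fused mean 0
  expect_true(all(fu$T[-1] == -1))
  expect_true(all(fu$delta_fusion[-1] == 0))
  expect_equal(fu$m_fusion, m0 + fu$delta_fusion)
})

test_that("vote fusion matches the brute-force reference on random stacks", {
  set.seed(500)
  for (rep in 1:200) {
    n <- sample(c(1, 3, 5), 1)
    L <- 6
    m0 <- matrix(rnorm(L * 16), L)
    runs <- lapply(seq_len(n), function(s) {
      d <- matrix(rnorm(L * 16), L)
      d[sample(L * 16, 10)] <- 0  # exercise the zero-trend branch
      fake_run(m0, m0 + d, s)
    })
    st <- delta_stack(runs)
    fu <- vote_fuse(st)
    or <- oracle_vote_fuse(st$deltas, m0)
    expect_equal(fu$T, or$T)
    expect_equal(fu$delta_fusion, or$delta_fusion)
    expect_equal(fu$m_fusion, or$m_fusion)
    expect_equal(fu$support, or$support)
    # fused delta bounded by agreeing deltas; support majority where T != 0
    expect_true(all(fu$support[fu$T != 0] >= ceiling((n + 1) / 2)))
  }
})

test_that("single-run fusion degenerates to the run's own delta", {
  m0 <- matrix(rnorm(24 * 16), 24)
  mu <- m0 + matrix(rnorm(24 * 16, sd = 0.2), 24)
  fu <- vote_fuse(delta_stack(list(fake_run(m0, mu))))
  expect_equal(fu$delta_fusion, mu - m0)
  expect_equal(fu$m_fusion, mu)
})

test_that("even seed counts with a tied vote yield no consensus", {
  m0 <- matrix(0, 2, 16)
  runs <- list(fake_run(m0, m0 + 0.5), fake_run(m0, m0 - 0.5, 2L),
               fake_run(m0, m0 + 0.2, 3L), fake_run(m0, m0 - 0.2, 4L))
  fu <- vote_fuse(delta_stack(runs))
  expect_true(all(fu$T == 0))
  expect_true(all(fu$delta_fusion == 0))
})

test_that("position statistics pass through embedding values by biological position", {
  conv <- position_convention()
  tab <- gen_prior_table("MTP", 13)
  emb <- build_mtp_init(tab, conv)
  ps <- position_stats(emb$matrix, conv, stage = "origin")
  expect_equal(nrow(ps$values), 240)
  for (k in sample(nrow(tab), 25)) {
    v <- ps$values$value[ps$values$bio_pos == tab$position[k] &
                         ps$values$token == tab$token[k]]
    expect_equal(v, tab$value[k])
  }
  # constant embedding -> zero variance everywhere
  ps0 <- position_stats(matrix(1, conv$L, 16), conv)
  expect_true(all(ps0$summary$variance == 0))
  # mean difference between two constructed embeddings matches hand arithmetic
  e1 <- matrix(1, conv$L, 16); e2 <- matrix(1, conv$L, 16)
  e2[conv$row_of_bio[20], token_index(mm_tokens)] <- 3
  d <- position_stats(e2, conv)$summary$mean -
       position_stats(e1, conv)$summary$mean
  expect_equal(d[20], 2)
  expect_equal(d[19], 0)
})

test_that("pair similarity implements the weighted Pearson/distance fusion", {
  conv <- position_convention()
  set.seed(77)
  emb <- matrix(rnorm(24 * 16), 24)
  # plant two identical profiles so the min distance is 0
  emb[conv$row_of_bio, token_index("AC")] <-
    emb[conv$row_of_bio, token_index("AG")]
  sim <- pair_similarity(emb, conv, region = "all", alpha = 0.5)
  expect_true(isSymmetric(sim$phi))
  expect_equal(sim$phi["AC", "AG"], 1)  # P = 1, Norm(0) = 0
  expect_equal(diag(sim$phi),
               rep(0.5 * 1 + 0.5 * (1 - sim$norm_E[1, 1]), 12),
               ignore_attr = TRUE)
  # alpha limits
  sim0 <- pair_similarity(emb, conv, region = "all", alpha = 0)
  expect_equal(sim0$phi, sim0$P)
  sim1 <- pair_similarity(emb, conv, region = "all", alpha = 1)
  far <- which(sim1$norm_E == 1, arr.ind = TRUE)[1, ]
  expect_equal(sim1$phi[far[1], far[2]], 0)
  # hand check of one off-diagonal entry
  v1 <- emb[conv$row_of_bio, token_index("CA")]
  v2 <- emb[conv$row_of_bio, token_index("TG")]
  off <- sim$E[upper.tri(sim$E)]
  ne <- (sqrt(sum((v1 - v2)^2)) - min(off)) / (max(off) - min(off))
  expect_equal(sim$phi["CA", "TG"], 0.5 * cor(v1, v2) + 0.5 * (1 - ne))
})

test_that("pair similarity respects region selection and flags zero variance", {
  conv <- position_convention()
  set.seed(3)
  emb <- matrix(rnorm(24 * 16), 24)
  seed_sim <- pair_similarity(emb, conv, region = "seed")
  all_sim <- pair_similarity(emb, conv, region = "all")
  expect_false(isTRUE(all.equal(seed_sim$phi, all_sim$phi)))
  embz <- emb
  embz[conv$row_of_bio, token_index("AC")] <- 0.7
  expect_warning(simz <- pair_similarity(embz, conv), "zero-variance")
  expect_true(all(is.na(simz$P["AC", setdiff(mm_tokens, "AC")])))
})

test_that("similarity is equivariant under relabeling of the input profiles", {
  conv <- position_convention()
  set.seed(12)
  emb <- matrix(rnorm(24 * 16), 24)
  sim <- pair_similarity(emb, conv)
  # swap two mismatch profiles; the matrix rows/cols must swap accordingly
  emb2 <- emb
  i1 <- token_index("AC"); i2 <- token_index("TG")
  emb2[, c(i1, i2)] <- emb[, c(i2, i1)]
  sim2 <- pair_similarity(emb2, conv)
  expect_equal(sim2$phi["AC", "CA"], sim$phi["TG", "CA"])
  expect_equal(sim2$phi["TG", "GA"], sim$phi["AC", "GA"])
})

test_that("group summary averages intra and inter blocks correctly", {
  conv <- position_convention()
  set.seed(21)
  emb <- matrix(rnorm(24 * 16), 24)
  sim <- pair_similarity(emb, conv)
  gs <- group_similarity_summary(sim)
  expect_equal(nrow(gs), 10)  # 4 intra + 6 inter
  expect_equal(sum(gs$type == "intra"), 4)
  # brute force one intra and one inter entry
  rA <- c("AC", "AG", "AT")
  expect_equal(gs$mean_phi[gs$group1 == "rA" & gs$group2 == "rA"],
               mean(sim$phi[rA, rA][upper.tri(matrix(0, 3, 3))]))
  rC <- c("CA", "CG", "CT")
  expect_equal(gs$mean_phi[gs$group1 == "rA" & gs$group2 == "rC"],
               mean(sim$phi[rA, rC]))
})

test_that("cross-dataset concordance recovers planted correlation structure", {
  conv <- position_convention()
  set.seed(9)
  base <- matrix(rnorm(24 * 16), 24)
  mk <- function(d) {
    structure(list(delta_fusion = d, T = sign(d), m_fusion = d,
                   support = matrix(5L, 24, 16), n_seeds = 5L),
              class = "fused_update")
  }
  noise <- matrix(rnorm(24 * 16, sd = 0.05), 24)
  fused <- list(a = mk(base), b = mk(base + noise), c = mk(-base))
  cc <- cross_dataset_concordance(fused, conv)
  expect_lt(cc$correlations["a", "c"], -0.9)
  expect_gt(cc$correlations["a", "b"], 0.9)
  # a and b agree with each other and disagree with c -> c ranks last
  expect_identical(cc$ranking$dataset_id[3], "c")
  # negated twin gives exactly -1
  cc2 <- cross_dataset_concordance(list(x = mk(base), y = mk(-base)), conv)
  expect_equal(cc2$correlations["x", "y"], -1)
  expect_error(cross_dataset_concordance(list(a = mk(base))), "two datasets")
})
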