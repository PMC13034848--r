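# Shared small fixtures; everything is generated in code at test time.

alpha <- pair_alphabet()
mm_tokens <- setdiff(alpha$tokens, alpha$match_set)

# random MTP-like table covering a subset of cells
random_mtp_table <- function(seed, n = 60) {
  withr_seed <- crisprembed:::withr_seed
  withr_seed(seed, {
    grid <- expand.grid(position = 1:20, token = mm_tokens,
                        stringsAsFactors = FALSE)
    pick <- grid[sample(nrow(grid), n), ]
    pick$value <- runif(n)
    prior_table(pick, kind = "MTP")
  })
}

# a tiny trained pair of runs reused across several tests (built once)
.tiny_cache <- new.env()

tiny_training_setup <- function() {
  if (!is.null(.tiny_cache$setup)) return(.tiny_cache$setup)
  conv <- position_convention()
  spec <- synthetic_spec(n_guides = 6, sites_per_guide = 60,
                         prevalence = 0.15, seed = 42)
  ds <- gen_dataset(spec)
  tr <- ds[ds$split == "train", ]
  va <- ds[ds$split == "val", ]
  setup <- list(
    conv = conv, spec = spec, ds = ds,
    tr = list(cols = encode_pairs(tr, conv), label = tr$label),
    va = list(cols = encode_pairs(va, conv), label = va$label),
    mtp = build_mtp_init(gen_prior_table("MTP", 42), conv),
    drics = normalize_drics(build_drics_init(gen_prior_table("DRICS", 42),
                                             conv)),
    small_cfg = submodel_config("M", kernels_per_branch = 4L,
                                recurrent_layers = 1L,
                                recurrent_hidden = 6L,
                                head_sizes = c(8L, 1L)))
  .tiny_cache$setup <- setup
  setup
}

# independent oracles -------------------------------------------------

# all-pairs AUROC
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exhaustive threshold-sweep AUPRC (step integration over distinct scores)
oracle_auprc <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; area <- 0
  P <- sum(labels)
  for (th in ths) {
    pred <- scores >= th
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / P
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# brute-force vote fusion on an n x L x K delta array
oracle_vote_fuse <- function(deltas, m_init) {
  n <- dim(deltas)[1]; L <- dim(deltas)[2]; K <- dim(deltas)[3]
  TT <- matrix(0, L, K); df <- matrix(0, L, K); sup <- matrix(0L, L, K)
  for (i in 1:L) for (j in 1:K) {
    tr <- ifelse(deltas[, i, j] > 0, 1, -1)
    s <- sum(tr)
    if (s >= 1) TT[i, j] <- 1 else if (s <= -1) TT[i, j] <- -1
    if (TT[i, j] != 0) {
      agree <- which(tr == TT[i, j])
      sup[i, j] <- length(agree)
      df[i, j] <- mean(deltas[agree, i, j])
    }
  }
  list(T = TT, delta_fusion = df, m_fusion = m_init + df, support = sup)
}

# exact signed-rank p by direct enumeration of all 2^n sign patterns
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  mean(v_all >= v_obs - 1e-12)
}
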