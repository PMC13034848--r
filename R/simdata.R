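#' Generate a synthetic prior table
#'
#' Emulates the shape of the literature priors without reproducing their
#' values.  MTP: tolerance values for the 12 mismatch tokens at each of
#' the 20 biological positions, drawn in `(0, 1]`, with seed-region
#' positions (1-10) biased toward lower tolerance.  DRICS: contribution
#' scores for all 16 tokens at all 20 positions, match tokens in
#' `(0, 0.6]` and mismatch tokens in `[-5.5, 0)`, emulating the reported
#' raw range of the source scores.
#'
#' @param kind `"MTP"` or `"DRICS"`.
#' @param seed Integer seed; tables are reproducible given the seed.
#' @param drics_range Raw range emulated for DRICS (min, max).
#' @return A [prior_table()].
#' @export
gen_prior_table <- function(kind = c("MTP", "DRICS"), seed = 1L,
                            drics_range = c(-5.5, 0.6)) {
  kind <- match.arg(kind)
  withr_seed(seed, {
    mm <- setdiff(.alphabet$tokens, .alphabet$match_set)
    if (kind == "MTP") {
      grid <- tidyr::expand_grid(position = 1:20, token = mm)
      # seed region less tolerant on average
      upper <- ifelse(grid$position <= 10, 0.6, 1.0)
      grid$value <- runif(nrow(grid), min = 1e-3, max = upper)
      prior_table(grid, kind = "MTP", provenance = "synthetic")
    } else {
      grid <- tidyr::expand_grid(position = 1:20, token = .alphabet$tokens)
      is_match <- grid$token %in% .alphabet$match_set
      v <- numeric(nrow(grid))
      v[is_match] <- runif(sum(is_match), 1e-3, drics_range[2])
      v[!is_match] <- runif(sum(!is_match), drics_range[1], -1e-3)
      # pin the extremes so the emulated raw range is attained
      v[which(is_match)[1]] <- drics_range[2]
      v[which(!is_match)[1]] <- drics_range[1]
      grid$value <- v
      prior_table(grid, kind = "DRICS", provenance = "synthetic")
    }
  })
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Specification of a synthetic off-target study
#'
#' Defines the planted generative model: random 20-mer guides, off-target
#' sites derived by sampling mismatch positions and types, and Bernoulli
#' labels whose success probability is governed by a planted 20 x 16
#' position-by-token effect matrix through a chosen link.
#'
#' Under the `logistic_sum` link the label probability of a site is
#' `plogis(intercept + sum planted_w[bio_pos, token])` over its
#' mismatched positions; under `product_tolerance` it is
#' `plogis(intercept) * prod planted_w[bio_pos, token]` with the planted
#' matrix holding tolerances in `(0, 1]`.  The intercept is calibrated at
#' generation time so the expected prevalence matches `prevalence`.
#'
#' @param n_guides Number of sgRNAs (default 20).
#' @param sites_per_guide Candidate sites per guide (default 2000).
#' @param mismatch_count_range Inclusive range of mismatches per site
#'   (default `c(1, 6)`).
#' @param planted_w Optional 20 x 16 effect matrix; default drawn from
#'   the spec's seed with stronger (more negative) penalties in the
#'   PAM-proximal seed region and match cells at 0 baseline.
#' @param link `"logistic_sum"` or `"product_tolerance"`.
#' @param prevalence Target positive prevalence (in `(0, 0.5)`).
#' @param seed Integer seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_guides = 20L, sites_per_guide = 2000L,
                           mismatch_count_range = c(1L, 6L),
                           planted_w = NULL,
                           link = c("logistic_sum", "product_tolerance"),
                           prevalence = 0.02, seed = 1L) {
  link <- match.arg(link)
  if (!(prevalence > 0 && prevalence < 0.5)) {
    abort("prevalence target must lie in (0, 0.5)")
  }
  if (is.null(planted_w)) {
    planted_w <- default_planted_w(seed, link)
  }
  stopifnot(identical(dim(planted_w), c(20L, 16L)))
  mm_idx <- token_index(setdiff(.alphabet$tokens, .alphabet$match_set))
  if (sd(planted_w[, mm_idx]) == 0) {
    abort("planted mismatch effects must not be constant")
  }
  structure(list(n_guides = as.integer(n_guides),
                 sites_per_guide = as.integer(sites_per_guide),
                 mismatch_count_range = as.integer(mismatch_count_range),
                 planted_w = planted_w, link = link,
                 prevalence = prevalence, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Default planted effect matrix
#'
#' Mismatch cells draw position-specific penalties, stronger in the
#' seed region (biological positions 1-10), with token-level jitter so
#' effects differ across mismatch types; match cells sit at the baseline
#' (0 for the additive link, 1 for the product link).
#'
#' @param seed Integer seed.
#' @param link Link the matrix is destined for.
#' @return A 20 x 16 numeric matrix (rows = biological positions,
#'   columns = canonical tokens).
#' @export
default_planted_w <- function(seed = 1L, link = "logistic_sum") {
  withr_seed(seed + 104729L, {
    w <- matrix(0, 20L, 16L, dimnames = list(NULL, .alphabet$tokens))
    mm <- setdiff(.alphabet$tokens, .alphabet$match_set)
    pos_strength <- c(runif(10, 1.2, 2.6), runif(10, 0.1, 1.2)) # seed > non-seed
    for (tok in mm) {
      w[, tok] <- -pos_strength * runif(20, 0.3, 1.7)
    }
    if (link == "product_tolerance") w <- exp(w)  # tolerances in (0, 1]
    if (link == "product_tolerance") w[, .alphabet$match_set] <- 1
    w
  })
}

# additive score of a site: sum of effects (logistic link) or sum of
# log-tolerances (product link)
.site_score <- function(w, pos, tok_idx, link) {
  if (length(pos) == 0) return(0)
  v <- w[cbind(pos, tok_idx)]
  if (link == "product_tolerance") sum(log(v)) else sum(v)
}

#' Generate a synthetic sgRNA-off-target dataset
#'
#' Draws guides uniformly over 20-mers (plus NGG PAM and one matched
#' 5' context base under the default convention), mutates each site at
#' sampled positions and mismatch types, assigns Bernoulli labels under
#' the planted model, and emits guide-disjoint train/validation/test
#' splits.
#'
#' @param spec A [synthetic_spec()].
#' @param split_fractions Guide fractions for train/val/test
#'   (default `c(0.6, 0.2, 0.2)`).
#' @param conv A [position_convention()].
#' @return A tibble with columns `sgrna_id`, `guide_seq`, `target_seq`,
#'   `label`, `dataset_id`, `split`, `p_true`; attribute `intercept`
#'   holds the calibrated intercept.
#' @export
gen_dataset <- function(spec, split_fractions = c(0.6, 0.2, 0.2),
                        conv = position_convention(),
                        dataset_id = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"))
  bases <- c("A", "C", "G", "T")
  withr_seed(spec$seed, {
    n_g <- spec$n_guides; n_s <- spec$sites_per_guide
    guides <- replicate(n_g, paste(sample(bases, 20, TRUE), collapse = ""))
    while (anyDuplicated(guides)) {
      guides[duplicated(guides)] <-
        replicate(sum(duplicated(guides)), paste(sample(bases, 20, TRUE), collapse = ""))
    }
    ids <- sprintf("sg%03d", seq_len(n_g))
    n <- n_g * n_s
    rng <- spec$mismatch_count_range
    # per-site mismatch structure
    counts <- if (rng[1] == rng[2]) rep(rng[1], n)
              else sample(seq(rng[1], rng[2]), n, TRUE)
    guide_of <- rep(seq_len(n_g), each = n_s)
    pos_list <- vector("list", n)
    tok_list <- vector("list", n)
    eta <- numeric(n)
    gmat <- do.call(rbind, lapply(guides, .split_seq))
    target_pro <- matrix("", n, 20)
    for (i in seq_len(n)) {
      k <- counts[i]
      pos <- sort(sample.int(20L, k))              # biological positions
      gb <- gmat[guide_of[i], 21L - pos]           # guide base at those rows
      tb <- vapply(gb, function(b) sample(setdiff(bases, b), 1L), "")
      tok <- token_index(paste0(gb, tb))
      pos_list[[i]] <- pos; tok_list[[i]] <- tok
      pro <- gmat[guide_of[i], ]
      pro[21L - pos] <- tb
      target_pro[i, ] <- pro
      eta[i] <- .site_score(spec$planted_w, pos, tok, spec$link)
    }
    # intercept calibration to the target prevalence
    if (spec$link == "logistic_sum") {
      f <- function(b) mean(plogis(b + eta)) - spec$prevalence
      lo <- -30; hi <- 30
      intercept <- uniroot(f, c(lo, hi), tol = 1e-9)$root
      p <- plogis(intercept + eta)
    } else {
      tolprod <- exp(eta)  # planted_w held tolerances; eta = sum(log tol)
      f <- function(b) mean(plogis(b) * tolprod) - spec$prevalence
      if (f(30) < 0) {
        warn(sprintf("prevalence target %.3f infeasible; achieved %.4f",
                     spec$prevalence, mean(tolprod)))
        intercept <- 30
      } else {
        intercept <- uniroot(f, c(-30, 30), tol = 1e-9)$root
      }
      p <- plogis(intercept) * tolprod
    }
    label <- rbinom(n, 1L, p)
    pad <- sample(bases, n_g, TRUE)               # matched 5' context base
    pam1 <- sample(bases, n, TRUE)                # N position of NGG
    guide_seq <- paste0(pad[guide_of],
                        guides[guide_of], "NGG")
    target_seq <- paste0(pad[guide_of],
                         apply(target_pro, 1, paste, collapse = ""),
                         pam1, "GG")
    # guide-disjoint split
    n_train <- max(1L, round(split_fractions[1] * n_g))
    n_val <- max(1L, round(split_fractions[2] * n_g))
    n_test <- n_g - n_train - n_val
    if (n_test < 1L) abort("split fractions leave no test guides")
    split_of <- rep(c("train", "val", "test"), c(n_train, n_val, n_test))
    tb <- tibble::tibble(
      sgrna_id = ids[guide_of],
      guide_seq = guide_seq,
      target_seq = target_seq,
      label = as.integer(label),
      dataset_id = dataset_id,
      split = split_of[guide_of],
      p_true = p)
    attr(tb, "intercept") <- intercept
    attr(tb, "planted_w") <- spec$planted_w
    tb
  })
}

#' Analytic site probability under the planted model
#'
#' @param spec A [synthetic_spec()].
#' @param positions Biological positions of the mismatches.
#' @param tokens Mismatch tokens at those positions.
#' @param intercept The calibrated intercept (attribute of the dataset).
#' @return Probability of a positive label.
#' @export
planted_site_prob <- function(spec, positions, tokens, intercept) {
  ti <- token_index(tokens)
  eta <- .site_score(spec$planted_w, positions, ti, spec$link)
  if (spec$link == "logistic_sum") plogis(intercept + eta)
  else plogis(intercept) * exp(eta)
}

#' Write a generated dataset as train/val/test pair TSVs
#'
#' @param dataset Result of [gen_dataset()].
#' @param dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in unique(dataset$split)) {
    p <- file.path(dir, paste0(s, ".tsv"))
    write_pairs(dataset[dataset$split == s, ], p)
    paths <- c(paths, p)
  }
  w <- attr(dataset, "planted_w")
  if (!is.null(w)) {
    wt <- tibble::as_tibble(w)
    wt <- dplyr::bind_cols(tibble::tibble(position = 1:20), wt)
    readr::write_tsv(wt, file.path(dir, "planted_w.tsv"))
  }
  jsonlite::write_json(
    list(intercept = attr(dataset, "intercept"),
         n_pairs = nrow(dataset),
         prevalence = mean(dataset$label)),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
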