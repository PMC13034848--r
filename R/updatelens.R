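#' Stack per-seed embedding deltas
#'
#' For each seed run the delta is the exact element-wise difference
#' between the updated and the initial embedding.  All runs must share
#' the same initial embedding.
#'
#' @param runs List of `seed_run` objects.
#' @return A `delta_stack`: `deltas` (n x L x 16 array), `seeds`,
#'   `m_init`.
#' @export
delta_stack <- function(runs) {
  stopifnot(length(runs) >= 1)
  m_init <- runs[[1]]$m_init
  for (r in runs) {
    if (!identical(r$m_init, m_init)) {
      abort("runs do not share the same initial embedding")
    }
  }
  n <- length(runs)
  deltas <- array(0, c(n, nrow(m_init), ncol(m_init)))
  for (s in seq_len(n)) deltas[s, , ] <- runs[[s]]$m_update - m_init
  structure(list(deltas = deltas,
                 seeds = vapply(runs, function(r) r$seed, integer(1)),
                 m_init = m_init),
            class = "delta_stack")
}

#' Majority-vote fusion of per-seed embedding deltas
#'
#' Each cell's per-seed trend is +1 when its delta is positive and -1
#' otherwise (an exact zero counts as -1).  The primary direction `T`
#' is the majority trend; the fused delta is the mean of the deltas of
#' the agreeing seeds, and the fused embedding is the initial embedding
#' plus the fused delta.  With an even seed count a tied vote yields
#' `T = 0` and a fused delta of 0 (no consensus).
#'
#' @param stack A [delta_stack()].
#' @return A `fused_update`: `T` (L x 16 in -1/0/+1), `delta_fusion`,
#'   `m_fusion`, `support` (agreeing-seed counts), `n_seeds`.
#' @export
vote_fuse <- function(stack) {
  stopifnot(inherits(stack, "delta_stack"))
  d <- stack$deltas
  n <- dim(d)[1]; L <- dim(d)[2]; K <- dim(d)[3]
  tr <- ifelse(d > 0, 1, -1)                    # n x L x 16 trends
  tsum <- apply(tr, c(2, 3), sum)
  TT <- sign(tsum)
  delta_fusion <- matrix(0, L, K)
  support <- matrix(0L, L, K)
  for (i in seq_len(L)) {
    for (j in seq_len(K)) {
      if (TT[i, j] == 0) next
      agree <- tr[, i, j] == TT[i, j]
      support[i, j] <- sum(agree)
      delta_fusion[i, j] <- mean(d[agree, i, j])
    }
  }
  structure(list(T = TT, delta_fusion = delta_fusion,
                 m_fusion = stack$m_init + delta_fusion,
                 support = support, n_seeds = n),
            class = "fused_update")
}

#' @export
print.fused_update <- function(x, ...) {
  cat(sprintf("<fused_update> %d seeds | consensus cells: %d/%d\n",
              x$n_seeds, sum(x$T != 0), length(x$T)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fused_update <- function(x, conv = position_convention(), ...) {
  L <- nrow(x$delta_fusion)
  tibble::tibble(
    row = rep(seq_len(L), 16),
    bio_pos = rep(conv$bio_map, 16),
    token = rep(.alphabet$tokens, each = L),
    direction = as.vector(x$T),
    delta = as.vector(x$delta_fusion),
    support = as.vector(x$support),
    value = as.vector(x$m_fusion))
}

#' @exportS3Method generics::glance
glance.fused_update <- function(x, ...) {
  tibble::tibble(n_seeds = x$n_seeds,
                 consensus_cells = sum(x$T != 0),
                 mean_abs_delta = mean(abs(x$delta_fusion)))
}

#' Per-position distribution of mismatch embedding values
#'
#' For each biological position 1-20 (PAM-proximal = 1) the twelve
#' mismatch-token values of an embedding matrix are collected, with
#' their mean and population variance -- the data behind per-position
#' violin plots of original versus updated embedding spaces.
#'
#' @param embedding `L x 16` matrix (e.g. `m_fusion` of a
#'   [vote_fuse()] result, or a prior matrix).
#' @param conv A [position_convention()].
#' @param tokens Tokens to profile (default the 12 mismatch tokens).
#' @param stage Label stored alongside (e.g. `"origin"` / `"update"`).
#' @return A `position_stats` list: `values` (long tibble `bio_pos`,
#'   `token`, `group`, `value`, `stage`) and `summary` (`bio_pos`,
#'   `mean`, `variance`).
#' @export
position_stats <- function(embedding, conv = position_convention(),
                           tokens = setdiff(pair_alphabet()$tokens,
                                            pair_alphabet()$match_set),
                           stage = "update") {
  stopifnot(nrow(embedding) == conv$L)
  idx <- token_index(tokens)
  vals <- embedding[conv$row_of_bio, idx, drop = FALSE]
  values <- tibble::tibble(
    bio_pos = rep(1:20, length(tokens)),
    token = rep(tokens, each = 20),
    group = rep(ifelse(tokens %in% .alphabet$match_set, "match",
                       paste0("r", substr(tokens, 1, 1))), each = 20),
    value = as.vector(vals),
    stage = stage)
  pvar <- function(v) mean((v - mean(v))^2)
  summary <- values |>
    dplyr::group_by(.data$bio_pos) |>
    dplyr::summarise(mean = mean(.data$value),
                     variance = pvar(.data$value), .groups = "drop") |>
    dplyr::mutate(stage = stage)
  structure(list(values = values, summary = summary),
            class = "position_stats")
}

#' @export
print.position_stats <- function(x, ...) {
  cat(sprintf("<position_stats> stage=%s | %d values over %d positions\n",
              x$values$stage[1], nrow(x$values),
              dplyr::n_distinct(x$values$bio_pos)))
  invisible(x)
}

#' Weighted similarity between mismatch-token profiles
#'
#' For every pair of mismatch tokens, the per-position value vectors
#' over the chosen region are compared by Pearson correlation `P` and
#' Euclidean distance `E`; distances are min-max normalized over the 66
#' unordered token pairs, and the similarity is the weighted fusion
#' `Phi = (1 - alpha) * P + alpha * (1 - Norm(E))`.
#'
#' @param embedding `L x 16` matrix.
#' @param conv A [position_convention()].
#' @param region `"seed"` (biological positions 1-10), `"nonseed"`
#'   (11-20) or `"all"` (1-20).
#' @param alpha Weight of the distance component, in `[0, 1]`
#'   (default 0.5).
#' @return A `similarity_matrix`: `phi` (12 x 12, token-labelled),
#'   `P`, `E`, `norm_E`, `region`, `alpha`.  Token profiles with zero
#'   variance yield `NA` Pearson entries (flagged with a warning).
#' @export
pair_similarity <- function(embedding, conv = position_convention(),
                            region = c("all", "seed", "nonseed"),
                            alpha = 0.5) {
  region <- match.arg(region)
  if (!(alpha >= 0 && alpha <= 1)) abort("alpha must lie in [0, 1]")
  pos <- switch(region, seed = 1:10, nonseed = 11:20, all = 1:20)
  if (length(pos) < 3) abort("region must span at least 3 positions")
  mm <- setdiff(.alphabet$tokens, .alphabet$match_set)
  V <- embedding[conv$row_of_bio[pos], token_index(mm), drop = FALSE]
  colnames(V) <- mm
  zero_var <- apply(V, 2, sd) == 0
  if (any(zero_var)) {
    warn(paste("zero-variance profile(s):",
               paste(mm[zero_var], collapse = ", "),
               "- Pearson entries flagged NA"))
  }
  P <- suppressWarnings(cor(V))
  E <- as.matrix(stats::dist(t(V)))
  off <- E[upper.tri(E)]
  e_min <- min(off); e_max <- max(off)
  norm_E <- if (e_max > e_min) (E - e_min) / (e_max - e_min)
            else E * 0
  phi <- (1 - alpha) * P + alpha * (1 - norm_E)
  dimnames(phi) <- dimnames(P) <- dimnames(E) <- dimnames(norm_E) <-
    list(mm, mm)
  structure(list(phi = phi, P = P, E = E, norm_E = norm_E,
                 region = region, alpha = alpha),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> region=%s alpha=%.2f\n",
              x$region, x$alpha))
  print(round(x$phi, 3))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.similarity_matrix <- function(x, ...) {
  mm <- rownames(x$phi)
  g <- tidyr::expand_grid(token1 = mm, token2 = mm)
  g$phi <- as.vector(t(x$phi))
  g$pearson <- as.vector(t(x$P))
  g$distance <- as.vector(t(x$E))
  g
}

#' Intra- and inter-group similarity summary
#'
#' Averages the fused similarity within each mismatch group (`rA`,
#' `rC`, `rG`, `rT`; three unordered token pairs each) and between each
#' of the six group pairs (nine token pairs each).
#'
#' @param sim A [pair_similarity()] result.
#' @return A tibble `group1`, `group2`, `type` (intra/inter),
#'   `mean_phi`.
#' @export
group_similarity_summary <- function(sim) {
  stopifnot(inherits(sim, "similarity_matrix"))
  phi <- sim$phi
  mm <- rownames(phi)
  grp <- mismatch_group(mm)
  groups <- c("rA", "rC", "rG", "rT")
  out <- list()
  for (a in seq_along(groups)) {
    for (b in a:length(groups)) {
      ga <- mm[grp == groups[a]]; gb <- mm[grp == groups[b]]
      block <- phi[ga, gb, drop = FALSE]
      if (a == b) {
        v <- block[upper.tri(block)]
        type <- "intra"
      } else {
        v <- as.vector(block)
        type <- "inter"
      }
      out[[length(out) + 1]] <- tibble::tibble(
        group1 = groups[a], group2 = groups[b], type = type,
        mean_phi = mean(v))
    }
  }
  dplyr::bind_rows(out)
}

#' Cross-dataset concordance of fused update distributions
#'
#' Each dataset's update distribution is its vote-fused delta over the
#' guide-row mismatch cells (240 values, fixed order).  Pairwise
#' Pearson correlations quantify concordance; each dataset's mean
#' correlation with the others yields a descending ranking.
#'
#' @param fused Named list of `fused_update` objects (>= 2).
#' @param conv A [position_convention()].
#' @return A list with `correlations` (pairwise matrix) and `ranking`
#'   (tibble `dataset_id`, `mean_similarity`, `rank`).  Datasets with a
#'   constant update vector are flagged `NA`.
#' @export
cross_dataset_concordance <- function(fused, conv = position_convention()) {
  if (length(fused) < 2) abort("at least two datasets are required")
  if (is.null(names(fused)) || any(names(fused) == "")) {
    names(fused) <- paste0("dataset", seq_along(fused))
  }
  mm_idx <- token_index(setdiff(.alphabet$tokens, .alphabet$match_set))
  vecs <- vapply(fused, function(f) {
    as.vector(f$delta_fusion[conv$guide_rows, mm_idx])
  }, numeric(length(conv$guide_rows) * length(mm_idx)))
  const <- apply(vecs, 2, sd) == 0
  if (any(const)) {
    warn(paste("constant update vector(s):",
               paste(names(fused)[const], collapse = ", ")))
  }
  cm <- suppressWarnings(cor(vecs))
  mean_sim <- vapply(seq_len(ncol(cm)), function(i) {
    mean(cm[i, -i])
  }, numeric(1))
  ranking <- tibble::tibble(dataset_id = names(fused),
                            mean_similarity = mean_sim) |>
    dplyr::arrange(dplyr::desc(.data$mean_similarity)) |>
    dplyr::mutate(rank = dplyr::row_number())
  list(correlations = cm, ranking = ranking)
}
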