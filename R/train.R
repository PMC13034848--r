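#' Training configuration
#'
#' Adam with mini-batches, binary cross-entropy (optionally positive-
#' class weighted), early stopping on validation AUPRC, and a set of
#' random seeds for independent replicate runs.
#'
#' @param epochs_max Maximum epochs per run.
#' @param patience Epochs without validation-AUPRC improvement before
#'   stopping; must not exceed `epochs_max`.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam learning rate.
#' @param pos_weight Positive-class weight for the loss (1 =
#'   unweighted binary cross-entropy).
#' @param seeds Integer seeds, one training replicate each.
#' @return A `train_config` list.  The early-stopping metric is fixed
#'   to validation AUPRC.
#' @export
train_config <- function(epochs_max = 30L, patience = 5L,
                         batch_size = 256L, learning_rate = 1e-3,
                         pos_weight = 1, seeds = 1:5) {
  if (length(seeds) < 1) abort("at least one seed is required")
  if (patience > epochs_max) abort("patience must not exceed epochs_max")
  structure(list(epochs_max = as.integer(epochs_max),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 pos_weight = pos_weight,
                 seeds = as.integer(seeds),
                 early_stop_metric = "val_auprc"),
            class = "train_config")
}

.as_encoded <- function(x, conv) {
  if (is.matrix(x)) x else encode_pairs(x, conv)
}

#' Train one sub-model with synchronous embedding updates
#'
#' The prior embedding (when trainable) and all downstream weights are
#' updated jointly by Adam each mini-batch.  After every epoch the
#' validation AUPRC is computed; training stops when it has not
#' improved for `patience` epochs, and the best-epoch parameters are
#' returned.  Fully reproducible given the seed: the seed drives weight
#' initialization and the per-epoch shuffling order.
#'
#' @param train_pairs,val_pairs Pair tibbles (with `label`), or lists
#'   `list(cols = <encoded matrix>, label = <0/1>)`.
#' @param prior The `prior_embedding` initializing the model.
#' @param config A [submodel_config()].
#' @param tc A [train_config()].
#' @param seed Seed for this run (defaults to the first in `tc$seeds`).
#' @param conv Position convention (taken from the prior).
#' @return A `seed_run` with elements `seed`, `model`, `m_init`,
#'   `m_update`, `val_history` (tibble), `stopped_epoch`, `best_epoch`.
#' @export
train_submodel <- function(train_pairs, val_pairs, prior, config,
                           tc = train_config(), seed = tc$seeds[1]) {
  conv <- prior$conv
  tr <- .train_matrices(train_pairs, conv)
  va <- .train_matrices(val_pairs, conv)
  if (length(unique(va$label)) < 2) {
    abort("validation set must contain both classes (AUPRC undefined)",
          class = "crispr_single_class")
  }
  model <- build_submodel(config, prior, seed = seed)
  cfg <- .cpp_cfg(config, conv$L, tc$pos_weight)
  params <- unname(model$params)
  mstate <- lapply(params, function(p) p * 0)
  vstate <- mstate
  tstep <- 0L
  best <- list(auprc = -Inf, params = params, epoch = 0L)
  history <- vector("list", tc$epochs_max)
  wait <- 0L
  n <- nrow(tr$cols)
  stopped <- tc$epochs_max
  withr_seed(seed + 1L, {
    for (epoch in seq_len(tc$epochs_max)) {
      ord <- sample.int(n)
      res <- cpp_train_epoch(params, mstate, vstate, tstep,
                             tr$cols, as.numeric(tr$label), ord,
                             tc$batch_size, tc$learning_rate, cfg)
      params <- res$params; mstate <- res$m; vstate <- res$v
      tstep <- res$t
      pv <- cpp_predict(params, va$cols, cfg)
      auprc <- auprc_step(pv, va$label)
      history[[epoch]] <- tibble::tibble(epoch = epoch,
                                         train_loss = res$loss,
                                         val_auprc = auprc)
      if (auprc > best$auprc + 1e-8) {
        best <- list(auprc = auprc, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= tc$patience) { stopped <- epoch; break }
      }
      stopped <- epoch
    }
  })
  names(best$params) <- names(model$params)
  model$params <- best$params
  structure(list(seed = as.integer(seed), model = model,
                 m_init = unname(prior$matrix),
                 m_update = unname(best$params$emb),
                 val_history = dplyr::bind_rows(history),
                 stopped_epoch = stopped, best_epoch = best$epoch,
                 best_val_auprc = best$auprc),
            class = "seed_run")
}

.train_matrices <- function(x, conv) {
  if (is.list(x) && !is.data.frame(x) && !is.null(x$cols)) {
    list(cols = x$cols, label = as.integer(x$label))
  } else {
    stopifnot(is.data.frame(x), "label" %in% names(x))
    list(cols = encode_pairs(x, conv), label = as.integer(x$label))
  }
}

#' @export
print.seed_run <- function(x, ...) {
  cat(sprintf("<seed_run> seed=%d stopped_epoch=%d best_epoch=%d best val AUPRC=%.4f\n",
              x$seed, x$stopped_epoch, x$best_epoch, x$best_val_auprc))
  invisible(x)
}

#' Independent training replicates across random seeds
#'
#' One run per seed: distinct downstream initializations and shuffling
#' streams, identical data and prior.  Encoding is done once and shared.
#'
#' @inheritParams train_submodel
#' @param progress Print a line per finished run?
#' @return List of `seed_run`, one per seed of `tc$seeds`.
#' @export
run_seeds <- function(train_pairs, val_pairs, prior, config,
                      tc = train_config(), progress = FALSE) {
  seeds <- tc$seeds
  if (anyDuplicated(seeds)) abort("duplicate seeds", class = "crispr_dup_seeds")
  conv <- prior$conv
  tr <- .train_matrices(train_pairs, conv)
  va <- .train_matrices(val_pairs, conv)
  runs <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    runs[[i]] <- train_submodel(tr, va, prior, config, tc, seed = seeds[i])
    if (progress) {
      message(sprintf("seed %d: best val AUPRC %.4f (epoch %d/%d)",
                      seeds[i], runs[[i]]$best_val_auprc,
                      runs[[i]]$best_epoch, runs[[i]]$stopped_epoch))
    }
  }
  runs
}

#' @rdname train_submodel
#' @param x A `seed_run`.
#' @exportS3Method generics::tidy
tidy.seed_run <- function(x, ...) x$val_history

#' @rdname train_submodel
#' @exportS3Method generics::glance
glance.seed_run <- function(x, ...) {
  tibble::tibble(seed = x$seed, stopped_epoch = x$stopped_epoch,
                 best_epoch = x$best_epoch,
                 best_val_auprc = x$best_val_auprc,
                 embedding_changed = !identical(x$m_update, x$m_init))
}

#' Write / read a seed-run checkpoint directory
#'
#' The checkpoint holds TSV snapshots of the initial and updated
#' embedding, all downstream weights in long TSV form, and a JSON with
#' config, seed and training trace, so a run is fully reconstructable.
#'
#' @param run A `seed_run`.
#' @param dir Checkpoint directory (created).
#' @export
write_checkpoint <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emb_i <- .new_embedding(run$m_init, run$model$prior_kind, run$model$conv,
                          normalized = TRUE)
  emb_u <- .new_embedding(run$m_update, run$model$prior_kind, run$model$conv,
                          normalized = TRUE)
  write_embedding(emb_i, file.path(dir, "embedding_init.tsv"))
  write_embedding(emb_u, file.path(dir, "embedding_current.tsv"))
  long <- purrr::imap_dfr(run$model$params, function(p, nm) {
    tibble::tibble(param = nm,
                   i = rep(seq_len(nrow(p)), ncol(p)),
                   j = rep(seq_len(ncol(p)), each = nrow(p)),
                   value = as.vector(p))
  })
  readr::write_tsv(long, file.path(dir, "weights.tsv"))
  meta <- list(seed = run$seed, config = unclass(run$model$config),
               L = run$model$conv$L, prior_kind = run$model$prior_kind,
               stopped_epoch = run$stopped_epoch,
               best_epoch = run$best_epoch,
               best_val_auprc = run$best_val_auprc,
               val_history = run$val_history)
  jsonlite::write_json(meta, file.path(dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' @rdname write_checkpoint
#' @param conv Position convention used when the run was trained.
#' @export
read_checkpoint <- function(dir, conv = position_convention()) {
  meta <- jsonlite::read_json(file.path(dir, "run.json"),
                              simplifyVector = TRUE)
  config <- do.call(submodel_config, meta$config[
    setdiff(names(meta$config), character(0))])
  long <- readr::read_tsv(file.path(dir, "weights.tsv"),
                          col_types = readr::cols())
  params <- lapply(split(long, factor(long$param, unique(long$param))),
                   function(d) {
                     matrix(d$value, max(d$i), max(d$j))
                   })
  params <- params[unique(long$param)]
  m_init <- read_embedding(file.path(dir, "embedding_init.tsv"), conv)
  m_update <- read_embedding(file.path(dir, "embedding_current.tsv"), conv)
  model <- structure(list(config = config, conv = conv,
                          prior_kind = meta$prior_kind, params = params,
                          seed = meta$seed),
                     class = "crispr_submodel")
  structure(list(seed = meta$seed, model = model,
                 m_init = unname(m_init$matrix),
                 m_update = unname(m_update$matrix),
                 val_history = tibble::as_tibble(meta$val_history),
                 stopped_epoch = meta$stopped_epoch,
                 best_epoch = meta$best_epoch,
                 best_val_auprc = meta$best_val_auprc),
            class = "seed_run")
}
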