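#' Sub-model architecture configuration
#'
#' The two sub-models share one architecture family: trainable prior
#' embedding, an Inception block of parallel 1-D convolution branches
#' (kernel sizes 3 and 5, 20 kernels each) plus an identity residual
#' branch, a bidirectional LSTM stack, and a dense head of 80, 20 and 1
#' neurons ending in a sigmoid.  The M-model (MTP prior) uses two
#' recurrent layers of hidden size 25; the D-model (DRICS prior) one
#' layer of hidden size 20.
#'
#' @param kind `"M"` or `"D"`.
#' @param conv_kernel_sizes Kernel sizes of the convolution branches.
#' @param kernels_per_branch Filters per branch.
#' @param residual_branch Include the identity residual branch?
#' @param recurrent_layers,recurrent_hidden BiLSTM depth and hidden
#'   size; defaults depend on `kind`.
#' @param head_sizes Dense layer sizes; the last must be 1.
#' @param embedding_trainable Update the prior embedding during
#'   training?  Setting `FALSE` gives the frozen-prior ("no-update")
#'   control model.
#' @param use_inception,use_bilstm Ablation switches: without the
#'   Inception block the embedding feeds the recurrent stack directly;
#'   without the BiLSTM the concatenated convolution output feeds the
#'   head directly.
#' @return A `submodel_config` list.
#' @export
submodel_config <- function(kind = c("M", "D"),
                            conv_kernel_sizes = c(3L, 5L),
                            kernels_per_branch = 20L,
                            residual_branch = TRUE,
                            recurrent_layers = NULL,
                            recurrent_hidden = NULL,
                            head_sizes = c(80L, 20L, 1L),
                            embedding_trainable = TRUE,
                            use_inception = TRUE,
                            use_bilstm = TRUE) {
  kind <- match.arg(kind)
  if (is.null(recurrent_layers)) recurrent_layers <- if (kind == "M") 2L else 1L
  if (is.null(recurrent_hidden)) recurrent_hidden <- if (kind == "M") 25L else 20L
  if (utils::tail(head_sizes, 1) != 1L) abort("last head size must be 1")
  stopifnot(kernels_per_branch > 0, recurrent_hidden > 0)
  if (!use_inception && !use_bilstm) {
    abort("at most one of the Inception and BiLSTM blocks can be ablated")
  }
  structure(list(kind = kind,
                 conv_kernel_sizes = as.integer(conv_kernel_sizes),
                 kernels_per_branch = as.integer(kernels_per_branch),
                 residual_branch = residual_branch,
                 recurrent_layers = as.integer(recurrent_layers),
                 recurrent_hidden = as.integer(recurrent_hidden),
                 head_sizes = as.integer(head_sizes),
                 embedding_trainable = embedding_trainable,
                 use_inception = use_inception,
                 use_bilstm = use_bilstm),
            class = "submodel_config")
}

# cfg list consumed by the C++ core
.cpp_cfg <- function(config, L, pos_weight = 1) {
  list(L = as.integer(L),
       n_filters = config$kernels_per_branch,
       rnn_layers = config$recurrent_layers,
       rnn_hidden = config$recurrent_hidden,
       kernel_sizes = config$conv_kernel_sizes,
       residual = isTRUE(config$residual_branch),
       use_conv = isTRUE(config$use_inception),
       use_rnn = isTRUE(config$use_bilstm),
       emb_trainable = isTRUE(config$embedding_trainable),
       head_sizes = config$head_sizes,
       pos_weight = as.numeric(pos_weight))
}

# number of channels after the inception block
.n_channels <- function(config) {
  if (!config$use_inception) return(1L)
  length(config$conv_kernel_sizes) * config$kernels_per_branch +
    as.integer(isTRUE(config$residual_branch))
}

.glorot <- function(n_in, n_out, nrow = n_in, ncol = n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(runif(nrow * ncol, -s, s), nrow, ncol)
}

# canonical ordered parameter list; consumes the current RNG stream
.init_params <- function(config, prior_matrix) {
  L <- nrow(prior_matrix)
  params <- list(emb = prior_matrix)
  if (config$use_inception) {
    for (k in config$conv_kernel_sizes) {
      F <- config$kernels_per_branch
      params[[paste0("convW", k)]] <- .glorot(k, F)
      params[[paste0("convb", k)]] <- matrix(0, 1, F)
    }
  }
  n_ch <- .n_channels(config)
  if (config$use_bilstm) {
    H <- config$recurrent_hidden
    for (l in seq_len(config$recurrent_layers)) {
      cin <- if (l == 1) n_ch else 2L * H
      for (d in c("f", "b")) {
        params[[paste0("Wx", l, d)]] <- .glorot(cin, 4 * H)
        params[[paste0("Wh", l, d)]] <- .glorot(H, 4 * H)
        b <- matrix(0, 1, 4 * H)
        b[1, (H + 1):(2 * H)] <- 1  # forget-gate bias
        params[[paste0("b", l, d)]] <- b
      }
    }
    flat <- L * 2L * H
  } else {
    flat <- L * n_ch
  }
  sizes <- c(flat, config$head_sizes)
  for (i in seq_along(config$head_sizes)) {
    params[[paste0("W", i)]] <- .glorot(sizes[i], sizes[i + 1])
    params[[paste0("hb", i)]] <- matrix(0, 1, sizes[i + 1])
  }
  params
}

#' Build a sub-model from its prior embedding
#'
#' The embedding parameter is initialized exactly (bit-for-bit) to the
#' prior matrix; all downstream weights are drawn from the given seed
#' (Glorot-uniform), so two builds with the same seed are identical.
#'
#' @param config A [submodel_config()].
#' @param prior A `prior_embedding` matching the config kind (MTP for
#'   M, normalized DRICS for D).
#' @param seed Integer seed for the downstream weights.
#' @return A `crispr_submodel`.
#' @export
build_submodel <- function(config, prior, seed = 1L) {
  stopifnot(inherits(config, "submodel_config"),
            inherits(prior, "prior_embedding"))
  expected <- if (config$kind == "M") "MTP" else "DRICS"
  if (prior$kind != expected) {
    abort(sprintf("config kind %s requires a %s prior", config$kind, expected))
  }
  if (prior$kind == "DRICS" && !prior$normalized) {
    abort("DRICS prior must be normalized before model construction")
  }
  params <- withr_seed(seed, .init_params(config, unname(prior$matrix)))
  structure(list(config = config, conv = prior$conv,
                 prior_kind = prior$kind, params = params,
                 seed = as.integer(seed)),
            class = "crispr_submodel")
}

#' @export
print.crispr_submodel <- function(x, ...) {
  cat(sprintf("<crispr_submodel> kind=%s L=%d params=%d seed=%d\n",
              x$config$kind, x$conv$L, n_parameters(x), x$seed))
  invisible(x)
}

#' Total number of scalar parameters of a sub-model
#' @param model A `crispr_submodel`.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' Current embedding matrix of a sub-model
#' @param model A `crispr_submodel`.
#' @export
embedding_matrix <- function(model) {
  m <- model$params$emb
  dimnames(m) <- list(paste0("row", seq_len(nrow(m))), .alphabet$tokens)
  m
}

#' Predict off-target probabilities
#'
#' @param object A `crispr_submodel`.
#' @param pairs Data frame with `guide_seq`/`target_seq` columns, or a
#'   pre-encoded integer matrix from [encode_pairs()].
#' @param ... Unused.
#' @return Numeric vector of probabilities in `(0, 1)`, one per pair,
#'   in input order.
#' @export
predict.crispr_submodel <- function(object, pairs, ...) {
  cols <- if (is.matrix(pairs)) pairs else encode_pairs(pairs, object$conv)
  if (ncol(cols) != object$conv$L) {
    abort(sprintf("encoded length %d does not match model L = %d",
                  ncol(cols), object$conv$L),
          class = "crispr_length_error")
  }
  p <- cpp_predict(unname(object$params), cols,
                   .cpp_cfg(object$config, object$conv$L))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Mean-fusion ensemble of the two sub-model outputs
#'
#' @param p_m,p_d Probability vectors from the M- and D-models.
#' @return Element-wise arithmetic mean.
#' @examples
#' ensemble_predict(c(0.2, 0.8), c(0.4, 0.6))
#' @export
ensemble_predict <- function(p_m, p_d) {
  if (length(p_m) != length(p_d)) {
    abort("sub-model prediction vectors differ in length")
  }
  (p_m + p_d) / 2
}
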