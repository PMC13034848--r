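#' Read / write sgRNA-off-target pair files
#'
#' Tab-separated, UTF-8, one pair per row, header
#' `sgrna_id guide_seq target_seq label dataset_id` (extra columns such
#' as `split` are preserved).
#'
#' @param path File path.
#' @return A tibble of pairs.
#' @export
read_pairs <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    sgrna_id = readr::col_character(),
    guide_seq = readr::col_character(),
    target_seq = readr::col_character(),
    label = readr::col_integer(),
    dataset_id = readr::col_character(),
    .default = readr::col_guess()))
  need <- c("sgrna_id", "guide_seq", "target_seq", "label", "dataset_id")
  if (!all(need %in% names(tb))) {
    abort(paste("pair file must have columns:", paste(need, collapse = " ")),
          class = "crispr_parse_error")
  }
  tb
}

#' @rdname read_pairs
#' @param pairs Pair tibble.
#' @export
write_pairs <- function(pairs, path) {
  readr::write_tsv(pairs, path)
  invisible(path)
}

#' Validate a pair file row by row
#'
#' Checks column presence, sequence alphabet (`A,C,G,T,N`), equal
#' guide/target lengths, binary labels, and length compatibility with
#' the convention (sequences one short of `L` are flagged as
#' normalizable by left-padding, counted as warnings).
#'
#' @param path Pair TSV path.
#' @param conv A [position_convention()].
#' @return A list: `n_rows`, `n_fatal`, `n_warnings`, `problems`
#'   (tibble `line`, `severity`, `message`), `ok`.
#' @export
validate_pairs_file <- function(path, conv = position_convention()) {
  if (!file.exists(path)) abort(paste("cannot read", path))
  tb <- tryCatch(read_pairs(path), error = function(e) NULL)
  if (is.null(tb)) {
    return(list(n_rows = 0L, n_fatal = 1L, n_warnings = 0L,
                problems = tibble::tibble(
                  line = 0L, severity = "fatal",
                  message = "unparseable file or missing columns"),
                ok = FALSE))
  }
  probs <- list()
  note <- function(line, severity, message) {
    probs[[length(probs) + 1]] <<- tibble::tibble(
      line = line + 1L, severity = severity, message = message)
  }
  n_pad <- length(conv$pad_rows)
  for (i in seq_len(nrow(tb))) {
    g <- tb$guide_seq[i]; t <- tb$target_seq[i]
    if (is.na(g) || is.na(t) || grepl("[^ACGTN]", paste0(g, t))) {
      note(i, "fatal", "sequence contains characters outside A,C,G,T,N")
      next
    }
    if (nchar(g) != nchar(t)) {
      note(i, "fatal", "guide and target lengths differ")
      next
    }
    if (!(tb$label[i] %in% c(0L, 1L)) || is.na(tb$label[i])) {
      note(i, "fatal", sprintf("label is %s, not 0/1", tb$label[i]))
      next
    }
    if (nchar(g) == conv$L - n_pad && n_pad > 0) {
      note(i, "warning", sprintf(
        "length %d normalized to %d by left-padding", nchar(g), conv$L))
    } else if (nchar(g) != conv$L) {
      note(i, "fatal", sprintf("length %d incompatible with L = %d",
                               nchar(g), conv$L))
    }
  }
  problems <- dplyr::bind_rows(probs)
  n_fatal <- if (nrow(problems)) sum(problems$severity == "fatal") else 0L
  n_warn <- if (nrow(problems)) sum(problems$severity == "warning") else 0L
  list(n_rows = nrow(tb), n_fatal = n_fatal, n_warnings = n_warn,
       problems = problems, ok = n_fatal == 0L)
}

#' Remove candidate guides similar to a reference set
#'
#' Guide identity is ungapped positional identity over the 20-mer
#' protospacer (matching positions / 20).  Candidates whose identity to
#' any reference guide reaches the threshold are removed -- the hygiene
#' filter that keeps test guides independent of training guides.
#'
#' @param candidate_guides,reference_guides Character vectors of
#'   20-mers.
#' @param threshold Identity fraction in `(0, 1]` (default 0.9).
#' @return A list with `kept` (character) and `removed` (tibble
#'   `guide`, `best_match`, `identity`).
#' @export
filter_similar_guides <- function(candidate_guides, reference_guides,
                                  threshold = 0.9) {
  if (!(threshold > 0 && threshold <= 1)) abort("threshold must be in (0,1]")
  lens <- nchar(c(candidate_guides, reference_guides))
  if (length(lens) && length(unique(lens)) > 1) {
    abort("all guides must have equal length (ungapped identity)",
          class = "crispr_length_error")
  }
  if (length(reference_guides) == 0) {
    return(list(kept = candidate_guides,
                removed = tibble::tibble(guide = character(),
                                         best_match = character(),
                                         identity = numeric())))
  }
  L <- nchar(candidate_guides[1])
  ref_mat <- do.call(rbind, lapply(reference_guides, .split_seq))
  removed <- list()
  keep <- logical(length(candidate_guides))
  for (i in seq_along(candidate_guides)) {
    cs <- .split_seq(candidate_guides[i])
    ident <- rowMeans(ref_mat == matrix(cs, nrow(ref_mat), L, byrow = TRUE))
    best <- which.max(ident)
    if (ident[best] >= threshold) {
      removed[[length(removed) + 1]] <- tibble::tibble(
        guide = candidate_guides[i],
        best_match = reference_guides[best],
        identity = ident[best])
    } else {
      keep[i] <- TRUE
    }
  }
  list(kept = candidate_guides[keep], removed = dplyr::bind_rows(
    c(list(tibble::tibble(guide = character(), best_match = character(),
                          identity = numeric())), removed)))
}

#' Write / read a predictions table
#'
#' TSV with columns `sgrna_id guide_seq target_seq label p_m p_d
#' p_ensemble`.
#'
#' @param predictions Prediction tibble.
#' @param path File path.
#' @export
write_predictions <- function(predictions, path) {
  readr::write_tsv(predictions, path)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  readr::read_tsv(path, col_types = readr::cols())
}

#' Predict with both sub-models and the ensemble
#'
#' @param pairs Pair tibble.
#' @param model_m,model_d Trained `crispr_submodel`s (either may be
#'   `NULL`, in which case its column is `NA` and the ensemble falls
#'   back to the available model).
#' @return The pair tibble plus `p_m`, `p_d`, `p_ensemble`.
#' @export
predict_pairs <- function(pairs, model_m = NULL, model_d = NULL) {
  if (is.null(model_m) && is.null(model_d)) {
    abort("at least one sub-model is required")
  }
  p_m <- if (!is.null(model_m)) predict(model_m, pairs) else NULL
  p_d <- if (!is.null(model_d)) predict(model_d, pairs) else NULL
  ens <- if (!is.null(p_m) && !is.null(p_d)) ensemble_predict(p_m, p_d)
         else if (!is.null(p_m)) p_m else p_d
  out <- dplyr::select(pairs, dplyr::any_of(
    c("sgrna_id", "guide_seq", "target_seq", "label", "dataset_id")))
  out$p_m <- if (is.null(p_m)) NA_real_ else p_m
  out$p_d <- if (is.null(p_d)) NA_real_ else p_d
  out$p_ensemble <- ens
  out
}

#' Run configuration read / write
#'
#' A single YAML file collecting the position convention, both
#' sub-model configs, the training config and analysis settings; it
#' round-trips losslessly.
#'
#' @param convention,model_m,model_d,train,metrics_threshold,analysis_alpha
#'   Components; defaults document themselves via the constructors.
#' @return A `run_config` list.
#' @export
run_config <- function(convention = list(L = 24L, n_pam = 3L,
                                         pad_token = "AA"),
                       model_m = submodel_config("M"),
                       model_d = submodel_config("D"),
                       train = train_config(),
                       metrics_threshold = 0.5,
                       analysis_alpha = 0.5) {
  structure(list(convention = convention,
                 model_m = unclass(model_m), model_d = unclass(model_d),
                 train = unclass(train),
                 metrics_threshold = metrics_threshold,
                 analysis_alpha = analysis_alpha),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  def <- run_config()
  cfg <- modifyList(unclass(def), raw)
  # restore integer types lost in YAML round-trip
  for (f in c("model_m", "model_d", "train")) {
    for (nm in names(cfg[[f]])) {
      if (is.numeric(cfg[[f]][[nm]]) && !nm %in%
          c("learning_rate", "pos_weight")) {
        cfg[[f]][[nm]] <- as.integer(cfg[[f]][[nm]])
      }
    }
  }
  structure(cfg, class = "run_config")
}
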