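#' Construct a prior table
#'
#' A prior table carries literature-style per-position, per-token values
#' over the twenty protospacer positions (biological coordinates,
#' PAM-proximal = 1): mismatch tolerance values for an MTP prior,
#' RNA-DNA interaction contribution scores for a DRICS prior.
#'
#' @param entries Data frame with columns `position` (integer 1-20),
#'   `token` (pairing token) and `value` (numeric).
#' @param kind `"MTP"` or `"DRICS"`.
#' @param provenance Free-text origin note.
#' @return A tibble of class `prior_table` with attributes `kind` and
#'   `provenance`.
#' @export
prior_table <- function(entries, kind = c("MTP", "DRICS"),
                        provenance = "unspecified") {
  kind <- match.arg(kind)
  need <- c("position", "token", "value")
  if (!all(need %in% names(entries))) {
    abort("prior table needs columns position, token, value",
          class = "crispr_parse_error")
  }
  tb <- tibble::as_tibble(entries[need])
  bad_pos <- which(!(tb$position %in% 1:20))
  if (length(bad_pos)) {
    abort(sprintf("row %d: position %s outside 1..20",
                  bad_pos[1], tb$position[bad_pos[1]]),
          class = "crispr_parse_error")
  }
  bad_tok <- which(!(tb$token %in% .alphabet$tokens))
  if (length(bad_tok)) {
    abort(sprintf("row %d: invalid token '%s'", bad_tok[1], tb$token[bad_tok[1]]),
          class = "crispr_parse_error")
  }
  if (any(!is.finite(tb$value))) {
    abort("non-finite prior value", class = "crispr_parse_error")
  }
  dup <- duplicated(tb[c("position", "token")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf("row %d: duplicate (position, token) = (%d, %s)",
                  i, tb$position[i], tb$token[i]),
          class = "crispr_parse_error")
  }
  tb$position <- as.integer(tb$position)
  structure(tb, class = c("prior_table", class(tb)),
            kind = kind, provenance = provenance)
}

#' Read a prior table from a TSV file
#'
#' Expected layout: tab-separated with header `position  token  value`.
#'
#' @param path File path.
#' @inheritParams prior_table
#' @return A [prior_table()].
#' @export
read_prior_table <- function(path, kind = c("MTP", "DRICS"),
                             provenance = path) {
  kind <- match.arg(kind)
  tb <- readr::read_tsv(path, col_types = readr::cols(
    position = readr::col_integer(),
    token = readr::col_character(),
    value = readr::col_double()))
  prior_table(tb, kind = kind, provenance = provenance)
}

#' @export
write_prior_table <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path)
  invisible(path)
}

.new_embedding <- function(matrix, kind, conv, normalized = FALSE,
                           v_max = NA_real_, v_min = NA_real_) {
  dimnames(matrix) <- list(
    paste0("row", seq_len(conv$L)), .alphabet$tokens)
  structure(list(matrix = matrix, kind = kind, conv = conv,
                 normalized = normalized, v_max = v_max, v_min = v_min),
            class = "prior_embedding")
}

#' @export
print.prior_embedding <- function(x, ...) {
  cat(sprintf("<prior_embedding> kind=%s L=%d normalized=%s\n",
              x$kind, x$conv$L, x$normalized))
  invisible(x)
}

.check_guide_only <- function(table) {
  # tables are in biological coordinates 1..20, so PAM rows cannot be
  # addressed; the 1..20 range check already enforces this.
  invisible(TRUE)
}

#' Build the initial MTP embedding space
#'
#' Every PAM (and pad) row entry and every match-token entry is 1;
#' mismatch entries present in the table are copied to the matrix row
#' given by the biological-position map; mismatch entries absent from
#' the table are treated as missing information and default to 1.
#'
#' @param table An MTP [prior_table()].
#' @param conv A [position_convention()].
#' @return A `prior_embedding` of kind `"MTP"`.
#' @export
build_mtp_init <- function(table, conv = position_convention()) {
  if (attr(table, "kind") != "MTP") abort("table kind must be MTP")
  if (any(table$token %in% .alphabet$match_set)) {
    abort("MTP priors are defined for mismatch tokens only",
          class = "crispr_parse_error")
  }
  M <- matrix(1, conv$L, 16L)
  rows <- conv$row_of_bio[table$position]
  M[cbind(rows, token_index(table$token))] <- table$value
  .new_embedding(M, "MTP", conv)
}

#' Build the initial DRICS embedding space
#'
#' PAM and pad rows are 0 (no literature information there); all guide
#' rows are copied from the table, which must cover all 16 tokens at all
#' 20 biological positions.
#'
#' @param table A DRICS [prior_table()].
#' @param conv A [position_convention()].
#' @return An unnormalized `prior_embedding` of kind `"DRICS"`.
#' @export
build_drics_init <- function(table, conv = position_convention()) {
  if (attr(table, "kind") != "DRICS") abort("table kind must be DRICS")
  full <- tidyr::expand_grid(position = 1:20, token = .alphabet$tokens)
  missing <- dplyr::anti_join(full, table, by = c("position", "token"))
  if (nrow(missing)) {
    abort(sprintf("incomplete DRICS table: missing (%d, %s) and %d more",
                  missing$position[1], missing$token[1], nrow(missing) - 1L),
          class = "crispr_incomplete_table")
  }
  D <- matrix(0, conv$L, 16L)
  D[cbind(conv$row_of_bio[table$position], token_index(table$token))] <-
    table$value
  .new_embedding(D, "DRICS", conv)
}

#' Piecewise normalization of a DRICS embedding
#'
#' Nonnegative raw entries are divided by the maximum raw score
#' `v_max`, negative entries by `|v_min|`, mapping the positive range
#' onto `[0, 1]` and the negative range onto `[-1, 0]` while preserving
#' signs and within-sign order.  `v_max`/`v_min` are scanned over guide
#' rows only (PAM/pad zeros are fill-ins, not scores).
#'
#' @param D An unnormalized DRICS `prior_embedding`.
#' @return The normalized embedding with `v_max`, `v_min` recorded.
#' @export
normalize_drics <- function(D) {
  stopifnot(inherits(D, "prior_embedding"))
  if (D$kind != "DRICS") abort("only DRICS embeddings are normalized")
  if (D$normalized) {
    abort("embedding is already normalized", class = "crispr_renormalize")
  }
  raw <- D$matrix[D$conv$guide_rows, , drop = FALSE]
  v_max <- max(raw); v_min <- min(raw)
  if (v_max <= 0 || v_min >= 0) {
    abort("degenerate raw range: need both positive and negative scores",
          class = "crispr_degenerate_range")
  }
  M <- D$matrix
  M[M >= 0] <- M[M >= 0] / v_max
  M[M < 0]  <- M[M < 0] / abs(v_min)
  .new_embedding(M, "DRICS", D$conv, normalized = TRUE,
                 v_max = v_max, v_min = v_min)
}

#' Export an embedding matrix as TSV plus side-car metadata
#'
#' The matrix file has row labels `row_i/bio_pos` and token column
#' labels; a side-car JSON records kind, L, PAM rows, normalization
#' state and the recorded range.
#'
#' @param emb A `prior_embedding`.
#' @param path Output TSV path; metadata goes to `<path>.meta.json`.
#' @export
write_embedding <- function(emb, path) {
  conv <- emb$conv
  bio <- ifelse(is.na(conv$bio_map), "-", conv$bio_map)
  tb <- tibble::as_tibble(emb$matrix)
  tb <- dplyr::bind_cols(
    tibble::tibble(row = paste0("row", seq_len(conv$L), "/", bio)), tb)
  readr::write_tsv(tb, path)
  meta <- list(kind = emb$kind, L = conv$L,
               pam_rows = conv$pam_rows, pad_rows = conv$pad_rows,
               normalized = emb$normalized,
               v_max = emb$v_max, v_min = emb$v_min)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read an embedding written by [write_embedding()]
#' @param path TSV path (side-car `<path>.meta.json` must exist).
#' @param conv The matching [position_convention()].
#' @return A `prior_embedding`.
#' @export
read_embedding <- function(path, conv = position_convention()) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  tb <- readr::read_tsv(path, col_types = readr::cols())
  M <- as.matrix(tb[, .alphabet$tokens])
  storage.mode(M) <- "double"
  .new_embedding(M, meta$kind, conv, normalized = isTRUE(meta$normalized),
                 v_max = if (is.null(meta$v_max)) NA_real_ else meta$v_max,
                 v_min = if (is.null(meta$v_min)) NA_real_ else meta$v_min)
}
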