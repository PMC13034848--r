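#' The guide/target base-pair alphabet
#'
#' Sixteen two-letter tokens describe how a guide (sgRNA) base pairs with
#' the protospacer-strand DNA base at one position.  The first letter is
#' the guide base (written in DNA letters, `T` standing for `U`), the
#' second the DNA base.  Tokens are kept in lexicographic canonical order
#' `AA, AC, AG, AT, CA, ..., TT`; the column index of every embedding
#' matrix follows this order.
#'
#' Four tokens are Watson-Crick matches (`AA`, `CC`, `GG`, `TT` --
#' guide A pairs the protospacer-strand A because complementarity is read
#' through the target strand).  The twelve mismatch tokens fall into four
#' groups keyed by the guide base: `rA = {AC, AG, AT}`, `rC = {CA, CG,
#' CT}`, `rG = {GA, GC, GT}`, `rT = {TA, TC, TG}`.  The wobble pairs
#' rU-dG and rG-dT are the tokens `TC` and `GA`.
#'
#' @return A list with elements `tokens` (character 16), `match_set`
#'   (character 4) and `mismatch_groups` (named list of four character
#'   triples).
#' @examples
#' pair_alphabet()$tokens
#' @export
pair_alphabet <- function() {
  bases <- c("A", "C", "G", "T")
  tokens <- as.vector(t(outer(bases, bases, paste0)))
  match_set <- c("AA", "CC", "GG", "TT")
  mm <- setdiff(tokens, match_set)
  groups <- split(mm, substr(mm, 1, 1))
  names(groups) <- paste0("r", names(groups))
  list(tokens = tokens, match_set = match_set,
       mismatch_groups = groups[c("rA", "rC", "rG", "rT")])
}

.alphabet <- pair_alphabet()

#' Token for one guide/target base pairing
#'
#' @param guide_base,target_base Single characters in `A,C,G,T`.
#' @return The two-letter token, guide base first.
#' @examples
#' pair_token("T", "C")   # the rU-dG wobble token
#' @export
pair_token <- function(guide_base, target_base) {
  ok <- guide_base %in% c("A", "C", "G", "T") &
    target_base %in% c("A", "C", "G", "T")
  if (!all(ok)) {
    abort(paste0("invalid base(s): ",
                 paste(unique(c(guide_base[!ok], target_base[!ok])),
                       collapse = ", ")),
          class = "crispr_invalid_base")
  }
  paste0(guide_base, target_base)
}

#' Canonical column index of a token
#' @param token Two-letter token(s).
#' @return Integer index in `1..16`.
#' @export
token_index <- function(token) {
  idx <- match(token, .alphabet$tokens)
  if (anyNA(idx)) {
    abort(paste0("unknown token(s): ",
                 paste(unique(token[is.na(idx)]), collapse = ", ")),
          class = "crispr_invalid_token")
  }
  idx
}

#' Mismatch group of a mismatch token
#'
#' Groups are keyed by the guide base: `rA`, `rC`, `rG`, `rT`.
#'
#' @param token Mismatch token(s).
#' @return Character vector of group names.
#' @examples
#' mismatch_group("AG")  # "rA"
#' @export
mismatch_group <- function(token) {
  token_index(token)  # validates
  if (any(token %in% .alphabet$match_set)) {
    abort("match tokens have no mismatch group",
          class = "crispr_not_a_mismatch")
  }
  paste0("r", substr(token, 1, 1))
}

#' Position convention for length-L pair encodings
#'
#' Rows of the embedding matrices run 5' to 3'.  The default layout for
#' `L = 24` is one left pad row (flanking context, treated as matched),
#' the twenty protospacer rows, then the three PAM rows (NGG).
#' Biological positions count from the PAM: biological position 1 is the
#' PAM-proximal protospacer base (row 21 under the default), position 20
#' the PAM-distal base (row 2).  Positions 1-10 form the seed region,
#' 11-20 the non-seed region.
#'
#' @param L Total encoded length (default 24).
#' @param n_pam Number of PAM rows at the 3' end (default 3).
#' @param pad_token Token used to fill pad rows when a sequence shorter
#'   than `L` is left-padded (default `"AA"`).
#' @return A `position_convention` list with `L`, `guide_rows`,
#'   `pam_rows`, `pad_rows`, `pad_token`, `bio_map` (length-`L` integer,
#'   `NA` off the guide rows) and `row_of_bio` (length-20 integer).
#' @export
position_convention <- function(L = 24L, n_pam = 3L, pad_token = "AA") {
  L <- as.integer(L); n_pam <- as.integer(n_pam)
  n_pad <- L - 20L - n_pam
  if (n_pad < 0L) abort("L too small for 20 guide rows plus the PAM")
  token_index(pad_token)
  pad_rows <- if (n_pad > 0L) seq_len(n_pad) else integer(0)
  guide_rows <- n_pad + 1:20
  pam_rows <- (n_pad + 21L):L
  bio_map <- rep(NA_integer_, L)
  # biological position 1 = PAM-proximal = 3'-most guide row
  bio_map[guide_rows] <- rev(seq_len(20L))
  row_of_bio <- vapply(1:20, function(p) which(bio_map == p), integer(1))
  structure(list(L = L, guide_rows = guide_rows, pam_rows = pam_rows,
                 pad_rows = pad_rows, pad_token = pad_token,
                 bio_map = bio_map, row_of_bio = row_of_bio),
            class = "position_convention")
}

#' @export
print.position_convention <- function(x, ...) {
  cat("Position convention: L =", x$L,
      "| pad rows:", length(x$pad_rows),
      "| guide rows:", paste0(min(x$guide_rows), "-", max(x$guide_rows)),
      "| PAM rows:", paste0(min(x$pam_rows), "-", max(x$pam_rows)), "\n")
  invisible(x)
}

.split_seq <- function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]]

#' Encode one guide/target pair as embedding indices
#'
#' Each position becomes a (row, column) index into an `L x 16` embedding
#' matrix: the row is the position, the column the canonical index of the
#' pairing token.  Sequences of length `L - length(pad_rows)` are
#' left-padded using the convention's pad token.  `N` is accepted only in
#' PAM rows, where it is resolved to the match token of the opposing base
#' (the PAM prior values are constant so the choice does not alter prior
#' semantics).
#'
#' @param guide_seq,target_seq Equal-length nucleotide strings.
#' @param conv A [position_convention()].
#' @return A list with `rows` (integer `1..L`), `cols` (integer in
#'   `1..16`), `tokens` (character L) and `L`.
#' @export
encode_pair <- function(guide_seq, target_seq, conv = position_convention()) {
  g <- .split_seq(guide_seq); t <- .split_seq(target_seq)
  if (length(g) != length(t)) {
    abort("guide and target sequences differ in length",
          class = "crispr_length_error")
  }
  n_pad <- length(conv$pad_rows)
  if (length(g) == conv$L - n_pad && n_pad > 0L) {
    pg <- .split_seq(conv$pad_token)
    g <- c(rep(pg[1], n_pad), g)
    t <- c(rep(pg[2], n_pad), t)
  }
  if (length(g) != conv$L) {
    abort(sprintf("sequence length %d does not fit convention L = %d",
                  length(g), conv$L),
          class = "crispr_length_error")
  }
  # resolve N in PAM rows to the match token of the opposing base
  for (i in conv$pam_rows) {
    if (g[i] == "N" && t[i] == "N") { g[i] <- "A"; t[i] <- "A" }
    else if (g[i] == "N") g[i] <- t[i]
    else if (t[i] == "N") t[i] <- g[i]
  }
  if (any(g == "N") || any(t == "N")) {
    abort("ambiguity code N outside the PAM rows",
          class = "crispr_invalid_base")
  }
  tokens <- pair_token(g, t)
  list(rows = seq_len(conv$L), cols = token_index(tokens),
       tokens = tokens, L = conv$L)
}

#' Encode a table of guide/target pairs
#'
#' Vectorized companion of [encode_pair()]: returns the integer matrix of
#' embedding column indices that the network consumes.
#'
#' @param pairs Data frame with `guide_seq` and `target_seq` columns.
#' @param conv A [position_convention()].
#' @return Integer matrix, `nrow(pairs)` by `L`, entries in `1..16`.
#' @export
encode_pairs <- function(pairs, conv = position_convention()) {
  stopifnot(is.data.frame(pairs))
  out <- matrix(0L, nrow(pairs), conv$L)
  for (i in seq_len(nrow(pairs))) {
    out[i, ] <- encode_pair(pairs$guide_seq[i], pairs$target_seq[i], conv)$cols
  }
  out
}

#' Decode an encoded pair back to its token sequence
#' @param enc Result of [encode_pair()] (or a bare integer column vector).
#' @return Character vector of tokens.
#' @export
decode_tokens <- function(enc) {
  cols <- if (is.list(enc)) enc$cols else enc
  .alphabet$tokens[cols]
}
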