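test_that("prior tables validate tokens, positions and duplicates", {
  tb <- data.frame(position = c(1, 5), token = c("AC", "GA"),
                   value = c(0.4, 0.2))
  expect_s3_class(prior_table(tb, "MTP"), "prior_table")
  expect_error(prior_table(transform(tb, token = c("AU", "GA")), "MTP"),
               class = "crispr_parse_error")
  expect_error(prior_table(transform(tb, position = c(0, 5)), "MTP"),
               class = "crispr_parse_error")
  dup <- rbind(tb, tb[1, ])
  expect_error(prior_table(dup, "MTP"), class = "crispr_parse_error")
})

test_that("prior table TSV round-trips through read/write", {
  tb <- random_mtp_table(11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_prior_table(tb, path)
  back <- read_prior_table(path, "MTP")
  expect_equal(as.data.frame(back), as.data.frame(tb), ignore_attr = TRUE)
  expect_equal(nrow(read_prior_table(path, "MTP")), 60)
})

test_that("MTP construction matches the fill rules entry-wise on random tables", {
  conv <- position_convention()
  for (seed in c(3, 9, 27)) {
    tb <- random_mtp_table(seed)
    emb <- build_mtp_init(tb, conv)
    # oracle: evaluate the rule directly for every cell
    for (i in seq_len(conv$L)) {
      for (j in 1:16) {
        tok <- alpha$tokens[j]
        expected <- 1
        if (i %in% conv$guide_rows && !(tok %in% alpha$match_set)) {
          hit <- tb$position == conv$bio_map[i] & tb$token == tok
          if (any(hit)) expected <- tb$value[hit]
        }
        expect_identical(unname(emb$matrix[i, j]), expected)
      }
    }
  }
})

test_that("MTP rejects match-token entries", {
  tb <- prior_table(data.frame(position = 1, token = "AA", value = 0.3),
                    "MTP")
  expect_error(build_mtp_init(tb), class = "crispr_parse_error")
})

test_that("DRICS construction copies the full grid and zeroes PAM/pad rows", {
  conv <- position_convention()
  tab <- gen_prior_table("DRICS", 5)
  emb <- build_drics_init(tab, conv)
  expect_true(all(emb$matrix[conv$pam_rows, ] == 0))
  expect_true(all(emb$matrix[conv$pad_rows, ] == 0))
  # entry-wise oracle over guide rows
  for (k in sample(nrow(tab), 50)) {
    i <- conv$row_of_bio[tab$position[k]]
    j <- token_index(tab$token[k])
    expect_identical(unname(emb$matrix[i, j]), tab$value[k])
  }
})

test_that("an incomplete DRICS table is rejected", {
  tab <- gen_prior_table("DRICS", 5)
  short <- prior_table(as.data.frame(tab)[-10, ], "DRICS")
  expect_error(build_drics_init(short), class = "crispr_incomplete_table")
})

test_that("piecewise normalization maps extremes to +/-1, keeps zeros and order", {
  conv <- position_convention()
  tab <- gen_prior_table("DRICS", 8)
  raw <- build_drics_init(tab, conv)
  norm <- normalize_drics(raw)
  g <- raw$matrix[conv$guide_rows, ]
  gn <- norm$matrix[conv$guide_rows, ]
  expect_equal(norm$v_max, max(g))
  expect_equal(norm$v_min, min(g))
  expect_equal(max(gn), 1)
  expect_equal(min(gn), -1)
  expect_true(all(gn >= -1 & gn <= 1))
  expect_true(all(sign(gn) == sign(g)))
  expect_true(all(norm$matrix[conv$pam_rows, ] == 0))
  # order preservation within each sign class
  pos <- g[g >= 0]; posn <- gn[g >= 0]
  expect_identical(order(pos), order(posn))
  neg <- g[g < 0]; negn <- gn[g < 0]
  expect_identical(order(neg), order(negn))
})

test_that("normalizing twice or a one-signed table errors", {
  conv <- position_convention()
  norm <- normalize_drics(build_drics_init(gen_prior_table("DRICS", 2), conv))
  expect_error(normalize_drics(norm), class = "crispr_renormalize")
  allpos <- tidyr::expand_grid(position = 1:20, token = alpha$tokens)
  allpos$value <- 1
  bad <- build_drics_init(prior_table(allpos, "DRICS"), conv)
  expect_error(normalize_drics(bad), class = "crispr_degenerate_range")
})

test_that("embedding TSV export round-trips with metadata", {
  conv <- position_convention()
  emb <- normalize_drics(build_drics_init(gen_prior_table("DRICS", 4), conv))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_embedding(emb, path)
  back <- read_embedding(path, conv)
  expect_equal(back$matrix, emb$matrix)
  expect_identical(back$kind, "DRICS")
  expect_true(back$normalized)
  expect_equal(back$v_max, emb$v_max)
})
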