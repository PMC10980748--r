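test_that("fit_ols equals the pseudoinverse solution and recovers exact maps", {
  # noiseless identifiability: Y = XW + b recovered to 1e-8
  X <- withr::with_seed(1, matrix(stats::rnorm(30 * 5), 30))
  W <- withr::with_seed(2, matrix(stats::rnorm(5 * 4), 5))
  b <- 1:4
  Y <- X %*% W + rep(b, each = 30)
  map <- fit_ols(X, Y)
  expect_lt(max(abs(map$weights[-1, ] - W)), 1e-8)
  expect_lt(max(abs(map$weights[1, ] - b)), 1e-8)
  # dense least-squares oracle via SVD pseudoinverse on random problems
  for (s in 1:5) {
    Xr <- withr::with_seed(10 + s, matrix(stats::rnorm(20 * 5), 20))
    Yr <- withr::with_seed(20 + s, matrix(stats::rnorm(20 * 3), 20))
    D <- cbind(1, Xr)
    sv <- svd(D)
    pinv_w <- sv$v %*% diag(1 / sv$d) %*% t(sv$u) %*% Yr
    expect_equal(unname(fit_ols(Xr, Yr)$weights), pinv_w, tolerance = 1e-8)
  }
  # constant column + intercept is singular
  expect_error(fit_ols(cbind(rep(1, 30), X), Y), "singular")
  expect_error(fit_ols(X[1:4, ], Y[1:4, ]), "training rows")
})

test_that("per-word pattern correlation matches the textbook Pearson oracle", {
  X <- withr::with_seed(3, matrix(stats::rnorm(40 * 4), 40))
  Y <- withr::with_seed(4, matrix(stats::rnorm(40 * 6), 40))
  map <- fit_ols(X, Y)
  sc <- score_zero_shot(map, X[1:10, ], Y[1:10, ])
  pred <- cbind(1, X[1:10, ]) %*% map$weights
  for (i in 1:10) {
    p <- pred[i, ]; o <- Y[i, ]
    oracle <- sum((p - mean(p)) * (o - mean(o))) /
      sqrt(sum((p - mean(p))^2) * sum((o - mean(o))^2))
    expect_equal(sc$per_word_r[i], oracle, tolerance = 1e-12)
  }
  # predictions identical to observations: r = 1; negated (mean-centred): -1
  idmap <- list(weights = rbind(0, diag(6)))
  class(idmap) <- "linear_map"
  Yc <- Y - rowMeans(Y)
  expect_equal(score_zero_shot(idmap, Yc[1:5, ], Yc[1:5, ])$per_word_r,
               rep(1, 5))
  expect_equal(score_zero_shot(idmap, -Yc[1:5, ], Yc[1:5, ])$per_word_r,
               rep(-1, 5))
  # zero-variance observed pattern: word dropped with a message
  Y2 <- Y[1:3, ]; Y2[2, ] <- 7
  expect_message(sc2 <- score_zero_shot(map, X[1:3, ], Y2), "zero-variance")
  expect_true(is.na(sc2$per_word_r[2]))
  expect_error(score_zero_shot(map, X[1:2, ], Y[1:2, 1, drop = FALSE]),
               ">= 2 electrodes")
})

test_that("nearest-neighbour control matches the exhaustive cosine argmax", {
  tr <- withr::with_seed(5, matrix(stats::rnorm(50 * 20), 50))
  te <- withr::with_seed(6, matrix(stats::rnorm(12 * 20), 12))
  res <- nearest_train_control(tr, te)
  for (i in 1:12) {
    sims <- apply(tr, 1, function(v)
      sum(v * te[i, ]) / sqrt(sum(v^2) * sum(te[i, ]^2)))
    expect_equal(res$index[i], which.max(sims))
  }
  # a test row equal to a training row selects it (similarity 1)
  res2 <- nearest_train_control(tr, tr[7, , drop = FALSE])
  expect_equal(res2$index, 7L, ignore_attr = TRUE)
  # singleton training set is substituted regardless
  res3 <- nearest_train_control(tr[1, , drop = FALSE], te)
  expect_true(all(res3$index == 1))
  expect_error(nearest_train_control(matrix(0, 1, 3), te[, 1:3]),
               "zero-norm")
})

test_that("zero-shot encoding orders variants correctly on synthetic data", {
  s <- tiny_setup(n_types = 60, embed_dim = 16, n_el = 12, cone = 20,
                  noise_sd = 0, k = 6)
  br <- oracle_brain_embeddings(s$fs$events, s$sel_table, s$gt, c(0, 200))
  enc <- zs_encode(s$sel_table, br, s$fs, seed = 2)
  sm <- summary(enc)
  peak <- function(v) sm$mean_r[sm$variant == v & sm$lag_ms == 200]
  expect_gt(peak("actual"), 0.95)
  expect_gt(peak("actual"), peak("nearest"))
  expect_gt(peak("nearest"), peak("shuffled"))
  expect_s3_class(enc, "zs_encoding")
  expect_output(print(enc), "peak mean r")
})

test_that("no cross-test coupling: other words' scores are unchanged when one word is removed", {
  s <- tiny_setup(n_types = 40, embed_dim = 10, n_el = 8, k = 4)
  br <- oracle_brain_embeddings(s$fs$events, s$sel_table, s$gt, 200)
  enc <- zs_encode(s$sel_table, br, s$fs, variants = "actual")
  # drop one test word of fold 0 and refit by hand
  ev <- s$fs$events
  drop_ix <- which(ev$fold == 0)[1]
  tr <- which(ev$fold != 0); te <- setdiff(which(ev$fold == 0), drop_ix)
  map <- fit_ols(unclass(s$sel_table)[tr, ], br[[1]][tr, ])
  r2 <- score_zero_shot(map, unclass(s$sel_table)[te, ],
                        br[[1]][te, ])$per_word_r
  orig <- enc$scores$r[match(ev$token[te], enc$scores$word)]
  expect_equal(r2, orig, tolerance = 1e-12)
})

test_that("breaking the shared electrode geometry destroys the alignment", {
  s <- tiny_setup(n_types = 60, embed_dim = 16, n_el = 12, k = 6)
  br <- oracle_brain_embeddings(s$fs$events, s$sel_table, s$gt, 200)
  # electrode-wise permutation applied to the test fold's rows only (the
  # training side keeps the true geometry); any single permutation has a
  # small fixed offset from the chance alignment of the map with its
  # permuted self, so the mean over random permutations is tested
  ev <- s$fs$events
  te <- which(ev$fold == 0); tr <- which(ev$fold != 0)
  map <- fit_ols(unclass(s$sel_table)[tr, ], br[[1]][tr, ])
  means <- vapply(1:20, function(rep) {
    perm <- withr::with_seed(700 + rep, sample.int(12))
    score_zero_shot(map, unclass(s$sel_table)[te, ],
                    br[[1]][te, perm])$mean_r
  }, numeric(1))
  ci <- mean(means) + c(-1, 1) * 2 * stats::sd(means) / sqrt(length(means))
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("contextual embeddings beat their static per-type collapse", {
  # wide cone + several occurrences per type: the per-type mean visibly
  # differs from the selected instance, so the contextual table should win
  st <- generate_stream(60, 300, 600, seed = 11)
  tab <- generate_contextual_table(st, 16, 40, seed = 12)
  W <- withr::with_seed(16, matrix(stats::rnorm(12 * 16), 12))
  gt <- ground_truth(W, noise_sd = 0.1)
  sel <- select_unique_instances(st, seed = 13)
  fs <- make_folds(sel, 6)
  s <- list(stream = st, table = tab, gt = gt, sel = sel, fs = fs,
            sel_table = tab[sel$row_idx, , drop = FALSE])
  br <- oracle_brain_embeddings(s$fs$events, s$sel_table, s$gt, 200,
                                seed = 31)
  static <- collapse_to_static(s$table, s$stream$type_id)
  sel_static <- static[s$sel$row_idx, , drop = FALSE]
  enc_c <- zs_encode(s$sel_table, br, s$fs, variants = "actual")
  enc_s <- zs_encode(sel_static, br, s$fs, variants = "actual")
  expect_gt(summary(enc_c)$mean_r, summary(enc_s)$mean_r)
})

test_that("encoding results export to TSV with the documented columns", {
  s <- tiny_setup(n_types = 20, embed_dim = 8, n_el = 6, k = 4)
  br <- oracle_brain_embeddings(s$fs$events, s$sel_table, s$gt, 200)
  enc <- zs_encode(s$sel_table, br, s$fs, variants = "actual")
  f <- withr::local_tempfile(fileext = ".tsv")
  save_encoding(enc, f)
  back <- utils::read.table(f, sep = "\t", header = TRUE)
  expect_equal(names(back), c("lag_ms", "variant", "word", "r"))
  expect_true(file.exists(sub("\\.tsv$", "_summary.tsv", f)))
})
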