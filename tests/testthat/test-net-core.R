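test_that("connection counts cover weights of every block plus biases", {
  expect_equal(count_connections(network_spec(2, 1)), 9L)
  # skip blocks add their full source-by-destination count
  # net7 on 8-3-2-3: (8*3 + 3*2 + 2*3 + 8*2 + 8*3) + (3 + 2 + 3) = 84
  expect_equal(count_connections(network_spec(8, 3, 2, "net7")), 84L)
  expect_equal(count_connections(network_spec(4, 12)), 99L)
  expect_equal(count_connections(network_spec(8, 11, 8, "net3")), 222L)
})

test_that("patterns are strictly forward and validated against layer counts", {
  for (id in paste0("net", 1:7)) {
    p <- connectivity_pattern(id)
    ord <- match(c("IN", "L1", "L2", "OUT"), p$layers)
    for (bl in p$blocks) {
      e <- strsplit(bl, "->", fixed = TRUE)[[1]]
      expect_lt(ord[match(e[1], c("IN", "L1", "L2", "OUT"))],
                ord[match(e[2], c("IN", "L1", "L2", "OUT"))])
    }
  }
  expect_error(network_spec(4, 3, 0, "net3"), "units_hidden")
  expect_error(network_spec(4, 3, 2, "net1"), "one-layer")
})

test_that("Nguyen-Widrow initialization is seeded and correctly scaled", {
  spec <- network_spec(6, 5, 4, "net6")
  w1 <- nguyen_widrow_init(spec, seed = 7)
  w2 <- nguyen_widrow_init(spec, seed = 7)
  expect_identical(w1, w2)
  w3 <- nguyen_widrow_init(spec, seed = 8)
  expect_false(identical(w1$W, w3$W))
  # per-unit incoming weight vectors have the Nguyen-Widrow magnitude
  expect_equal(sqrt(colSums(w1$W[["IN->L1"]]^2)),
               rep(nw_scale(5, 6), 5))
  # L2 receives IN and L1 under net6: fan-in 6 + 5
  stacked <- rbind(w1$W[["IN->L2"]], w1$W[["L1->L2"]])
  expect_equal(sqrt(colSums(stacked^2)), rep(nw_scale(4, 11), 4))
  # biases spread uniformly over [-beta, beta]
  expect_equal(w1$b$L1, nw_scale(5, 6) * seq(-1, 1, length.out = 5))
})

test_that("forward pass matches a hand-computed example and normalizes", {
  spec <- network_spec(2, 1)
  w <- nguyen_widrow_init(spec, seed = 1)
  # zeroed parameters give the uniform distribution
  w0 <- w
  w0$W <- lapply(w0$W, function(m) m * 0)
  w0$b <- lapply(w0$b, function(v) v * 0)
  expect_equal(as.vector(forward(spec, w0, c(3, 9))), rep(1 / 3, 3))
  # manual arithmetic oracle for 2 -> 1 -> 3
  w$W[["IN->L1"]] <- matrix(c(0.3, -0.2), 2, 1)
  w$b$L1 <- 0.1
  w$W[["L1->OUT"]] <- matrix(c(0.5, -1, 0.25), 1, 3)
  w$b$OUT <- c(0.05, 0, -0.05)
  x <- c(0.5, -0.25)
  h <- tanh(0.3 * 0.5 + (-0.2) * (-0.25) + 0.1)
  z <- c(0.5 * h + 0.05, -1 * h, 0.25 * h - 0.05)
  expect_equal(as.vector(forward(spec, w, x)), exp(z) / sum(exp(z)))
  # probabilities always sum to one
  set.seed(2)
  p <- forward(spec, nguyen_widrow_init(spec, 2),
               matrix(runif(20, -1, 1), 10, 2))
  expect_equal(rowSums(p), rep(1, 10))
  expect_error(forward(spec, w, c(1, 2, 3)), "columns")
})

test_that("cross-entropy has its closed-form values and stays finite", {
  expect_equal(cross_entropy(rbind(c(1, 0, 0)), rbind(c(1, 0, 0))), 0)
  expect_equal(cross_entropy(rbind(c(0, 1, 0)), rbind(rep(1 / 3, 3))),
               log(3))
  # zero predicted probability at the target class is clamped, not -Inf
  expect_true(is.finite(cross_entropy(rbind(c(0, 1, 0)),
                                      rbind(c(1, 0, 0)))))
  set.seed(3)
  for (i in 1:20) {
    y <- matrix(runif(15), 5, 3)
    y <- y / rowSums(y)
    t <- diag(3)[sample(3, 5, replace = TRUE), ]
    expect_gte(cross_entropy(t, y), 0)
  }
})

test_that("the learning-rate rule reverts above the ratio and keeps at it", {
  cfg <- train_config()
  up <- adapt_lr(1.05, 1.00, 0.01, cfg)
  expect_false(up$keep)
  expect_equal(up$lr, 0.007)
  keep <- adapt_lr(1.00, 1.00, 0.01, cfg)
  expect_true(keep$keep)
  expect_equal(keep$lr, 0.0105)
  # the threshold is a strict inequality
  boundary <- adapt_lr(1.04, 1.00, 0.01, cfg)
  expect_true(boundary$keep)
  expect_equal(boundary$lr, 0.0105)
})

test_that("analytic gradients match central finite differences on every pattern", {
  set.seed(11)
  for (id in paste0("net", 1:7)) {
    hidden <- if (id %in% c("net1", "net2")) 0L else 2L
    spec <- network_spec(3, 2, hidden, id)
    w <- nguyen_widrow_init(spec, seed = match(id, paste0("net", 1:7)))
    x <- matrix(runif(12, -1, 1), 4, 3)
    y <- diag(3)[c(1, 2, 3, 1), ]
    g <- ohcnet:::.gradients(spec, w, x, y)
    h <- 1e-5
    for (bl in names(w$W)) {
      for (i in seq_along(w$W[[bl]])) {
        wp <- w; wp$W[[bl]][i] <- wp$W[[bl]][i] + h
        wm <- w; wm$W[[bl]][i] <- wm$W[[bl]][i] - h
        fd <- (cross_entropy(y, forward(spec, wp, x)) -
                 cross_entropy(y, forward(spec, wm, x))) / (2 * h)
        expect_equal(g$W[[bl]][i], fd, tolerance = 1e-6)
      }
    }
    for (l in names(w$b)) {
      for (i in seq_along(w$b[[l]])) {
        wp <- w; wp$b[[l]][i] <- wp$b[[l]][i] + h
        wm <- w; wm$b[[l]][i] <- wm$b[[l]][i] - h
        fd <- (cross_entropy(y, forward(spec, wp, x)) -
                 cross_entropy(y, forward(spec, wm, x))) / (2 * h)
        expect_equal(g$b[[l]][i], fd, tolerance = 1e-6)
      }
    }
  }
  # and for the logistic variant of the internal units
  spec <- network_spec(3, 2, 2, "net5", activation = "logistic")
  w <- nguyen_widrow_init(spec, seed = 5)
  x <- matrix(runif(9, -1, 1), 3, 3)
  y <- diag(3)
  g <- ohcnet:::.gradients(spec, w, x, y)
  i <- 1
  h <- 1e-5
  wp <- w; wp$W[["IN->L1"]][i] <- wp$W[["IN->L1"]][i] + h
  wm <- w; wm$W[["IN->L1"]][i] <- wm$W[["IN->L1"]][i] - h
  fd <- (cross_entropy(y, forward(spec, wp, x)) -
           cross_entropy(y, forward(spec, wm, x))) / (2 * h)
  expect_equal(g$W[["IN->L1"]][i], fd, tolerance = 1e-6)
})

test_that("accuracy uses first-index tie-breaking and ignores sample order", {
  spec <- network_spec(4, 1)
  w <- nguyen_widrow_init(spec, seed = 1)
  w$W <- lapply(w$W, function(m) m * 0)
  w$b <- lapply(w$b, function(v) v * 0)
  x <- matrix(runif(36), 9, 4)
  y <- diag(3)[rep(1:3, 3), ]
  # uniform outputs predict class 1 everywhere: a third of a balanced set
  expect_equal(accuracy(spec, w, x, y), 1 / 3)
  w2 <- nguyen_widrow_init(spec, seed = 2)
  perm <- sample(9)
  expect_equal(accuracy(spec, w2, x, y),
               accuracy(spec, w2, x[perm, ], y[perm, ]))
  expect_error(accuracy(spec, w, x[0, , drop = FALSE], y[0, , drop = FALSE]),
               "empty")
})

test_that("training is deterministic, respects the ratio bound and the goal", {
  subset <- fixture_subset("formal11", "B")
  spec <- network_spec(8, 3)
  r1 <- train_network(spec, subset, config = fast_config(), seed = 5)
  r2 <- train_network(spec, subset, config = fast_config(), seed = 5)
  expect_identical(r1$weights, r2$weights)
  expect_identical(r1$trace, r2$trace)
  # retained consecutive epochs never worsen CE by more than the ratio
  kept_ce <- r1$trace$train_ce[r1$trace$kept == 1]
  if (length(kept_ce) > 1)
    expect_true(all(diff(log(kept_ce)) <= log(1.04) + 1e-12))
  expect_true(r1$stop_reason %in%
                c("goal_met", "validation_failures", "max_epochs"))
})

test_that("a zero learning-rate mask freezes a block bit-for-bit", {
  subset <- fixture_subset("formal11", "B")
  spec <- network_spec(8, 3)
  init <- nguyen_widrow_init(spec, seed = 9)
  mask <- ones_mask(spec)
  mask$W[["IN->L1"]][] <- 0
  res <- train_network(spec, subset, config = fast_config(), initial = init,
                       lr_mask = mask, seed = 9)
  expect_identical(res$weights$W[["IN->L1"]], init$W[["IN->L1"]])
  expect_false(identical(res$weights$W[["L1->OUT"]], init$W[["L1->OUT"]]))
})

test_that("trained weights carry the input mapping and accept raw inputs", {
  subset <- fixture_subset("formal11", "B")
  spec <- network_spec(8, 2)
  res <- train_network(spec, subset, config = fast_config(), seed = 3)
  expect_false(is.null(res$weights$input_map))
  mapped <- ohcnet:::.apply_input_map(subset$x, res$weights$input_map)
  expect_true(all(mapped >= -1 & mapped <= 1))
  bare <- res$weights
  bare$input_map <- NULL
  expect_equal(forward(spec, res$weights, subset$x),
               forward(spec, bare, mapped))
})

test_that("random division is seeded and proportioned", {
  d1 <- divide_random(100, seed = 4)
  d2 <- divide_random(100, seed = 4)
  expect_identical(d1, d2)
  expect_equal(as.integer(table(factor(d1, c("train", "validation",
                                             "test")))),
               c(70L, 15L, 15L))
  expect_false(identical(divide_random(100, 5), d1))
})

test_that("weight states round-trip through their text serialization", {
  subset <- fixture_subset("formal11", "B")
  spec <- network_spec(8, 2)
  res <- train_network(spec, subset, config = fast_config(), seed = 3)
  path <- file.path(withr::local_tempdir(), "weights.json")
  write_weights(res$weights, path)
  back <- read_weights(path)
  for (bl in names(res$weights$W))
    expect_equal(back$W[[bl]], res$weights$W[[bl]], ignore_attr = TRUE)
  expect_equal(forward(spec, back, subset$x[1:5, ]),
               forward(spec, res$weights, subset$x[1:5, ]))
  # epoch log round-trips too
  lp <- file.path(withr::local_tempdir(), "log.tsv")
  write_train_log(res, lp)
  expect_equal(nrow(read.table(lp, header = TRUE)), res$epochs_run)
})
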