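test_that("weight_network scores base edges per the weighting rule", {
  base <- data.frame(protein_a = c("A", "A"), protein_b = c("B", "C"))
  scored <- data.frame(protein_a = c("B", "X"), protein_b = c("A", "Y"),
                       score = c(900L, 800L))
  net <- weight_network(base, scored)
  smap <- stats::setNames(net$edges$score,
                          paste(net$edges$protein_a, net$edges$protein_b))
  expect_equal(unname(smap[["A B"]]), 900L)   # scored edge takes its score
  expect_equal(unname(smap[["A C"]]), 1L)     # unscored base edge -> 1
  expect_false("X" %in% net$nodes)            # scored pair absent from base
  expect_error(weight_network(base[0, ]), "empty base")

  dropped <- weight_network(base, scored, drop_unscored = TRUE)
  expect_equal(nrow(dropped$edges), 1L)
})

test_that("collapse_cycles averages within-cycle positions", {
  vals <- matrix(0, 2, 36)
  vals[1, c(1, 13, 25)] <- c(1, 2, 3)
  vals[2, ] <- seq_len(36)
  et <- expression_table(c("G1", "G2"), vals)
  out <- collapse_cycles(et, 3L)
  expect_equal(out$n_time, 12L)
  expect_equal(unname(out$values["G1", 1]), 2)          # mean(1, 2, 3)
  expect_equal(unname(out$values["G2", 5]), mean(c(5, 17, 29)))
  expect_identical(collapse_cycles(et, 1L), et)
  expect_error(collapse_cycles(et, 5L), "not divisible")
})

test_that("normalization maps each gene to its [0, 1] undulation scale", {
  et <- expression_table(c("G1", "G2"), rbind(c(2, 4, 6), c(5, 5, 5)))
  gep <- normalize_expression(et)
  expect_equal(unname(gep$gep["G1", ]), c(0, 0.5, 1))
  expect_equal(unname(gep$gep["G2", ]), c(0, 0, 0))  # degenerate gene

  set.seed(7)
  rnd <- expression_table(paste0("R", 1:20), matrix(rnorm(200), 20))
  g2 <- normalize_expression(rnd)
  expect_true(all(g2$gep >= 0 & g2$gep <= 1))
  expect_equal(unname(apply(g2$gep, 1, min)), rep(0, 20))
  expect_equal(unname(apply(g2$gep, 1, max)), rep(1, 20))
})

test_that("activity threshold is inclusive and validated", {
  gep <- normalize_expression(expression_table("G", rbind(c(0, 0.49, 0.5, 1))))
  # raw values here are already 0-1 so normalization keeps them
  act <- compute_activity(gep, 0.5)
  expect_equal(unname(act$ap[1, ]), c(0L, 0L, 1L, 1L))
  expect_error(compute_activity(gep, 1.5), "phi")
  expect_error(compute_activity(gep, -0.1), "phi")
  act0 <- compute_activity(gep, 0)
  expect_true(all(act0$ap == 1L))
})

test_that("temporal series applies the activity product rule", {
  net <- scored_network(c("A", "A"), c("B", "C"), c(999L, 500L))
  ap <- rbind(A = c(1L, 1L), B = c(1L, 0L))  # C has no expression profile
  act <- structure(list(ap = ap, phi = 0.5), class = "activity_matrix")
  ser <- build_temporal_series(net, act)
  expect_equal(ser$da[1, ], c(999L, 0L))  # both active / B inactive
  expect_equal(ser$da[2, ], c(0L, 0L))    # absentee protein: never active
  expect_true(all(ser$da <= net$edges$score))
})

test_that("interval merge equals the brute-force minimum and obeys nesting", {
  set.seed(11)
  for (rep in 1:20) {
    N <- sample(5:20, 1)
    Tn <- sample(2:8, 1)
    nodes <- sprintf("N%02d", seq_len(N))
    pr <- utils::combn(nodes, 2L)
    keep <- runif(ncol(pr)) < 0.3
    if (!any(keep)) keep[1] <- TRUE
    net <- scored_network(pr[1, keep], pr[2, keep],
                          sample(1:999, sum(keep), replace = TRUE))
    ap <- matrix(rbinom(N * Tn, 1, 0.7), N, Tn, dimnames = list(nodes, NULL))
    act <- structure(list(ap = ap, phi = 0.5), class = "activity_matrix")
    ser <- build_temporal_series(net, act)
    tipins <- merge_interval_networks(ser)
    expect_length(tipins, Tn * (Tn + 1) / 2)
    for (inet in tipins) {
      oracle <- brute_interval_scores(ser$da, inet$t_low, inet$t_high)
      got <- integer(length(oracle))
      if (nrow(inet$edges) > 0) {
        key <- paste(ser$edges$protein_a, ser$edges$protein_b)
        got[match(paste(inet$edges$protein_a, inet$edges$protein_b), key)] <-
          inet$edges$b
      }
      expect_identical(got, as.integer(oracle))
    }
    # anti-monotonicity: longer interval edge sets nest inside shorter ones
    key_of <- function(inet) paste(inet$edges$protein_a, inet$edges$protein_b)
    by_int <- lapply(tipins, key_of)
    bounds <- vapply(tipins, function(x) c(x$t_low, x$t_high), c(1L, 1L))
    for (i in seq_along(tipins)) {
      for (j in seq_along(tipins)) {
        if (bounds[1, j] <= bounds[1, i] && bounds[2, i] <= bounds[2, j]) {
          expect_true(all(by_int[[j]] %in% by_int[[i]]))
        }
      }
    }
  }
})

test_that("length-1 intervals equal the temporal networks; phi = 0 keeps the static network", {
  fx <- clique_fixture()
  pipe <- build_tipins(fx$edges[, 1:2], fx$edges, fx$expr, phi = 0)
  static_keys <- paste(pipe$network$edges$protein_a, pipe$network$edges$protein_b)
  for (inet in pipe$tipins) {
    expect_setequal(paste(inet$edges$protein_a, inet$edges$protein_b),
                    static_keys)
    expect_true(all(inet$edges$b <= 999L))
  }
  pipe2 <- build_tipins(fx$edges[, 1:2], fx$edges, fx$expr, phi = 0.5)
  diag1 <- Filter(function(x) x$l == 1L, pipe2$tipins)
  expect_length(diag1, 6L)
  for (t in seq_along(diag1)) {
    expect_equal(sort(diag1[[t]]$edges$b),
                 sort(pipe2$series$da[pipe2$series$da[, t] > 0, t]))
  }
})
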