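make_clique_pipeline <- function(split_localization = FALSE, phi = 0.5) {
  fx <- clique_fixture(split_localization)
  pipe <- build_tipins(fx$edges[, 1:2], fx$edges, fx$expr, phi = phi)
  c(fx, pipe)
}

test_that("a planted clique is recovered as a single cluster", {
  px <- make_clique_pipeline()
  inet <- Filter(function(x) x$t_low == 2 && x$t_high == 5, px$tipins)[[1]]
  cl <- identify_in_network(inet, px$gep, px$loc, px$bundle, px$thresholds)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$members, paste0("P", 1:5))
})

test_that("a member with disjoint localization is never admitted", {
  px <- make_clique_pipeline(split_localization = TRUE)
  inet <- Filter(function(x) x$t_low == 2 && x$t_high == 5, px$tipins)[[1]]
  cl <- identify_in_network(inet, px$gep, px$loc, px$bundle, px$thresholds)
  # P5 would drop JC to 0, so it can neither join P1-P4 nor grow its own
  # cluster (its frontier candidates all share no compartment with it)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$members, paste0("P", 1:4))
})

test_that("no cluster forms without r-reliable links", {
  px <- make_clique_pipeline()
  thr <- px$thresholds
  weak <- icj_thresholds(r = 999L, sigma = thr$sigma, omega = thr$omega,
                         theta = thr$theta, gamma = thr$gamma)
  fx <- clique_fixture()
  fx$edges$score <- 500L
  pipe <- build_tipins(fx$edges[, 1:2], fx$edges, fx$expr, phi = 0.5)
  inet <- Filter(function(x) x$t_low == 2 && x$t_high == 5, pipe$tipins)[[1]]
  expect_length(identify_in_network(inet, pipe$gep, fx$loc, fx$bundle, weak),
                0L)
})

test_that("the sweep deduplicates identical member sets with provenance", {
  px <- make_clique_pipeline()
  catalog <- run_icjointle(px$tipins, px$gep, px$loc, px$bundle,
                           px$thresholds)
  expect_length(catalog$complexes, 1L)
  expect_equal(catalog$complexes[[1]], paste0("P", 1:5))
  # the clique is active at times 2-5, so it is found in every subinterval
  expect_equal(nrow(catalog$provenance[[1]]), 4 * 5 / 2)
  expect_gt(catalog$n_raw, 1L)
  # dedup = "none" keeps the per-interval copies
  raw <- run_icjointle(px$tipins, px$gep, px$loc, px$bundle, px$thresholds,
                       dedup = "none")
  expect_length(raw$complexes, catalog$n_raw)
})

test_that("identification is deterministic and T = 1 reduces to one network", {
  gt <- generate_bundle(synthetic_spec(seed = 9, n_complexes = 4,
                                       n_background = 30))
  r1 <- recover_complexes(gt)
  r2 <- recover_complexes(gt)
  expect_identical(r1$catalog, r2$catalog)

  px <- make_clique_pipeline()
  fx <- clique_fixture()
  one_col <- expression_table(fx$proteins,
                              fx$expr$values[, 3, drop = FALSE])
  # T = 1: a single (degenerate) time point; every gene is degenerate, so
  # use phi = 0 to keep everything active
  pipe1 <- build_tipins(fx$edges[, 1:2], fx$edges, one_col, phi = 0)
  expect_length(pipe1$tipins, 1L)
  cat1 <- run_icjointle(pipe1$tipins, pipe1$gep, fx$loc, fx$bundle,
                        icj_thresholds(r = 900, sigma = 0.1, omega = 0.1,
                                       theta = 0.1, gamma = 0))
  direct <- identify_in_network(pipe1$tipins[[1]], pipe1$gep, fx$loc,
                                fx$bundle,
                                icj_thresholds(r = 900, sigma = 0.1,
                                               omega = 0.1, theta = 0.1,
                                               gamma = 0))
  expect_equal(cat1$complexes, lapply(direct, `[[`, "members"))
})

test_that("every output cluster satisfies the joint conditions post hoc", {
  gt <- generate_bundle(synthetic_spec(seed = 23, n_complexes = 6,
                                       n_background = 40))
  thr <- icj_thresholds()
  res <- recover_complexes(gt, thr)
  gep <- normalize_expression(gt$expression)
  expect_gt(length(res$catalog$complexes), 0L)
  for (i in seq_along(res$catalog$complexes)) {
    cx <- res$catalog$complexes[[i]]
    expect_true(joint_localization(cx, gt$localization)$satisfied)
    for (k in seq_len(nrow(res$catalog$provenance[[i]]))) {
      pv <- res$catalog$provenance[[i]][k, ]
      w <- expression_window(pv$t_low, pv$t_high, gt$spec$n_time)
      expect_true(joint_coexpression(cx, gep, w, thr$gamma)$satisfied)
    }
  }
})

test_that("catalog merging is idempotent and accumulates provenance", {
  px <- make_clique_pipeline()
  catalog <- run_icjointle(px$tipins, px$gep, px$loc, px$bundle,
                           px$thresholds)
  merged <- merge_catalogs(catalog, catalog)
  expect_equal(merged$complexes, catalog$complexes)
  expect_equal(nrow(merged$provenance[[1]]),
               2L * nrow(catalog$provenance[[1]]))
  again <- merge_catalogs(merged)
  expect_equal(again$complexes, merged$complexes)
  expect_equal(again$provenance, merged$provenance)
})
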