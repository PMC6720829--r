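test_that("joint localization is the AND of member vectors", {
  loc <- matrix(0L, 3, 22,
                dimnames = list(c("P1", "P2", "P3"),
                                yeast_localization_categories))
  loc["P1", 1:2] <- 1L
  loc["P2", 1] <- 1L
  loc["P3", 3] <- 1L
  jl <- joint_localization(c("P1", "P2"), loc)
  expect_equal(jl$jlv[1:3], c(1L, 0L, 0L))
  expect_equal(jl$jc, 1L)
  expect_true(jl$satisfied)
  # singleton: identity of AND
  expect_equal(joint_localization("P1", loc)$jlv, unname(loc["P1", ]))
  # disjoint localizations fail
  expect_false(joint_localization(c("P1", "P3"), loc)$satisfied)
  # missing protein: permissive default, strict switch
  expect_equal(joint_localization(c("P1", "ZZ"), loc)$jc, 2L)
  expect_equal(joint_localization(c("P1", "ZZ"), loc, strict = TRUE)$jc, 0L)
  expect_error(joint_localization(character(0), loc), "empty")
})

test_that("coexpression window spans l + 4 points with boundary truncation", {
  expect_equal(expression_window(5, 9, 12), c(3L, 11L))
  expect_equal(expression_window(1, 3, 12), c(1L, 5L))
  expect_equal(expression_window(10, 12, 12), c(8L, 12L))
  expect_equal(expression_window(3, 3, 12), c(1L, 5L))
  expect_error(expression_window(5, 4, 12))
})

test_that("joint coexpression is the windowed mean of the expression product", {
  gep <- gep_of(rbind(A = rep(1, 6), B = rep(0.5, 6), C = rep(0, 6),
                      D = c(1, 1, 0.2, 0.4, 1, 1)))
  expect_equal(joint_coexpression("A", gep, c(1, 6), 0.5)$jq, 1)
  expect_true(joint_coexpression("A", gep, c(1, 6), 1)$satisfied)
  # zero product kills the condition for any positive threshold
  jc0 <- joint_coexpression(c("A", "C"), gep, c(1, 6), 0.01)
  expect_equal(jc0$jq, 0)
  expect_false(jc0$satisfied)
  # k genes at 0.5 give 0.5^k
  expect_equal(joint_coexpression(c("B", "B"), gep, c(1, 6), 0)$jq, 0.25)
  expect_equal(joint_coexpression(c("A", "B"), gep, c(2, 4), 0)$jq, 0.5)
  # literal-formula denominator divides by T instead of the window length
  expect_equal(joint_coexpression("D", gep, c(3, 4), 0,
                                  denominator = "T")$jq, 0.6 / 6)
  expect_equal(joint_coexpression("D", gep, c(3, 4), 0)$jq, 0.3)
  # absent gene fails the condition
  expect_false(joint_coexpression(c("A", "ZZ"), gep, c(1, 6), 0)$satisfied)
  expect_error(joint_coexpression(character(0), gep), "empty")
})

test_that("JC and JQ are anti-monotone under set growth", {
  set.seed(31)
  loc <- matrix(rbinom(20 * 22, 1, 0.4), 20, 22,
                dimnames = list(sprintf("P%02d", 1:20),
                                yeast_localization_categories))
  gep <- gep_of(matrix(runif(20 * 8), 20, 8,
                       dimnames = list(sprintf("P%02d", 1:20), NULL)))
  for (rep in 1:50) {
    ps <- sample(rownames(loc), sample(1:6, 1))
    extra <- sample(setdiff(rownames(loc), ps), 1)
    expect_lte(joint_localization(c(ps, extra), loc)$jc,
               joint_localization(ps, loc)$jc)
    expect_lte(joint_coexpression(c(ps, extra), gep, c(2, 7), 0)$jq,
               joint_coexpression(ps, gep, c(2, 7), 0)$jq)
  }
})

test_that("term information gives the stated depths and information content", {
  ti <- toy_term_info()
  expect_equal(unname(ti$depth[c("GO:R", "GO:X", "GO:Y")]), c(0L, 1L, 2L))
  expect_equal(unname(ti$count[c("GO:R", "GO:X", "GO:Y")]), c(10L, 5L, 2L))
  expect_equal(unname(ti$ic[["GO:R"]]), 0)        # annotates everything
  expect_equal(ti$ic[["GO:Y"]], -log(0.2), tolerance = 1e-12)
  expect_equal(ti$ic[["GO:Y"]], 1.6094379, tolerance = 1e-6)
  expect_error(term_information(list(terms = character(0))), "empty")
})

test_that("term similarity follows the mica-based exponential form", {
  ti <- toy_term_info()
  # self-similarity of the deep term: l = 0, h = 2, d = -ln(0.2)
  expect_equal(term_similarity("GO:Y", "GO:Y", ti),
               tanh(0.3 * 2) * tanh(30 * -log(0.2)), tolerance = 1e-12)
  expect_equal(term_similarity("GO:Y", "GO:Y", ti), 0.5370496,
               tolerance = 1e-6)
  # mica of X and Y is X: l = 1, h = 1, d = -ln(0.5)
  expect_equal(term_similarity("GO:X", "GO:Y", ti),
               exp(-0.2) * tanh(0.3) * tanh(30 * log(2)), tolerance = 1e-12)
  # root mica: depth 0 wipes the similarity
  expect_equal(term_similarity("GO:R", "GO:X", ti), 0)
  # symmetry
  expect_equal(term_similarity("GO:X", "GO:Y", ti),
               term_similarity("GO:Y", "GO:X", ti))
  # unknown term
  expect_equal(term_similarity("GO:Z", "GO:Y", ti), 0)
})

test_that("the two quotient factors are hyperbolic tangents", {
  set.seed(5)
  for (i in 1:100) {
    h <- sample(0:12, 1); d <- runif(1, 0, 5)
    explicit_h <- (exp(0.3 * h) - exp(-0.3 * h)) / (exp(0.3 * h) + exp(-0.3 * h))
    explicit_d <- (exp(30 * d) - exp(-30 * d)) / (exp(30 * d) + exp(-30 * d))
    expect_equal(explicit_h, tanh(0.3 * h), tolerance = 1e-12)
    expect_equal(explicit_d, tanh(30 * d), tolerance = 1e-12)
  }
})

test_that("term-set and protein similarities average best matches", {
  ti <- toy_term_info()
  syy <- term_similarity("GO:Y", "GO:Y", ti)
  sxy <- term_similarity("GO:X", "GO:Y", ti)
  expect_equal(termset_similarity("GO:Y", c("GO:X", "GO:Y"), ti), syy)
  expect_equal(termset_similarity("GO:Y", "GO:X", ti), sxy)
  expect_equal(termset_similarity("GO:Y", character(0), ti), 0)
  # P01 and P02 share the identical term set {Y}
  expect_equal(protein_similarity("P01", "P02", ti), syy)
  # m = n = 1 with distinct terms: average of two equal best matches
  expect_equal(protein_similarity("P01", "P03", ti), sxy)
  expect_equal(protein_similarity("P01", "P03", ti),
               protein_similarity("P03", "P01", ti))
  # no annotation in this ontology
  expect_equal(protein_similarity("P01", "QQ", ti), 0)
})

test_that("cluster minimal similarity honors the r-reliable gate", {
  bundle <- structure(list(CC = toy_term_info()), class = "annotation_bundle")
  net <- data.frame(protein_a = c("P01", "P01"),
                    protein_b = c("P02", "P03"),
                    score = c(999L, 100L))
  syy <- term_similarity("GO:Y", "GO:Y", bundle$CC)
  sxy <- term_similarity("GO:X", "GO:Y", bundle$CC)
  pc <- c("P02", "P03")
  # both links reliable: min of the two protein similarities
  expect_equal(cluster_min_similarity(pc, "P01", "CC", bundle, net, 50),
               min(syy, sxy))
  # only P02 reliable: P03 is excluded from the min
  expect_equal(cluster_min_similarity(pc, "P01", "CC", bundle, net, 900),
               syy)
  # no reliable link: defined as 0 (condition fails)
  net2 <- transform(net, score = c(10L, 20L))
  expect_equal(cluster_min_similarity(pc, "P01", "CC", bundle, net2, 900), 0)
})

test_that("the expanding condition is the 2-of-3 majority", {
  fx <- clique_fixture()
  smap <- fx$edges
  pc <- c("P1", "P2")
  s <- protein_similarity("P3", "P1", fx$bundle$CC)
  expect_gt(s, 0.7)  # fixture geometry: tanh(0.9) * tanh(30 * ln(6/5))
  mk <- function(sigma, omega, theta) {
    expanding_condition(pc, "P3", fx$bundle, smap,
                        icj_thresholds(r = 900, sigma = sigma, omega = omega,
                                       theta = theta, gamma = 0))
  }
  expect_true(mk(0.5, 0.5, 0.5)$ec)                 # three flags
  expect_true(mk(0.5, 0.5, 0.99)$ec)                # exactly two flags
  r1 <- mk(0.99, 0.99, 0.5)                         # exactly one flag
  expect_false(r1$ec)
  expect_true(r1$bbp); expect_false(r1$bcc); expect_false(r1$bmf)
  expect_false(mk(0.99, 0.99, 0.99)$ec)             # no flags
})

test_that("cluster minimal similarity never increases as the cluster grows", {
  ti <- toy_term_info()
  bundle <- structure(list(CC = ti), class = "annotation_bundle")
  set.seed(17)
  prot <- sprintf("P%02d", 1:10)
  for (rep in 1:20) {
    u <- sample(prot, 1)
    rest <- setdiff(prot, u)
    pc <- sample(rest, 3)
    extra <- sample(setdiff(rest, pc), 1)
    # all pairs r-reliable
    pr <- utils::combn(prot, 2L)
    net <- data.frame(protein_a = pr[1, ], protein_b = pr[2, ], score = 999L)
    expect_lte(
      cluster_min_similarity(c(pc, extra), u, "CC", bundle, net, 900),
      cluster_min_similarity(pc, u, "CC", bundle, net, 900))
  }
})
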