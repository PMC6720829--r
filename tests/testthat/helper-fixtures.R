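# fixtures and independent oracles shared across the suite

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# toy ontology: root -> X -> Y (single chain), one aspect
toy_dag_aspect <- function() {
  list(terms = c("GO:R", "GO:X", "GO:Y"),
       parents = list("GO:R" = character(0), "GO:X" = "GO:R",
                      "GO:Y" = "GO:X"),
       roots = "GO:R")
}

# corpus of 10 proteins: 2 annotated to Y, 3 more to X, 5 at the root
toy_term_info <- function() {
  prot <- sprintf("P%02d", 1:10)
  ann <- c(rep("GO:Y", 2), rep("GO:X", 3), rep("GO:R", 5))
  term_information(toy_dag_aspect(),
                   stats::setNames(as.list(ann), prot))
}

# five-protein clique fixture: 999-scored clique, shared compartment and a
# shared depth-3 GO term in all three ontologies, expression peaking at
# times 2-5 of 6. A sixth protein (PX, annotated at the root, absent from
# the network) keeps the shared term informative (IC > 0).
clique_fixture <- function(split_localization = FALSE) {
  prot <- paste0("P", 1:5)
  pairs <- utils::combn(prot, 2L)
  edges <- data.frame(protein_a = pairs[1, ], protein_b = pairs[2, ],
                      score = 999L, stringsAsFactors = FALSE)
  vals <- matrix(2, 5, 6, dimnames = list(prot, NULL))
  vals[, 2:5] <- 10
  expr <- expression_table(prot, vals)
  loc <- matrix(0L, 5, 22,
                dimnames = list(prot, yeast_localization_categories))
  loc[, 1] <- 1L
  if (split_localization) {
    loc["P5", ] <- 0L
    loc["P5", 2] <- 1L
  }
  mk_aspect <- function(aspect) {
    terms <- paste0(aspect, c(":R", ":A", ":B", ":C"))
    parents <- stats::setNames(
      list(character(0), terms[1], terms[2], terms[3]), terms)
    list(terms = terms, parents = parents, roots = terms[1])
  }
  dag <- structure(list(BP = mk_aspect("BP"), MF = mk_aspect("MF"),
                        CC = mk_aspect("CC")), class = "go_dag")
  annotations <- lapply(c(BP = "BP", MF = "MF", CC = "CC"), function(a) {
    c(stats::setNames(as.list(rep(paste0(a, ":C"), length(prot))), prot),
      list(PX = paste0(a, ":R")))
  })
  list(proteins = prot, edges = edges, expr = expr, loc = loc, dag = dag,
       annotations = annotations,
       bundle = annotation_bundle(dag, annotations),
       thresholds = icj_thresholds(r = 900L, sigma = 0.1, omega = 0.1,
                                   theta = 0.1, gamma = 0.001))
}

# brute-force interval minimum: the independent oracle for the TI-PIN
# recurrence
brute_interval_scores <- function(da, t_low, t_high) {
  apply(da[, t_low:t_high, drop = FALSE], 1L, min)
}

# independent brute-force matching metrics, straight from the definitions
brute_match_report <- function(ic, kc, lambda = 0.2) {
  m <- length(ic); n <- length(kc)
  os <- function(a, b) length(intersect(a, b))^2 / (length(a) * length(b))
  mic <- 0L
  n_exact <- 0L
  for (j in seq_len(m)) {
    best <- 0
    for (i in seq_len(n)) best <- max(best, os(ic[[j]], kc[[i]]))
    if (best >= lambda) mic <- mic + 1L
    if (best == 1) n_exact <- n_exact + 1L
  }
  mkc <- 0L
  mmr_sum <- 0
  for (i in seq_len(n)) {
    best <- 0
    for (j in seq_len(m)) best <- max(best, os(ic[[j]], kc[[i]]))
    if (best >= lambda) mkc <- mkc + 1L
    mmr_sum <- mmr_sum + best
  }
  sn_num <- 0; sn_den <- 0; ppv_num <- 0; ppv_den <- 0
  for (i in seq_len(n)) {
    best <- 0
    for (j in seq_len(m)) {
      tij <- length(intersect(kc[[i]], ic[[j]]))
      best <- max(best, tij)
      ppv_den <- ppv_den + tij
    }
    sn_num <- sn_num + best
    sn_den <- sn_den + length(kc[[i]])
  }
  for (j in seq_len(m)) {
    best <- 0
    for (i in seq_len(n)) best <- max(best, length(intersect(kc[[i]], ic[[j]])))
    ppv_num <- ppv_num + best
  }
  prec <- mic / m; rec <- mkc / n
  sn <- sn_num / sn_den
  ppv <- if (ppv_den > 0) ppv_num / ppv_den else 0
  acc <- sqrt(sn * ppv)
  mmr <- mmr_sum / n
  list(Mic = mic, Mkc = mkc, prec = prec, rec = rec,
       fm = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0,
       Sn = sn, PPV = ppv, Acc = acc, MMR = mmr,
       FAM = rec + acc + mmr, n_exact = n_exact)
}

# exhaustive hypergeometric upper tail by subset enumeration
enum_enrichment_tail <- function(N, K, n_s, k_s) {
  if (k_s == 0L) return(1)
  subs <- utils::combn(N, n_s)
  marked <- colSums(subs <= K)
  mean(marked >= k_s)
}

# random catalogs over a small protein universe
random_catalog <- function(n_complexes, universe, min_size = 2L,
                           max_size = 6L) {
  lapply(seq_len(n_complexes), function(i) {
    sample(universe, sample(min_size:max_size, 1L))
  })
}

# hand-built normalized expression object
gep_of <- function(mat) {
  structure(list(genes = rownames(mat), gep = mat),
            class = "normalized_expression")
}
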