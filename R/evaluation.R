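#' Overlap score between two protein sets
#'
#' `|intersection|^2 / (|ic| * |kc|)`; 1 iff the sets are identical, 0 iff
#' disjoint.
#'
#' @param ic,kc Non-empty character vectors (protein sets).
#' @return Overlap score in \[0, 1\].
#' @export
overlap_score <- function(ic, kc) {
  ic <- unique(ic); kc <- unique(kc)
  if (length(ic) == 0L || length(kc) == 0L) stop("empty protein set")
  length(intersect(ic, kc))^2 / (length(ic) * length(kc))
}

#' Statistical matching metrics of predicted vs known complexes
#'
#' Computes the full matching suite of a predicted catalog `IC` against a
#' reference catalog `KC` at overlap threshold `lambda`:
#' \describe{
#'   \item{Mic, Mkc}{number of predicted (known) complexes with overlap
#'     score `>= lambda` against some known (predicted) complex}
#'   \item{prec, rec, fm}{`Mic/|IC|`, `Mkc/|KC|`, their harmonic mean}
#'   \item{Frac}{fraction of known complexes matched (equals `rec`)}
#'   \item{MMR}{mean over known complexes of the best overlap score against
#'     any predicted complex (the printed formula). With
#'     `mmr = "matching"` a true maximum-weight one-to-one matching
#'     between known and predicted complexes is used instead; both values
#'     are always returned as `mmr_printed` and `mmr_matching`.}
#'   \item{Sn, PPV, Acc}{cluster-wise sensitivity, positive predictive
#'     value and their geometric mean, from the common-protein counts
#'     `t_ij`}
#'   \item{FAM}{`Frac + Acc + MMR`}
#'   \item{n_exact}{number of predicted complexes with overlap score
#'     exactly 1 against some known complex (`#PM`)}
#' }
#'
#' @param ic,kc Lists of protein-ID vectors (predicted and known catalogs).
#' @param lambda Overlap threshold in (0, 1\]; default 0.2.
#' @param mmr Which variant feeds `MMR` (and hence `FAM`): the printed
#'   per-known best-overlap mean (`"printed"`, default) or the one-to-one
#'   maximum-weight matching (`"matching"`).
#' @return A list of class `match_report` with the fields above plus
#'   `lambda`, `n_ic`, `n_kc` and `pm_fam` (`n_exact * FAM`).
#' @export
match_report <- function(ic, kc, lambda = 0.2, mmr = c("printed", "matching")) {
  mmr <- match.arg(mmr)
  if (length(ic) == 0L || length(kc) == 0L) stop("empty catalog")
  if (!is.numeric(lambda) || lambda <= 0 || lambda > 1) {
    stop("lambda must be in (0, 1]")
  }
  ic <- lapply(ic, unique)
  kc <- lapply(kc, unique)
  m <- length(ic); n <- length(kc)
  os <- matrix(0, n, m)        # known x predicted overlap scores
  tij <- matrix(0L, n, m)      # common-protein counts
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      t0 <- length(intersect(kc[[i]], ic[[j]]))
      tij[i, j] <- t0
      os[i, j] <- t0^2 / (length(kc[[i]]) * length(ic[[j]]))
    }
  }
  Mic <- sum(apply(os, 2L, max) >= lambda)
  Mkc <- sum(apply(os, 1L, max) >= lambda)
  prec <- Mic / m
  rec <- Mkc / n
  fm <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  mmr_printed <- mean(apply(os, 1L, max))
  mmr_matching <- mmr_one_to_one(os)
  MMR <- if (mmr == "printed") mmr_printed else mmr_matching
  ni <- lengths(kc)
  Sn <- sum(apply(tij, 1L, max)) / sum(ni)
  tot <- sum(tij)
  PPV <- if (tot > 0) sum(apply(tij, 2L, max)) / tot else 0
  Acc <- sqrt(Sn * PPV)
  n_exact <- sum(apply(os, 2L, max) == 1)
  FAM <- fam_score(rec, Acc, MMR)
  structure(list(lambda = lambda, n_ic = m, n_kc = n, Mic = Mic, Mkc = Mkc,
                 prec = prec, rec = rec, fm = fm, Frac = rec,
                 MMR = MMR, mmr_printed = mmr_printed,
                 mmr_matching = mmr_matching, Sn = Sn, PPV = PPV, Acc = Acc,
                 FAM = FAM, n_exact = n_exact, pm_fam = n_exact * FAM,
                 os = os, tij = tij),
            class = "match_report")
}

## maximum-weight one-to-one matching between known (rows) and predicted
## (columns) complexes; total matched overlap divided by the number of
## known complexes
mmr_one_to_one <- function(os) {
  n <- nrow(os); m <- ncol(os)
  idx <- which(os > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, n), rep(TRUE, m)),
    edges = as.vector(t(cbind(idx[, 1], n + idx[, 2])))
  )
  mt <- igraph::max_bipartite_match(g, weights = os[idx])
  sum(mt$matching_weight) / n
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "match_report (lambda=%.2g): #PM=%d fm=%.3f Frac=%.3f Acc=%.3f MMR=%.3f FAM=%.3f #PMxFAM=%.2f\n",
    x$lambda, x$n_exact, x$fm, x$Frac, x$Acc, x$MMR, x$FAM, x$pm_fam))
  invisible(x)
}

#' Comprehensive matching score
#'
#' @param frac Fraction of known complexes matched.
#' @param acc Geometric accuracy (sqrt of Sn x PPV).
#' @param mmr Maximum matching ratio.
#' @return `frac + acc + mmr`, in \[0, 3\].
#' @export
fam_score <- function(frac, acc, mmr) {
  frac + acc + mmr
}

#' Geometric mean of relative performance of two predictions
#'
#' `sqrt((pm1 * fam1) / (pm2 * fam2))`: greater than 1 iff the first
#' prediction dominates on the exact-match x comprehensive-score product.
#'
#' @param pm1,fam1 Exact-match count and comprehensive score of the first
#'   prediction.
#' @param pm2,fam2 Same for the second; their product must be positive.
#' @return The relative geometric mean.
#' @export
relative_geometric_mean <- function(pm1, fam1, pm2, fam2) {
  if (pm2 * fam2 <= 0) stop("reference performance product must be positive")
  sqrt((pm1 * fam1) / (pm2 * fam2))
}

#' Hypergeometric enrichment tail probability
#'
#' Probability of observing at least `k_s` annotated proteins in a complex
#' of `n_s` proteins drawn from a network of `N` proteins of which `K` are
#' annotated with the tested term. Computed with the stable hypergeometric
#' survival function.
#'
#' @param N Network size (background).
#' @param K Number of term-annotated proteins in the network.
#' @param n_s Complex size.
#' @param k_s Number of term-annotated proteins in the complex.
#' @return Upper tail probability `P(X >= k_s)` in \[0, 1\].
#' @export
enrichment_pvalue <- function(N, K, n_s, k_s) {
  stopifnot(N >= 0, K >= 0, K <= N, n_s >= 0, n_s <= N,
            k_s >= 0, k_s <= min(K, n_s))
  if (k_s == 0L) return(1)
  stats::phyper(k_s - 1, K, N - K, n_s, lower.tail = FALSE)
}

#' Over-expression (enrichment) score of a predicted catalog
#'
#' For each complex, tests every term annotating at least one member (in
#' the chosen ontology) with [enrichment_pvalue()] against the background
#' of the `background` proteins; the complex's p-value is the minimum over
#' tested terms (no multiple-testing correction). A complex is significant
#' if its p-value is strictly below `psi`; the over-expression score is the
#' fraction of significant complexes.
#'
#' @param catalog List of protein-ID vectors (or a `complex_list`).
#' @param prot_terms Named list mapping protein ID to annotated terms (one
#'   ontology, e.g. `bundle$BP$prot_terms`).
#' @param background Character vector of the network's proteins (defines
#'   `N`).
#' @param psi Significance level (default 0.01).
#' @return A list with `score`, `n_significant`, `n_total` and `p_values`
#'   (per complex).
#' @export
overexpression_score <- function(catalog, prot_terms, background,
                                 psi = 0.01) {
  if (length(catalog) == 0L) stop("empty catalog")
  background <- unique(background)
  N <- length(background)
  prot_terms <- prot_terms[intersect(names(prot_terms), background)]
  ## term -> count of annotated proteins in the background
  term_tab <- table(unlist(prot_terms))
  p_values <- vapply(catalog, function(cx) {
    cx <- intersect(unique(cx), background)
    n_s <- length(cx)
    terms <- unique(unlist(prot_terms[intersect(cx, names(prot_terms))]))
    if (n_s == 0L || length(terms) == 0L) return(1)
    min(vapply(terms, function(tm) {
      K <- as.integer(term_tab[[tm]])
      k_s <- sum(vapply(cx, function(p) tm %in% prot_terms[[p]], TRUE))
      enrichment_pvalue(N, K, n_s, k_s)
    }, 0))
  }, 0)
  n_sig <- sum(p_values < psi)
  list(score = n_sig / length(catalog), n_significant = n_sig,
       n_total = length(catalog), p_values = p_values)
}
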