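#' Threshold set for the identification algorithm
#'
#' Bundles the five admission thresholds. Defaults are the published values
#' for the STRING network scored on the 1-999 scale: reliability `r = 999`,
#' cellular-component similarity `sigma = 0.7`, molecular-function
#' similarity `omega = 0.6`, biological-process similarity `theta = 0.1`.
#' The joint-coexpression threshold `gamma` has no published value and
#' defaults to 0.01; treat it as a required tuning parameter (see the
#' methods vignette).
#'
#' @param r Reliability threshold, integer in \[1, 999\].
#' @param sigma,omega,theta Per-ontology (CC/MF/BP) minimal-similarity
#'   thresholds in \[0, 1\].
#' @param gamma Joint-coexpression threshold in \[0, 1\].
#' @return A named list of class `icj_thresholds`.
#' @export
icj_thresholds <- function(r = 999L, sigma = 0.7, omega = 0.6, theta = 0.1,
                           gamma = 0.01) {
  stopifnot(r >= 1, r <= 999, r == floor(r),
            sigma >= 0, sigma <= 1, omega >= 0, omega <= 1,
            theta >= 0, theta <= 1, gamma >= 0, gamma <= 1)
  structure(list(r = as.integer(r), sigma = sigma, omega = omega,
                 theta = theta, gamma = gamma), class = "icj_thresholds")
}

#' Joint colocalization of a protein set
#'
#' The joint localization vector is the element-wise logical AND of the
#' members' 22-category localization vectors; the joint colocalization
#' count `JC` is its sum. The joint colocalization condition holds iff
#' `JC > 0`, i.e. at least one compartment hosts every member.
#'
#' Proteins absent from the localization table are treated as localized
#' everywhere (all-ones vector) by default, so that missing GFP data does
#' not veto a cluster; set `strict = TRUE` to treat absentees as localized
#' nowhere instead.
#'
#' @param ps Character vector of protein IDs (non-empty).
#' @param loc 0/1 localization matrix from [read_localization()].
#' @param strict Treat proteins missing from `loc` as all-zeros?
#' @return List with `jlv` (0/1 integer vector), `jc` (integer) and
#'   `satisfied` (`jc > 0`).
#' @export
joint_localization <- function(ps, loc, strict = FALSE) {
  if (length(ps) == 0L) stop("empty protein set")
  jlv <- rep(1L, ncol(loc))
  for (p in ps) {
    i <- match(p, rownames(loc))
    v <- if (is.na(i)) {
      if (strict) rep(0L, ncol(loc)) else rep(1L, ncol(loc))
    } else loc[i, ]
    jlv <- jlv * v
    if (!any(jlv > 0L)) break
  }
  jc <- sum(jlv)
  list(jlv = as.integer(jlv), jc = as.integer(jc), satisfied = jc > 0L)
}

#' Coexpression analysis window for a temporal interval
#'
#' For an interval of length `l = t_high - t_low + 1` the joint
#' coexpression condition is evaluated over `l + 4` successive time points:
#' two before `t_low` and two after `t_high`. Near the boundaries the
#' window is truncated: if `t_low < 3` it starts at 1, and if
#' `t_high > T - 2` it ends at `T`.
#'
#' @param t_low,t_high Closed 1-based interval bounds.
#' @param n_time Total number of time points `T`.
#' @return Integer vector `c(lo, hi)` of the inclusive window.
#' @export
expression_window <- function(t_low, t_high, n_time) {
  stopifnot(t_low >= 1L, t_low <= t_high, t_high <= n_time)
  lo <- if (t_low < 3L) 1L else t_low - 2L
  hi <- if (t_high > n_time - 2L) n_time else t_high + 2L
  c(as.integer(lo), as.integer(hi))
}

#' Joint coexpression of a gene set
#'
#' The joint expression profile is the per-time-point product of the
#' members' normalized expression values; the joint coexpression quantity
#' `JQ` is its average. The condition holds iff `JQ >= gamma`. Genes
#' without an expression profile make the condition fail.
#'
#' @param gs Character vector of gene IDs (non-empty).
#' @param gep A `normalized_expression`.
#' @param window Inclusive time window `c(lo, hi)` (defaults to all time
#'   points).
#' @param gamma Coexpression threshold.
#' @param denominator `"window"` (default) averages the joint profile over
#'   the window length; `"T"` reproduces the literal formula dividing the
#'   windowed sum by the total number of time points.
#' @return List with `jge` (profile over the window), `jq` and `satisfied`.
#' @export
joint_coexpression <- function(gs, gep, window = NULL, gamma = 0.01,
                               denominator = c("window", "T")) {
  if (length(gs) == 0L) stop("empty gene set")
  denominator <- match.arg(denominator)
  Tn <- ncol(gep$gep)
  if (is.null(window)) window <- c(1L, Tn)
  idx <- match(gs, gep$genes)
  if (anyNA(idx)) {
    return(list(jge = NULL, jq = 0, satisfied = FALSE))
  }
  cols <- window[1]:window[2]
  sub <- gep$gep[idx, cols, drop = FALSE]
  jge <- apply(sub, 2L, prod)
  denom <- if (denominator == "window") length(cols) else Tn
  jq <- sum(jge) / denom
  list(jge = jge, jq = jq, satisfied = jq >= gamma)
}

#' Per-term information content and depth for one ontology
#'
#' Computes, for every term of one ontology's DAG: the depth `h` (length in
#' edges of the longest path from a root), the information content
#' `d = -ln(n_t / n_corpus)` where `n_t` counts the proteins annotated to
#' the term or any of its descendants and `n_corpus` is the number of
#' proteins with at least one annotation in this ontology, and the
#' shortest-path distance from the term to each of its ancestors (used to
#' locate the maximum-informative common ancestor).
#'
#' @param dag_aspect One aspect of a `go_dag` (list with `terms`,
#'   `parents`, `roots`).
#' @param prot_terms Named list mapping protein ID to its directly
#'   annotated terms in this ontology.
#' @return An object of class `term_info` with fields `terms`, `parents`,
#'   `depth`, `count`, `n_corpus`, `ic` (`NA` for zero-count terms),
#'   `anc` (named list of named shortest up-distance vectors, self
#'   included at distance 0) and `prot_terms`.
#' @export
term_information <- function(dag_aspect, prot_terms = list()) {
  terms <- dag_aspect$terms
  if (length(terms) == 0L) stop("empty ontology")
  parents <- dag_aspect$parents
  children <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
  ## topological order, roots first (parents precede children)
  indeg <- lengths(parents)
  queue <- terms[indeg == 0L]
  topo <- character(0)
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    topo <- c(topo, t)
    for (ch in children[[t]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  stopifnot(length(topo) == length(terms))  # acyclicity checked at read time
  depth <- stats::setNames(integer(length(terms)), terms)
  anc <- stats::setNames(vector("list", length(terms)), terms)
  for (t in topo) {
    if (length(parents[[t]]) == 0L) {
      depth[[t]] <- 0L
      anc[[t]] <- stats::setNames(0, t)
    } else {
      depth[[t]] <- max(depth[parents[[t]]]) + 1L
      dists <- stats::setNames(0, t)
      for (p in parents[[t]]) {
        pa <- anc[[p]] + 1
        for (nm in names(pa)) {
          if (is.na(dists[nm]) || !(nm %in% names(dists)) ||
              pa[[nm]] < dists[[nm]]) {
            dists[nm] <- pa[[nm]]
          }
        }
      }
      anc[[t]] <- dists
    }
  }
  ## annotated-protein sets propagated child -> parent (reverse topo)
  prot_terms <- prot_terms[lengths(prot_terms) > 0L]
  corpus <- names(prot_terms)
  n_corpus <- length(corpus)
  direct <- stats::setNames(vector("list", length(terms)), terms)
  for (p in names(prot_terms)) {
    pi <- match(p, corpus)
    for (t in intersect(prot_terms[[p]], terms)) {
      direct[[t]] <- c(direct[[t]], pi)
    }
  }
  protset <- direct
  for (t in rev(topo)) {
    acc <- protset[[t]]
    for (ch in children[[t]]) acc <- c(acc, protset[[ch]])
    protset[t] <- list(unique(acc))  # keep zero-count terms in the list
  }
  count <- stats::setNames(vapply(protset, length, 1L), terms)
  ic <- ifelse(count > 0L & n_corpus > 0L, -log(count / n_corpus), NA_real_)
  names(ic) <- terms
  structure(list(terms = terms, parents = parents, depth = depth,
                 count = count, n_corpus = n_corpus, ic = ic, anc = anc,
                 prot_terms = prot_terms),
            class = "term_info")
}

#' Assemble per-ontology term information
#'
#' @param dag A `go_dag` from [read_ontology()].
#' @param annotations Per-aspect annotation lists from
#'   [read_annotations()].
#' @return Named list of `term_info` objects (one per aspect in `dag`), of
#'   class `annotation_bundle`.
#' @export
annotation_bundle <- function(dag, annotations) {
  out <- lapply(names(dag), function(aspect) {
    term_information(dag[[aspect]],
                     if (aspect %in% names(annotations)) annotations[[aspect]]
                     else list())
  })
  names(out) <- names(dag)
  structure(out, class = "annotation_bundle")
}

#' Semantic similarity between two GO terms
#'
#' Similarity is driven by the maximum-informative common ancestor (mica)
#' of the two terms:
#' `sim = exp(-c1 * l) * tanh(c2 * h) * tanh(c3 * d)` where `l` is the sum
#' of the shortest-path lengths from the mica to each term, and `h` and `d`
#' are the mica's depth and information content. If the mica is a root
#' (`h = 0`) or annotates the whole corpus (`d = 0`) the similarity is 0;
#' likewise if either term has no annotated protein below it, or the terms
#' share no ancestor. Ties on mica IC are broken by the smaller `l`, then
#' lexicographically.
#'
#' @param go1,go2 Term IDs in the same ontology.
#' @param ti A `term_info`.
#' @param c1,c2,c3 Similarity constants (defaults 0.2, 0.3, 30).
#' @return Similarity in \[0, 1).
#' @export
term_similarity <- function(go1, go2, ti, c1 = 0.2, c2 = 0.3, c3 = 30) {
  a1 <- ti$anc[[go1]]
  a2 <- ti$anc[[go2]]
  if (is.null(a1) || is.null(a2)) return(0)
  if (is.na(ti$ic[[go1]]) || is.na(ti$ic[[go2]])) return(0)
  common <- intersect(names(a1), names(a2))
  if (length(common) == 0L) return(0)
  ics <- ti$ic[common]
  ics[is.na(ics)] <- -Inf
  best_ic <- max(ics)
  cand <- common[ics == best_ic]
  lsum <- a1[cand] + a2[cand]
  cand <- cand[lsum == min(lsum)]
  mica <- sort(cand)[1]
  l <- a1[[mica]] + a2[[mica]]
  h <- ti$depth[[mica]]
  d <- ti$ic[[mica]]
  if (!is.finite(d)) return(0)
  exp(-c1 * l) * tanh(c2 * h) * tanh(c3 * d)
}

#' Similarity between a term and a term set
#'
#' Maximum of [term_similarity()] over the members of `st`; 0 for an empty
#' set.
#'
#' @param go Term ID.
#' @param st Character vector of term IDs.
#' @param ti A `term_info`.
#' @param ... Passed to [term_similarity()].
#' @return Similarity in \[0, 1).
#' @export
termset_similarity <- function(go, st, ti, ...) {
  if (length(st) == 0L) return(0)
  max(vapply(st, function(g) term_similarity(go, g, ti, ...), 0))
}

#' Functional similarity between two proteins in one ontology
#'
#' Averages the best-match term similarities in both directions:
#' `(sum_i Sim(go_1i, ST2) + sum_j Sim(go_2j, ST1)) / (m + n)` where `ST1`
#' (size m) and `ST2` (size n) are the proteins' directly annotated term
#' sets. A protein with no annotation in the ontology yields similarity 0.
#'
#' @param p1,p2 Protein IDs.
#' @param ti A `term_info`.
#' @param ... Passed to [term_similarity()].
#' @return Similarity in \[0, 1\]; symmetric in its arguments.
#' @export
protein_similarity <- function(p1, p2, ti, ...) {
  st1 <- ti$prot_terms[[p1]]
  st2 <- ti$prot_terms[[p2]]
  if (length(st1) == 0L || length(st2) == 0L) return(0)
  s12 <- vapply(st1, function(g) termset_similarity(g, st2, ti, ...), 0)
  s21 <- vapply(st2, function(g) termset_similarity(g, st1, ti, ...), 0)
  (sum(s12) + sum(s21)) / (length(st1) + length(st2))
}

## cached protein similarity; cache is an environment keyed aspect|p1|p2
cached_protein_similarity <- function(p1, p2, aspect, bundle, cache = NULL) {
  ti <- bundle[[aspect]]
  if (is.null(ti)) return(0)
  if (is.null(cache)) return(protein_similarity(p1, p2, ti))
  key <- if (p1 <= p2) paste(aspect, p1, p2, sep = "|")
         else paste(aspect, p2, p1, sep = "|")
  val <- cache[[key]]
  if (is.null(val)) {
    val <- protein_similarity(p1, p2, ti)
    cache[[key]] <- val
  }
  val
}

## named score lookup keyed "a\tb" (canonical) from any network-like object
edge_score_map <- function(net) {
  edges <- if (inherits(net, "scored_network")) {
    data.frame(a = net$edges$protein_a, b = net$edges$protein_b,
               s = net$edges$score)
  } else if (inherits(net, "interval_network")) {
    data.frame(a = net$edges$protein_a, b = net$edges$protein_b,
               s = net$edges$b)
  } else if (is.data.frame(net)) {
    sc <- if ("score" %in% names(net)) net$score else net$b
    data.frame(a = net$protein_a, b = net$protein_b, s = sc)
  } else {
    stop("cannot interpret network object of class ", class(net)[1])
  }
  cp <- canonical_pairs(as.character(edges$a), as.character(edges$b))
  stats::setNames(as.numeric(edges$s), paste(cp$a, cp$b, sep = "\t"))
}

edge_score <- function(smap, u, v) {
  key <- if (u <= v) paste(u, v, sep = "\t") else paste(v, u, sep = "\t")
  s <- smap[[key]]
  if (is.null(s) || is.na(s)) 0 else s
}

#' Minimal similarity between a cluster and a candidate protein
#'
#' Minimum of the pairwise protein similarities between `u` and the cluster
#' members linked to `u` by an r-reliable edge (score at least `r`). If no
#' member has an r-reliable link to `u` the value is 0, so the
#' corresponding condition fails.
#'
#' @param pc Character vector of cluster member IDs.
#' @param u Candidate protein ID (not in `pc`).
#' @param aspect `"CC"`, `"MF"` or `"BP"`.
#' @param bundle An `annotation_bundle`.
#' @param net Network whose edge scores gate the comparison (a
#'   `scored_network`, `interval_network`, edge data frame, or a named
#'   score vector from the internal score-map helper).
#' @param r Reliability threshold.
#' @param cache Optional environment memoizing protein similarities.
#' @return Minimal similarity in \[0, 1\].
#' @export
cluster_min_similarity <- function(pc, u, aspect, bundle, net, r,
                                   cache = NULL) {
  stopifnot(length(pc) >= 1L, !(u %in% pc))
  smap <- if (is.numeric(net) && !is.null(names(net))) net
          else edge_score_map(net)
  linked <- pc[vapply(pc, function(v) edge_score(smap, u, v) >= r, TRUE)]
  if (length(linked) == 0L) return(0)
  min(vapply(linked, function(v) {
    cached_protein_similarity(u, v, aspect, bundle, cache)
  }, 0))
}

#' Expanding-cluster condition
#'
#' A candidate `u` may expand cluster `pc` if it is functionally similar to
#' the cluster in at least two of the three ontologies: the CC, MF and BP
#' minimal similarities (see [cluster_min_similarity()]) are compared
#' against `sigma`, `omega` and `theta` (inclusive), and the condition is
#' the 2-of-3 majority of the three flags.
#'
#' @inheritParams cluster_min_similarity
#' @param thresholds An [icj_thresholds()] object.
#' @return List with `ec` (logical), per-ontology flags `bcc`, `bmf`,
#'   `bbp`, and the three similarity values `cc`, `mf`, `bp`.
#' @export
expanding_condition <- function(pc, u, bundle, net, thresholds,
                                cache = NULL) {
  smap <- if (is.numeric(net) && !is.null(names(net))) net
          else edge_score_map(net)
  cc <- cluster_min_similarity(pc, u, "CC", bundle, smap, thresholds$r, cache)
  mf <- cluster_min_similarity(pc, u, "MF", bundle, smap, thresholds$r, cache)
  bp <- cluster_min_similarity(pc, u, "BP", bundle, smap, thresholds$r, cache)
  bcc <- cc >= thresholds$sigma
  bmf <- mf >= thresholds$omega
  bbp <- bp >= thresholds$theta
  list(ec = sum(bcc, bmf, bbp) >= 2L, bcc = bcc, bmf = bmf, bbp = bbp,
       cc = cc, mf = mf, bp = bp)
}
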