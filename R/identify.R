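#' Identify protein clusters in one temporal-interval network
#'
#' Seed-expansion clustering under the three admission conditions. Seeds
#' are the network's nodes in order of descending weighted degree (sum of
#' incident interval edge scores), ties broken lexicographically; a node
#' already placed in an output cluster of this network cannot seed or join
#' another cluster here. From a seed, the frontier is the set of
#' unassigned non-members with at least one interval edge of score
#' `>= r` to the cluster, visited in order of descending best edge score
#' then lexicographic ID; the first frontier node for which the joint
#' colocalization condition (on the tentative cluster), the joint
#' coexpression condition (over the interval's `l + 4` window) and the
#' expanding-cluster condition all hold is admitted, and the frontier is
#' recomputed. Growth stops when no frontier node is admissible; clusters
#' smaller than `min_size` are discarded.
#'
#' @param inet An `interval_network`.
#' @param gep A `normalized_expression`.
#' @param loc Localization matrix from [read_localization()].
#' @param bundle An `annotation_bundle`.
#' @param thresholds An [icj_thresholds()] object.
#' @param min_size Minimum output cluster size (default 2).
#' @param strict_localization Passed to [joint_localization()].
#' @param jq_denominator Passed to [joint_coexpression()].
#' @param cache Optional environment memoizing protein similarities across
#'   calls.
#' @return List of clusters; each is a list with `members` (sorted
#'   character vector), `seed`, `t_low`, `t_high`.
#' @export
identify_in_network <- function(inet, gep, loc, bundle, thresholds,
                                min_size = 2L, strict_localization = FALSE,
                                jq_denominator = "window", cache = NULL) {
  stopifnot(inherits(inet, "interval_network"),
            inherits(thresholds, "icj_thresholds"))
  edges <- inet$edges
  if (nrow(edges) == 0L) return(list())
  window <- expression_window(inet$t_low, inet$t_high, ncol(gep$gep))
  smap <- edge_score_map(inet)
  ## adjacency: node -> named numeric vector of neighbor scores
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (k in seq_len(nrow(edges))) {
    a <- edges$protein_a[k]; b <- edges$protein_b[k]; s <- edges$b[k]
    adj[[a]][[b]] <- s
    adj[[b]][[a]] <- s
  }
  wdeg <- vapply(adj, function(x) sum(unlist(x)), 0)
  seeds <- nodes[order(-wdeg, nodes)]
  assigned <- new.env(parent = emptyenv())
  clusters <- list()
  for (seed in seeds) {
    if (!is.null(assigned[[seed]])) next
    pc <- seed
    ## running joint state (both conditions are anti-monotone, so the
    ## cluster state can be updated incrementally)
    jl <- joint_localization(pc, loc, strict = strict_localization)
    repeat {
      ## frontier: unassigned non-members with an r-reliable link to pc
      cand <- character(0); best <- numeric(0)
      for (v in pc) {
        nb <- adj[[v]]
        for (u in names(nb)) {
          if (u %in% pc || !is.null(assigned[[u]])) next
          if (nb[[u]] >= thresholds$r) {
            i <- match(u, cand)
            if (is.na(i)) { cand <- c(cand, u); best <- c(best, nb[[u]]) }
            else if (nb[[u]] > best[i]) best[i] <- nb[[u]]
          }
        }
      }
      if (length(cand) == 0L) break
      ord <- order(-best, cand)
      admitted <- NULL
      for (u in cand[ord]) {
        ## condition order: colocalization -> coexpression -> expansion
        jl_u <- joint_localization(c(pc, u), loc, strict = strict_localization)
        if (!jl_u$satisfied) next
        jq <- joint_coexpression(c(pc, u), gep, window,
                                 gamma = thresholds$gamma,
                                 denominator = jq_denominator)
        if (!jq$satisfied) next
        ec <- expanding_condition(pc, u, bundle, smap, thresholds, cache)
        if (!ec$ec) next
        admitted <- u
        break
      }
      if (is.null(admitted)) break
      pc <- c(pc, admitted)
    }
    if (length(pc) >= min_size) {
      for (p in pc) assigned[[p]] <- TRUE
      clusters[[length(clusters) + 1L]] <- list(members = sort(pc),
                                                seed = seed,
                                                t_low = inet$t_low,
                                                t_high = inet$t_high)
    }
  }
  clusters
}

#' Run the full identification sweep over all interval networks
#'
#' Applies [identify_in_network()] to every temporal-interval network (all
#' `T*(T+1)/2` of them, in ascending interval length) and merges the
#' resulting clusters into a catalog. With `dedup = "exact"` (default)
#' clusters with identical member sets are collapsed into one catalog entry
#' whose provenance lists every source interval; with `dedup = "none"`
#' every per-interval cluster is kept.
#'
#' @param tipins List of `interval_network` objects (from
#'   [merge_interval_networks()]).
#' @param gep A `normalized_expression`.
#' @param loc Localization matrix.
#' @param bundle An `annotation_bundle`.
#' @param thresholds An [icj_thresholds()] object.
#' @param min_size Minimum cluster size.
#' @param dedup `"exact"` or `"none"`.
#' @param strict_localization,jq_denominator Passed through.
#' @return A `complex_catalog`: list with `complexes` (list of sorted
#'   member vectors), `provenance` (list of data frames with columns
#'   `t_low`, `t_high`, `seed`) and `n_raw` (cluster count before
#'   deduplication).
#' @export
run_icjointle <- function(tipins, gep, loc, bundle, thresholds,
                          min_size = 2L, dedup = c("exact", "none"),
                          strict_localization = FALSE,
                          jq_denominator = "window") {
  dedup <- match.arg(dedup)
  lens <- vapply(tipins, function(x) x$l, 1L)
  lows <- vapply(tipins, function(x) x$t_low, 1L)
  cache <- new.env(parent = emptyenv())
  all_clusters <- list()
  for (i in order(lens, lows)) {
    cl <- identify_in_network(tipins[[i]], gep, loc, bundle, thresholds,
                              min_size = min_size,
                              strict_localization = strict_localization,
                              jq_denominator = jq_denominator,
                              cache = cache)
    all_clusters <- c(all_clusters, cl)
  }
  catalog_from_clusters(all_clusters, dedup = dedup)
}

catalog_from_clusters <- function(clusters, dedup = "exact") {
  n_raw <- length(clusters)
  if (n_raw == 0L) {
    return(structure(list(complexes = list(), provenance = list(),
                          n_raw = 0L), class = "complex_catalog"))
  }
  members <- lapply(clusters, `[[`, "members")
  prov <- lapply(clusters, function(cl) {
    data.frame(t_low = cl$t_low, t_high = cl$t_high, seed = cl$seed,
               stringsAsFactors = FALSE)
  })
  if (dedup == "exact") {
    key <- vapply(members, paste, "", collapse = "\t")
    first <- !duplicated(key)
    idx <- match(key, key[first])
    out_members <- members[first]
    out_prov <- lapply(seq_len(sum(first)), function(j) {
      do.call(rbind, prov[idx == j])
    })
  } else {
    out_members <- members
    out_prov <- prov
  }
  structure(list(complexes = out_members, provenance = out_prov,
                 n_raw = n_raw), class = "complex_catalog")
}

#' @export
print.complex_catalog <- function(x, ...) {
  cat("complex_catalog:", length(x$complexes), "complexes (",
      x$n_raw, "before deduplication )\n")
  invisible(x)
}

#' Merge complex catalogs
#'
#' Exact member-set deduplication with provenance accumulation;
#' idempotent.
#'
#' @param ... `complex_catalog` objects.
#' @return A merged `complex_catalog`.
#' @export
merge_catalogs <- function(...) {
  cats <- list(...)
  clusters <- list()
  n_raw <- 0L
  for (ct in cats) {
    n_raw <- n_raw + ct$n_raw
    for (i in seq_along(ct$complexes)) {
      pv <- ct$provenance[[i]]
      for (k in seq_len(nrow(pv))) {
        clusters[[length(clusters) + 1L]] <-
          list(members = ct$complexes[[i]], t_low = pv$t_low[k],
               t_high = pv$t_high[k], seed = pv$seed[k])
      }
    }
  }
  out <- catalog_from_clusters(clusters, dedup = "exact")
  out$n_raw <- n_raw
  out
}

#' Convert a catalog to a plain complex list
#'
#' @param catalog A `complex_catalog`.
#' @return A `complex_list` suitable for [write_complexes()] and
#'   [match_report()].
#' @export
as_complex_list <- function(catalog) {
  complex_list(catalog$complexes)
}
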