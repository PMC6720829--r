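#' Construct a scored static interaction network
#'
#' Weights a base interaction network with external reliability scores.
#' Every edge of `base_edges` is kept: edges that also appear (as an
#' unordered pair) in `scored_edges` get that score, edges without a score
#' get weight 1, and scored pairs absent from the base network are ignored
#' (no edge, score 0).
#'
#' @param base_edges Data frame with columns `protein_a`, `protein_b`
#'   (unscored pair list defining the edge set).
#' @param scored_edges Optional data frame with `protein_a`, `protein_b`,
#'   `score` (1-999). If `NULL` all base edges get weight 1.
#' @param drop_unscored If `TRUE`, base edges with no external score are
#'   dropped instead of getting weight 1.
#' @return A `scored_network`: list with `nodes` (character, sorted) and
#'   `edges` (data frame `protein_a`, `protein_b`, `score`), canonical pair
#'   order, no self-loops, no duplicates.
#' @export
weight_network <- function(base_edges, scored_edges = NULL,
                           drop_unscored = FALSE) {
  if (is.null(base_edges) || nrow(base_edges) == 0L) {
    stop("empty base edge set")
  }
  cp <- canonical_pairs(as.character(base_edges$protein_a),
                        as.character(base_edges$protein_b))
  keep <- cp$a != cp$b
  key <- paste(cp$a, cp$b, sep = "\t")[keep]
  a <- cp$a[keep][!duplicated(key)]
  b <- cp$b[keep][!duplicated(key)]
  key <- key[!duplicated(key)]
  score <- rep(1L, length(key))
  if (!is.null(scored_edges) && nrow(scored_edges) > 0L) {
    sp <- canonical_pairs(as.character(scored_edges$protein_a),
                          as.character(scored_edges$protein_b))
    skey <- paste(sp$a, sp$b, sep = "\t")
    hit <- match(key, skey)
    score[!is.na(hit)] <- as.integer(scored_edges$score[hit[!is.na(hit)]])
    if (drop_unscored) {
      keep2 <- !is.na(hit)
      a <- a[keep2]; b <- b[keep2]; score <- score[keep2]; key <- key[keep2]
    }
  }
  ord <- order(key)
  scored_network(a[ord], b[ord], score[ord])
}

#' Low-level scored network constructor
#'
#' @param protein_a,protein_b Character vectors of canonical pairs
#'   (`protein_a < protein_b`, no duplicates, no self-loops).
#' @param score Integer scores in \[1, 999\].
#' @return A `scored_network` object.
#' @export
scored_network <- function(protein_a, protein_b, score) {
  stopifnot(length(protein_a) == length(protein_b),
            length(score) == length(protein_a),
            all(protein_a != protein_b),
            all(score >= 1L), all(score <= 999L))
  structure(list(
    nodes = sort(unique(c(protein_a, protein_b))),
    edges = data.frame(protein_a = protein_a, protein_b = protein_b,
                       score = as.integer(score), stringsAsFactors = FALSE)
  ), class = "scored_network")
}

#' @export
print.scored_network <- function(x, ...) {
  cat("scored_network:", length(x$nodes), "proteins,",
      nrow(x$edges), "interactions\n")
  invisible(x)
}

#' Average replicate expression cycles
#'
#' Collapses a raw multi-cycle expression profile (e.g. three successive
#' metabolic cycles of 12 samples each) into a single cycle by averaging,
#' for each within-cycle position, the values at that position across
#' cycles: output column `i` is the mean of input columns
#' `i, i+P, ..., i+(n_cycles-1)*P` with `P = ncol/n_cycles`.
#'
#' @param raw An `expression_table`.
#' @param n_cycles Number of replicate cycles; must divide the column count.
#' @return An `expression_table` with `ncol(raw)/n_cycles` time points.
#' @export
collapse_cycles <- function(raw, n_cycles) {
  stopifnot(inherits(raw, "expression_table"), n_cycles >= 1L)
  tc <- ncol(raw$values)
  if (tc %% n_cycles != 0L) {
    stop("column count ", tc, " not divisible by n_cycles = ", n_cycles)
  }
  if (n_cycles == 1L) return(raw)
  P <- tc %/% n_cycles
  out <- matrix(0, nrow(raw$values), P)
  for (c0 in seq_len(n_cycles) - 1L) {
    out <- out + raw$values[, c0 * P + seq_len(P), drop = FALSE]
  }
  expression_table(raw$genes, out / n_cycles)
}

#' Normalize expression to the per-gene \[0, 1\] undulation scale
#'
#' Per gene, maps raw values to `(ev - min) / (max - min)`, the undulating
#' degree above the gene's base expression level. Degenerate genes with
#' constant expression are set to all zeros (no undulation, never active
#' for any positive threshold).
#'
#' @param raw An `expression_table`.
#' @return A `normalized_expression`: list with `genes` and `gep`
#'   (numeric matrix in \[0, 1\], genes x time points).
#' @export
normalize_expression <- function(raw) {
  stopifnot(inherits(raw, "expression_table"))
  v <- raw$values
  lo <- apply(v, 1L, min)
  hi <- apply(v, 1L, max)
  span <- hi - lo
  gep <- (v - lo) / ifelse(span > 0, span, 1)
  gep[span == 0, ] <- 0
  structure(list(genes = raw$genes, gep = gep),
            class = "normalized_expression")
}

#' Compute per-time-point activity states
#'
#' A gene product is active at time `t` iff its normalized expression at
#' `t` is at least the active threshold `phi` (inclusive, exact
#' comparison).
#'
#' @param gep A `normalized_expression`.
#' @param phi Active threshold in \[0, 1\].
#' @return An `activity_matrix`: list with `ap` (0/1 integer matrix,
#'   genes x time points) and `phi`.
#' @export
compute_activity <- function(gep, phi) {
  stopifnot(inherits(gep, "normalized_expression"))
  if (!is.numeric(phi) || length(phi) != 1L || phi < 0 || phi > 1) {
    stop("active threshold phi must be a single value in [0, 1]")
  }
  ap <- (gep$gep >= phi) * 1L
  structure(list(ap = ap, phi = phi), class = "activity_matrix")
}

#' Build the series of temporal interaction networks
#'
#' Restricts the scored static network to the proteins active at each time
#' point: the score of edge (i, j) at time t is
#' `ap_i(t) * ap_j(t) * a(i, j)`. Proteins without an expression profile
#' are treated as never active, so all their edges vanish from every
#' temporal network.
#'
#' @param net A `scored_network`.
#' @param act An `activity_matrix`.
#' @return A `temporal_series`: list with `nodes`, `edges` (the static
#'   pairs and scores) and `da` (integer matrix, edges x time points, the
#'   per-time-point edge scores).
#' @export
build_temporal_series <- function(net, act) {
  stopifnot(inherits(net, "scored_network"), inherits(act, "activity_matrix"))
  Tn <- ncol(act$ap)
  if (Tn == 0L) stop("activity matrix has no time points")
  genes <- rownames(act$ap)
  ia <- match(net$edges$protein_a, genes)
  ib <- match(net$edges$protein_b, genes)
  ## activity rows for the edge endpoints (all-zero row when the protein
  ## has no expression profile: never active)
  get_rows <- function(idx) {
    m <- matrix(0L, length(idx), Tn)
    ok <- !is.na(idx)
    if (any(ok)) m[ok, ] <- act$ap[idx[ok], , drop = FALSE]
    m
  }
  da <- get_rows(ia) * get_rows(ib) * net$edges$score
  structure(list(nodes = net$nodes, edges = net$edges, da = da,
                 n_time = Tn), class = "temporal_series")
}

interval_network <- function(t_low, t_high, edges_a, edges_b, b) {
  keep <- b > 0L
  structure(list(t_low = t_low, t_high = t_high,
                 l = t_high - t_low + 1L,
                 edges = data.frame(protein_a = edges_a[keep],
                                    protein_b = edges_b[keep],
                                    b = as.integer(b[keep]),
                                    stringsAsFactors = FALSE)),
            class = "interval_network")
}

#' @export
print.interval_network <- function(x, ...) {
  cat(sprintf("interval_network [%d, %d]: %d edges\n",
              x$t_low, x$t_high, nrow(x$edges)))
  invisible(x)
}

#' Merge temporal networks into temporal-interval networks
#'
#' Builds every temporal-interval network over closed 1-based intervals
#' `[t_low, t_high]`. The interval edge score is the minimum of the
#' per-time-point scores over the interval, computed bottom-up by the
#' recurrence `b[low, high] = min(b[low, high-1], b[low+1, high])` in
#' ascending interval length; the length-1 diagonal equals the temporal
#' networks themselves. Edges with interval score 0 are absent. With T time
#' points this yields `T*(T+1)/2` networks including the diagonal
#' (`T*(T-1)/2` strictly merged ones).
#'
#' @param series A `temporal_series`.
#' @param max_length Optional cap on the interval length (defaults to all
#'   lengths up to T).
#' @return A list of `interval_network` objects ordered by ascending
#'   length, then by `t_low`.
#' @export
merge_interval_networks <- function(series, max_length = NULL) {
  stopifnot(inherits(series, "temporal_series"))
  Tn <- series$n_time
  if (is.null(max_length)) max_length <- Tn
  a <- series$edges$protein_a
  b <- series$edges$protein_b
  out <- vector("list", 0L)
  ## band of interval score vectors at the current length; only two bands
  ## are ever materialized
  band <- lapply(seq_len(Tn), function(t) series$da[, t])
  for (t in seq_len(Tn)) {
    out[[length(out) + 1L]] <- interval_network(t, t, a, b, band[[t]])
  }
  l <- 2L
  while (l <= min(max_length, Tn)) {
    nxt <- vector("list", Tn - l + 1L)
    for (low in seq_len(Tn - l + 1L)) {
      nxt[[low]] <- pmin(band[[low]], band[[low + 1L]])
      out[[length(out) + 1L]] <- interval_network(low, low + l - 1L, a, b,
                                                  nxt[[low]])
    }
    band <- nxt
    l <- l + 1L
  }
  ## ascending length, then t_low (already produced in that order)
  out
}

#' One-call TI-PIN construction from files or objects
#'
#' Convenience wrapper chaining [weight_network()], [collapse_cycles()],
#' [normalize_expression()], [compute_activity()],
#' [build_temporal_series()] and [merge_interval_networks()].
#'
#' @param base_edges Unscored pair data frame (or `scored_network` to use
#'   as-is, in which case `scored_edges` is ignored).
#' @param scored_edges Scored pair data frame or `NULL`.
#' @param expr An `expression_table`.
#' @param phi Active threshold.
#' @param n_cycles Number of replicate expression cycles to average.
#' @return A list with `network`, `gep`, `activity`, `series`, `tipins`.
#' @export
build_tipins <- function(base_edges, scored_edges = NULL, expr, phi,
                         n_cycles = 1L) {
  net <- if (inherits(base_edges, "scored_network")) base_edges
         else weight_network(base_edges, scored_edges)
  expr <- collapse_cycles(expr, n_cycles)
  gep <- normalize_expression(expr)
  act <- compute_activity(gep, phi)
  series <- build_temporal_series(net, act)
  list(network = net, gep = gep, activity = act, series = series,
       tipins = merge_interval_networks(series))
}
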