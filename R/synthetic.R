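#' Specification of a synthetic benchmark bundle
#'
#' Describes a fully synthetic input bundle with planted ground-truth
#' complexes. Defaults emulate a small yeast-like benchmark: a 12-point
#' expression time course (one averaged metabolic cycle), 10 planted
#' complexes of 3-6 proteins each carrying maximal-reliability (999)
#' within-complex interactions, a background of 100 proteins with random
#' low-scored interactions, one shared subcellular compartment and a
#' complex-specific deep GO term per planted complex in all three
#' ontologies.
#'
#' @param seed Integer RNG seed (Mersenne-Twister).
#' @param n_background Number of background proteins.
#' @param n_complexes Number of planted complexes.
#' @param size_range Inclusive complex size range (min at least 2).
#' @param n_time Time points per cycle.
#' @param n_cycles Replicate cycles in the raw expression table (the
#'   pipeline averages them back).
#' @param interval_length_range Inclusive range of planted interval
#'   lengths.
#' @param within_score Reliability score of within-complex edges (default
#'   999, i.e. r-reliable at the strictest published threshold).
#' @param background_score_range Score range of background edges; the
#'   default \[1, 900\] keeps them below every published `r`.
#' @param background_edge_factor Background edge count as a multiple of the
#'   protein count.
#' @param noise Expression noise level in \[0, 1\]: Gaussian noise with
#'   standard deviation `noise` times the signal amplitude is added to the
#'   raw values.
#' @param extra_localization_prob Probability that a planted member gets
#'   one additional random compartment beyond the complex's shared one.
#' @param go_depth Depth of the complex-specific GO leaves (default 5).
#' @param overlap Allow planted complexes to share a protein (stress mode;
#'   default keeps them vertex-disjoint).
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(seed = 1L, n_background = 100L, n_complexes = 10L,
                           size_range = c(3L, 6L), n_time = 12L,
                           n_cycles = 1L, interval_length_range = c(1L, 3L),
                           within_score = 999L,
                           background_score_range = c(1L, 900L),
                           background_edge_factor = 3,
                           noise = 0, extra_localization_prob = 0.3,
                           go_depth = 5L, overlap = FALSE) {
  if (size_range[1] < 2L) stop("infeasible spec: complexes need >= 2 members")
  if (interval_length_range[2] > n_time) {
    stop("infeasible spec: planted interval longer than the time course")
  }
  if (n_time < 1L || n_cycles < 1L) stop("infeasible spec: empty time course")
  if (within_score < 1L || within_score > 999L ||
      background_score_range[1] < 1L || background_score_range[2] > 999L) {
    stop("infeasible spec: scores must lie in [1, 999]")
  }
  if (noise < 0 || noise > 1) stop("noise level must be in [0, 1]")
  structure(list(seed = as.integer(seed), n_background = as.integer(n_background),
                 n_complexes = as.integer(n_complexes),
                 size_range = as.integer(size_range),
                 n_time = as.integer(n_time), n_cycles = as.integer(n_cycles),
                 interval_length_range = as.integer(interval_length_range),
                 within_score = as.integer(within_score),
                 background_score_range = as.integer(background_score_range),
                 background_edge_factor = background_edge_factor,
                 noise = noise,
                 extra_localization_prob = extra_localization_prob,
                 go_depth = as.integer(go_depth), overlap = overlap),
            class = "synthetic_spec")
}

#' Generate a synthetic input bundle with planted complexes
#'
#' Deterministic given the spec's seed. At noise level 0, the members of
#' each planted complex are expressed above base level exactly on the
#' `l + 4` coexpression window around the planted interval (normalized
#' expression 1 there, 0 elsewhere), every within-complex edge carries the
#' `within_score` reliability, all members share one subcellular
#' compartment and one complex-specific GO term of depth `go_depth` in each
#' of the three ontologies. Background edges stay below the published
#' reliability thresholds so they cannot seed spurious r-reliable clusters.
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `ground_truth`: list with `spec`, `proteins`,
#'   `base_edges`, `scored_edges`, `expression` (raw `expression_table`
#'   with `n_time * n_cycles` columns), `localization`, `dag`,
#'   `annotations`, `complexes` (planted `complex_list`) and `intervals`
#'   (data frame of planted `t_low`, `t_high`).
#' @export
generate_bundle <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  Tn <- spec$n_time
  sizes <- sample(seq(spec$size_range[1], spec$size_range[2]),
                  spec$n_complexes, replace = TRUE)
  members <- lapply(seq_len(spec$n_complexes), function(k) {
    sprintf("CPX%02dP%d", k, seq_len(sizes[k]))
  })
  if (spec$overlap && spec$n_complexes > 1L) {
    for (k in 2:spec$n_complexes) {
      if (stats::runif(1) < 0.3) {
        members[[k]][1] <- sample(members[[k - 1L]], 1L)
        members[[k]] <- unique(members[[k]])
      }
    }
  }
  bg <- if (spec$n_background > 0L) sprintf("BG%03d", seq_len(spec$n_background))
        else character(0)
  proteins <- unique(c(unlist(members), bg))

  ## planted activity intervals and their coexpression windows
  lens <- sample(seq(spec$interval_length_range[1],
                     spec$interval_length_range[2]),
                 spec$n_complexes, replace = TRUE)
  t_low <- vapply(lens, function(l) sample(seq_len(Tn - l + 1L), 1L), 1L)
  t_high <- t_low + lens - 1L
  intervals <- data.frame(t_low = t_low, t_high = t_high)

  ## raw expression: base level 2, peak 10 on the planted window
  base_lv <- 2; peak <- 10
  vals <- matrix(base_lv, length(proteins), Tn,
                 dimnames = list(proteins, NULL))
  for (k in seq_len(spec$n_complexes)) {
    w <- expression_window(t_low[k], t_high[k], Tn)
    vals[members[[k]], w[1]:w[2]] <- peak
  }
  if (length(bg)) {
    vals[bg, ] <- matrix(stats::runif(length(bg) * Tn, base_lv, peak),
                         length(bg), Tn)
  }
  raw <- vals[, rep(seq_len(Tn), spec$n_cycles), drop = FALSE]
  if (spec$noise > 0) {
    raw <- raw + matrix(stats::rnorm(length(raw), 0,
                                     spec$noise * (peak - base_lv)),
                        nrow(raw), ncol(raw))
  }
  expr <- expression_table(proteins, raw)

  ## interactions: within-complex cliques at within_score, background below r
  wa <- character(0); wb <- character(0)
  for (k in seq_len(spec$n_complexes)) {
    pr <- utils::combn(sort(members[[k]]), 2L)
    wa <- c(wa, pr[1, ]); wb <- c(wb, pr[2, ])
  }
  within_key <- paste(wa, wb, sep = "\t")
  n_bg_edges <- round(spec$background_edge_factor * length(proteins))
  all_pr <- utils::combn(sort(proteins), 2L)
  all_key <- paste(all_pr[1, ], all_pr[2, ], sep = "\t")
  pool <- which(!(all_key %in% within_key))
  pick <- sample(pool, min(n_bg_edges, length(pool)))
  ba <- all_pr[1, pick]; bb <- all_pr[2, pick]
  bscore <- sample(seq(spec$background_score_range[1],
                       spec$background_score_range[2]),
                   length(pick), replace = TRUE)
  base_edges <- data.frame(protein_a = c(wa, ba), protein_b = c(wb, bb),
                           stringsAsFactors = FALSE)
  scored_edges <- data.frame(
    protein_a = c(wa, ba), protein_b = c(wb, bb),
    score = as.integer(c(rep(spec$within_score, length(wa)), bscore)),
    stringsAsFactors = FALSE)

  ## localization: one shared compartment per complex, random extras
  n_cat <- length(yeast_localization_categories)
  loc <- matrix(0L, length(proteins), n_cat,
                dimnames = list(proteins, yeast_localization_categories))
  shared_cat <- sample(n_cat, spec$n_complexes, replace = TRUE)
  for (k in seq_len(spec$n_complexes)) {
    loc[members[[k]], shared_cat[k]] <- 1L
    for (p in members[[k]]) {
      if (stats::runif(1) < spec$extra_localization_prob) {
        loc[p, sample(n_cat, 1L)] <- 1L
      }
    }
  }
  for (p in bg) loc[p, sample(n_cat, sample(2L, 1L))] <- 1L

  ## toy GO: per aspect a shared spine of depth go_depth - 1, one leaf per
  ## complex at depth go_depth, one generic depth-1 term for the background
  dag <- list(); annotations <- list()
  for (aspect in c("BP", "MF", "CC")) {
    root <- paste0(aspect, ":ROOT")
    spine <- if (spec$go_depth > 1L) {
      paste0(aspect, ":S", seq_len(spec$go_depth - 1L))
    } else character(0)
    leaves <- if (spec$n_complexes > 0L) {
      paste0(aspect, sprintf(":CPX%02d", seq_len(spec$n_complexes)))
    } else character(0)
    gen <- paste0(aspect, ":GEN")
    terms <- c(root, spine, leaves, gen)
    parents <- stats::setNames(vector("list", length(terms)), terms)
    parents[[root]] <- character(0)
    chain <- c(root, spine)
    for (i in seq_along(spine)) parents[[spine[i]]] <- chain[i]
    for (lf in leaves) parents[[lf]] <- chain[length(chain)]
    parents[[gen]] <- root
    dag[[aspect]] <- list(terms = terms, parents = parents, roots = root)
    ann <- stats::setNames(vector("list", length(proteins)), proteins)
    for (k in seq_len(spec$n_complexes)) {
      for (p in members[[k]]) ann[[p]] <- union(ann[[p]], leaves[k])
    }
    for (p in bg) ann[[p]] <- gen
    annotations[[aspect]] <- ann[lengths(ann) > 0L]
  }
  class(dag) <- "go_dag"

  structure(list(spec = spec, proteins = proteins,
                 base_edges = base_edges, scored_edges = scored_edges,
                 expression = expr, localization = loc, dag = dag,
                 annotations = annotations,
                 complexes = complex_list(members), intervals = intervals),
            class = "ground_truth")
}

#' Verify the internal consistency of a generated bundle
#'
#' Checks the generator's guarantees: every planted complex satisfies the
#' joint colocalization condition, the joint coexpression condition over
#' its planted window (at noise 0), and pairwise GO similarities above the
#' thresholds in at least two ontologies; background edges stay below `r`.
#'
#' @param gt A `ground_truth`.
#' @param thresholds An [icj_thresholds()] object.
#' @return List with `ok` (logical) and `issues` (character vector).
#' @export
verify_ground_truth <- function(gt, thresholds = icj_thresholds()) {
  issues <- character(0)
  gep <- normalize_expression(collapse_cycles(gt$expression,
                                              gt$spec$n_cycles))
  bundle <- annotation_bundle(gt$dag, gt$annotations)
  smap <- edge_score_map(gt$scored_edges)
  for (k in seq_along(gt$complexes)) {
    ps <- gt$complexes[[k]]
    if (!joint_localization(ps, gt$localization)$satisfied) {
      issues <- c(issues, sprintf("complex %d fails joint colocalization", k))
    }
    w <- expression_window(gt$intervals$t_low[k], gt$intervals$t_high[k],
                           gt$spec$n_time)
    if (!joint_coexpression(ps, gep, w, thresholds$gamma)$satisfied) {
      issues <- c(issues, sprintf("complex %d fails joint coexpression", k))
    }
    prs <- utils::combn(ps, 2L)
    for (j in seq_len(ncol(prs))) {
      sims <- c(CC = protein_similarity(prs[1, j], prs[2, j], bundle$CC),
                MF = protein_similarity(prs[1, j], prs[2, j], bundle$MF),
                BP = protein_similarity(prs[1, j], prs[2, j], bundle$BP))
      ok2 <- sum(sims["CC"] >= thresholds$sigma,
                 sims["MF"] >= thresholds$omega,
                 sims["BP"] >= thresholds$theta) >= 2L
      if (!ok2) {
        issues <- c(issues, sprintf(
          "pair %s-%s of complex %d similar in < 2 ontologies",
          prs[1, j], prs[2, j], k))
      }
    }
  }
  within <- unlist(lapply(gt$complexes, function(ps) {
    pr <- utils::combn(sort(ps), 2L); paste(pr[1, ], pr[2, ], sep = "\t")
  }))
  bg_scores <- smap[setdiff(names(smap), within)]
  if (length(bg_scores) && any(bg_scores >= thresholds$r)) {
    issues <- c(issues, "background edge at or above the reliability threshold")
  }
  list(ok = length(issues) == 0L, issues = issues)
}

#' Write a synthetic bundle to disk
#'
#' Emits every input file of the pipeline plus a plain-text manifest
#' recording the seed and all generator parameters.
#'
#' @param gt A `ground_truth`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(gt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_interactions(gt$base_edges, file.path(dir, "ppi_base.tsv"))
  write_interactions(gt$scored_edges, file.path(dir, "ppi_scored.tsv"))
  write_expression(gt$expression, file.path(dir, "expression.tsv"))
  write_localization(gt$localization, file.path(dir, "localization.tsv"))
  write_obo(gt$dag, file.path(dir, "ontology.obo"))
  write_gaf(gt$annotations, file.path(dir, "annotations.gaf"))
  write_complexes(gt$complexes, file.path(dir, "complexes.txt"),
                  provenance = sprintf("interval=%d,%d",
                                       gt$intervals$t_low,
                                       gt$intervals$t_high))
  sp <- gt$spec
  manifest <- c("rng: Mersenne-Twister",
                vapply(names(sp), function(nm) {
                  paste0(nm, ": ", paste(sp[[nm]], collapse = " "))
                }, ""))
  writeLines(manifest, file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Read a synthetic bundle back from disk
#'
#' @param dir Directory written by [write_bundle()].
#' @return List with `base_edges`, `scored_edges`, `expression`,
#'   `localization`, `dag`, `annotations`, `complexes`.
#' @export
read_bundle <- function(dir) {
  dag <- read_ontology(file.path(dir, "ontology.obo"))
  list(base_edges = read_unscored_interactions(file.path(dir, "ppi_base.tsv")),
       scored_edges = read_scored_interactions(file.path(dir, "ppi_scored.tsv")),
       expression = read_expression(file.path(dir, "expression.tsv")),
       localization = read_localization(file.path(dir, "localization.tsv")),
       dag = dag,
       annotations = read_annotations(file.path(dir, "annotations.gaf"), dag),
       complexes = read_complexes(file.path(dir, "complexes.txt")))
}

#' Run the full pipeline on a synthetic bundle and score the recovery
#'
#' Chains network weighting, cycle averaging, normalization, activity,
#' TI-PIN construction and the identification sweep, then matches the
#' predicted catalog against the planted complexes.
#'
#' @param gt A `ground_truth`.
#' @param thresholds An [icj_thresholds()] object.
#' @param phi Active threshold (default 0.1, the published value for the
#'   STRING-based networks).
#' @param min_size Minimum output cluster size.
#' @return List with `catalog` (a `complex_catalog`) and `report` (a
#'   [match_report()] against the planted truth).
#' @export
recover_complexes <- function(gt, thresholds = icj_thresholds(), phi = 0.1,
                              min_size = 2L) {
  pipe <- build_tipins(gt$base_edges, gt$scored_edges, gt$expression,
                       phi = phi, n_cycles = gt$spec$n_cycles)
  bundle <- annotation_bundle(gt$dag, gt$annotations)
  catalog <- run_icjointle(pipe$tipins, pipe$gep, gt$localization, bundle,
                           thresholds, min_size = min_size)
  report <- if (length(catalog$complexes) > 0L) {
    match_report(catalog$complexes, gt$complexes)
  } else NULL
  list(catalog = catalog, report = report)
}
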