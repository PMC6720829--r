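#' Subcellular localization categories for yeast
#'
#' The 22 subcellular compartments used to encode protein localization as a
#' 0/1 vector. The order is fixed; localization vectors produced by
#' [read_localization()] are indexed by this vector.
#'
#' @format A character vector of length 22.
#' @export
yeast_localization_categories <- c(
  "mitochondrion", "vacuole", "spindle pole", "cell periphery",
  "punctate composite", "vacuolar membrane", "ER", "nuclear periphery",
  "endosome", "bud neck", "microtubule", "Golgi", "late Golgi",
  "peroxisome", "actin", "nucleolus", "cytoplasm", "ER to Golgi",
  "early Golgi", "lipid particle", "nucleus", "bud"
)

## split a bespoke text file into non-comment, non-blank lines with their
## original line numbers ('#' starts a comment line in all bespoke formats)
read_clean_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

split_fields <- function(line) {
  strsplit(trimws(line), "[ \t]+")[[1]]
}

canonical_pairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  list(a = a, b = b)
}

#' Read a scored protein-protein interaction list
#'
#' Parses a STRING-style edge list: two protein identifiers per line plus an
#' integer reliability score in \[1, 999\]. Pairs are canonicalized (unordered,
#' stored with the lexicographically smaller identifier first), duplicate
#' pairs keep the maximum score, and self-interactions are dropped with a
#' message reporting the count.
#'
#' @param path Path to a whitespace-delimited text file. Lines starting with
#'   `#` are ignored.
#' @param scored If `TRUE` (default) a third integer column is required;
#'   if `FALSE` only the two identifier columns are read and the returned
#'   `score` column is `NA`.
#' @return A data frame with columns `protein_a`, `protein_b`, `score`
#'   (integer or `NA`), one row per canonical pair, ordered by pair.
#' @seealso [read_unscored_interactions()], [weight_network()]
#' @export
read_scored_interactions <- function(path, scored = TRUE) {
  cl <- read_clean_lines(path)
  if (length(cl$lines) == 0L) {
    stop("no interactions in '", path, "'")
  }
  fields <- lapply(cl$lines, split_fields)
  nf <- lengths(fields)
  want <- if (scored) 3L else 2L
  bad <- which(nf < want)
  if (length(bad)) {
    stop("malformed interaction line ", cl$lineno[bad[1]], " in '", path,
         "': expected at least ", want, " fields, got ", nf[bad[1]])
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  if (scored) {
    raw <- vapply(fields, `[[`, "", 3L)
    score <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(score) | score != floor(score))
    if (length(bad)) {
      stop("malformed score '", raw[bad[1]], "' on line ", cl$lineno[bad[1]],
           " in '", path, "'")
    }
    out_of_range <- which(score < 1 | score > 999)
    if (length(out_of_range)) {
      stop("score ", score[out_of_range[1]], " on line ",
           cl$lineno[out_of_range[1]], " outside [1, 999]")
    }
    score <- as.integer(score)
  } else {
    score <- rep(NA_integer_, length(a))
  }
  self <- a == b
  if (any(self)) {
    message("dropped ", sum(self), " self-interaction(s)")
    a <- a[!self]; b <- b[!self]; score <- score[!self]
  }
  cp <- canonical_pairs(a, b)
  key <- paste(cp$a, cp$b, sep = "\t")
  ## duplicate policy: keep the maximum score
  if (anyDuplicated(key)) {
    ord <- order(key, -ifelse(is.na(score), 0L, score))
    keep <- !duplicated(key[ord])
    idx <- ord[keep]
  } else {
    idx <- order(key)
  }
  data.frame(protein_a = cp$a[idx], protein_b = cp$b[idx],
             score = score[idx], stringsAsFactors = FALSE)
}

#' Read an unscored interaction pair list
#'
#' BioGrid/DIP-style two-column pair list; same canonicalization, duplicate
#' and self-pair handling as [read_scored_interactions()].
#'
#' @inheritParams read_scored_interactions
#' @return A data frame with columns `protein_a`, `protein_b`.
#' @export
read_unscored_interactions <- function(path) {
  read_scored_interactions(path, scored = FALSE)[, c("protein_a", "protein_b")]
}

#' Write an interaction list
#'
#' @param x Data frame with columns `protein_a`, `protein_b` and optionally
#'   `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(x, path) {
  cols <- intersect(c("protein_a", "protein_b", "score"), names(x))
  utils::write.table(x[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene expression matrix
#'
#' First column: gene identifier; remaining columns: numeric expression
#' values, one per time point. A header line is detected automatically (a
#' first row whose non-leading fields are not all numeric is treated as a
#' header and skipped).
#'
#' @param path Path to a whitespace-delimited matrix file.
#' @return An object of class `expression_table`: list with `genes`
#'   (character), `values` (numeric matrix, genes x time points) and
#'   `n_time` (integer).
#' @export
read_expression <- function(path) {
  cl <- read_clean_lines(path)
  if (length(cl$lines) == 0L) stop("no genes in '", path, "'")
  fields <- lapply(cl$lines, split_fields)
  first_vals <- suppressWarnings(as.numeric(fields[[1]][-1]))
  if (length(fields[[1]]) > 1L && all(is.na(first_vals))) {
    fields <- fields[-1]
    cl$lineno <- cl$lineno[-1]
    if (length(fields) == 0L) stop("no genes in '", path, "'")
  }
  nf <- lengths(fields)
  if (any(nf != nf[1])) {
    bad <- which(nf != nf[1])[1]
    stop("ragged row at line ", cl$lineno[bad], " in '", path, "': ",
         nf[bad], " fields, expected ", nf[1])
  }
  if (nf[1] < 2L) stop("expression file '", path, "' has no value columns")
  genes <- vapply(fields, `[[`, "", 1L)
  dup <- genes[duplicated(genes)]
  if (length(dup)) stop("duplicated gene ID '", dup[1], "' in '", path, "'")
  vals <- do.call(rbind, lapply(fields, function(f) {
    suppressWarnings(as.numeric(f[-1]))
  }))
  if (anyNA(vals) || any(!is.finite(vals))) {
    bad <- which(apply(vals, 1L, function(r) anyNA(r) || any(!is.finite(r))))[1]
    stop("non-numeric or non-finite expression value for gene '",
         genes[bad], "' in '", path, "'")
  }
  rownames(vals) <- genes
  expression_table(genes, vals)
}

#' Construct an expression table
#'
#' @param genes Character vector of unique gene identifiers.
#' @param values Numeric matrix, `length(genes)` rows.
#' @return An `expression_table` object.
#' @export
expression_table <- function(genes, values) {
  values <- as.matrix(values)
  stopifnot(length(genes) == nrow(values), !anyDuplicated(genes),
            all(is.finite(values)))
  rownames(values) <- genes
  structure(list(genes = genes, values = values, n_time = ncol(values)),
            class = "expression_table")
}

#' Write an expression table
#'
#' @param x An `expression_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expression_table"))
  df <- data.frame(gene = x$genes, x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a protein subcellular localization table
#'
#' Each row lists a protein identifier followed by the names of the
#' compartments in which the protein was observed during the cell cycle.
#' Multi-word category names (e.g. `spindle pole`) must be joined with an
#' underscore in the file; underscores are translated back to spaces before
#' matching against `categories`. A protein listed on several lines gets the
#' union (logical OR) of its vectors.
#'
#' @param path Path to the localization file.
#' @param categories Character vector of valid category names; defaults to
#'   [yeast_localization_categories].
#' @return A 0/1 integer matrix, proteins x categories, with protein IDs as
#'   row names and `categories` as column names.
#' @export
read_localization <- function(path, categories = yeast_localization_categories) {
  cl <- read_clean_lines(path)
  if (length(cl$lines) == 0L) stop("no localization rows in '", path, "'")
  mat_rows <- new.env(parent = emptyenv())
  order_seen <- character(0)
  for (k in seq_along(cl$lines)) {
    f <- split_fields(cl$lines[k])
    if (length(f) < 2L) {
      stop("localization line ", cl$lineno[k],
           " lists no categories for protein '", f[1], "'")
    }
    prot <- f[1]
    cats <- gsub("_", " ", f[-1], fixed = TRUE)
    idx <- match(cats, categories)
    if (anyNA(idx)) {
      stop("unknown localization category '", cats[which(is.na(idx))[1]],
           "' on line ", cl$lineno[k], " in '", path, "'")
    }
    vec <- integer(length(categories))
    vec[idx] <- 1L
    if (!is.null(mat_rows[[prot]])) {
      vec <- pmax(mat_rows[[prot]], vec)  # OR across appearances
    } else {
      order_seen <- c(order_seen, prot)
    }
    mat_rows[[prot]] <- vec
  }
  out <- t(vapply(order_seen, function(p) mat_rows[[p]],
                  integer(length(categories))))
  rownames(out) <- order_seen
  colnames(out) <- categories
  out
}

#' Write a localization table
#'
#' Inverse of [read_localization()]: spaces inside category names are
#' rendered as underscores.
#'
#' @param x 0/1 matrix, proteins x categories, with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_localization <- function(x, path) {
  cats <- gsub(" ", "_", colnames(x), fixed = TRUE)
  lines <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], cats[x[i, ] > 0]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a complex catalog
#'
#' One complex per line, whitespace-separated protein IDs (the CYC2008
#' line format). Singleton lines are dropped with a warning. Within each
#' complex, member IDs are deduplicated and kept in file order.
#'
#' @param path Path to the catalog file. `#` lines are comments.
#' @param dedup If `TRUE`, complexes with identical member sets are
#'   collapsed to the first occurrence (catalog invariant).
#' @return A list of character vectors of class `complex_list`.
#' @export
read_complexes <- function(path, dedup = FALSE) {
  cl <- read_clean_lines(path)
  sets <- lapply(cl$lines, function(l) unique(split_fields(l)))
  small <- lengths(sets) < 2L
  if (any(small)) {
    warning("dropped ", sum(small), " singleton complex line(s) in '",
            path, "'")
    sets <- sets[!small]
  }
  complex_list(sets, dedup = dedup)
}

#' Construct a complex list
#'
#' @param sets List of character vectors, each with at least two members.
#' @param dedup Collapse identical member sets?
#' @return A `complex_list` object.
#' @export
complex_list <- function(sets, dedup = FALSE) {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  stopifnot(all(lengths(sets) >= 2L))
  if (dedup && length(sets)) {
    key <- vapply(sets, function(s) paste(sort(s), collapse = "\t"), "")
    sets <- sets[!duplicated(key)]
  }
  structure(sets, class = "complex_list")
}

#' Write a complex catalog
#'
#' @param x A `complex_list` or plain list of character vectors.
#' @param path Output path.
#' @param provenance Optional character vector, one comment per complex,
#'   written as a `# ...` line above the complex.
#' @return `path`, invisibly.
#' @export
write_complexes <- function(x, path, provenance = NULL) {
  lines <- character(0)
  for (i in seq_along(x)) {
    if (!is.null(provenance)) lines <- c(lines, paste0("# ", provenance[i]))
    lines <- c(lines, paste(x[[i]], collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
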