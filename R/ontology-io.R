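GO_NAMESPACES <- c(BP = "biological_process", MF = "molecular_function",
                   CC = "cellular_component")
GAF_ASPECTS <- c(P = "BP", F = "MF", C = "CC")

#' Read a Gene Ontology file in OBO 1.2 format
#'
#' Parses `[Term]` stanzas (id, name, namespace, `is_a` parents,
#' `is_obsolete`), drops obsolete terms, splits the ontology by namespace
#' and verifies that each namespace's `is_a` graph is acyclic.
#'
#' @param path Path to an OBO file.
#' @return An object of class `go_dag`: a list with one element per aspect
#'   (`BP`, `MF`, `CC`) present in the file. Each element is a list with
#'   `terms` (character), `parents` (named list: term -> character vector of
#'   is_a parents within the same namespace) and `roots` (terms without
#'   parents).
#' @export
read_ontology <- function(path) {
  lines <- readLines(path, warn = FALSE)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0L) stop("empty ontology: no [Term] stanzas in '", path, "'")
  stanza_end <- c(term_starts[-1] - 1L, length(lines))
  ids <- character(0); ns <- character(0); parents <- list()
  for (k in seq_along(term_starts)) {
    block <- lines[term_starts[k]:stanza_end[k]]
    ## a stanza ends at the next [..] header
    hdr <- grep("^\\[", block)
    if (length(hdr) > 1L) block <- block[seq_len(hdr[2] - 1L)]
    get <- function(tag) sub(paste0("^", tag, ": *"), "", grep(paste0("^", tag, ":"), block, value = TRUE))
    if (length(grep("^is_obsolete: *true", block))) next
    id <- get("id")[1]
    nsk <- get("namespace")[1]
    if (is.na(id) || is.na(nsk)) next
    isa <- sub(" *!.*$", "", get("is_a"))
    ids <- c(ids, id); ns <- c(ns, nsk)
    parents[[id]] <- isa
  }
  if (length(ids) == 0L) stop("empty ontology: no usable terms in '", path, "'")
  out <- list()
  for (aspect in names(GO_NAMESPACES)) {
    keep <- ns == GO_NAMESPACES[[aspect]]
    if (!any(keep)) next
    terms <- ids[keep]
    par <- lapply(parents[terms], function(p) intersect(p, terms))
    names(par) <- terms
    check_acyclic(par, aspect)
    roots <- terms[lengths(par) == 0L]
    out[[aspect]] <- list(terms = terms, parents = par, roots = roots)
  }
  structure(out, class = "go_dag")
}

## Kahn's algorithm; stops with an error if the parent graph has a cycle.
check_acyclic <- function(parents, label) {
  indeg <- lengths(parents)  # edges term -> parent
  children <- list()
  for (t in names(parents)) {
    for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
  }
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in children[[t]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen != length(parents)) {
    stop("cycle detected in ", label, " ontology graph")
  }
  invisible(TRUE)
}

#' Write a minimal OBO file
#'
#' Inverse of [read_ontology()]; used by the synthetic-data generator.
#'
#' @param dag A `go_dag` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  lines <- c("format-version: 1.2", "")
  for (aspect in names(dag)) {
    o <- dag[[aspect]]
    for (t in o$terms) {
      lines <- c(lines, "[Term]", paste0("id: ", t), paste0("name: ", t),
                 paste0("namespace: ", GO_NAMESPACES[[aspect]]),
                 paste0("is_a: ", o$parents[[t]]), "")
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read protein GO annotations from a GAF 2.x file
#'
#' Uses column 2 (DB object ID) as the protein identifier, column 5 as the
#' GO term and column 9 as the aspect (`P`/`F`/`C`). Rows whose qualifier
#' (column 4) contains `NOT` are skipped. Annotations to terms absent from
#' the supplied ontology (e.g. obsolete) are dropped with a message giving
#' the count.
#'
#' @param path Path to a GAF file (`!` header lines are ignored).
#' @param dag A `go_dag` from [read_ontology()].
#' @param exclude_evidence Optional character vector of evidence codes
#'   (column 7) to drop; by default no evidence filtering is applied.
#' @return A named list with one element per aspect present in `dag`; each
#'   is a named list mapping protein ID to its set of directly annotated
#'   terms (character vector).
#' @export
read_annotations <- function(path, dag, exclude_evidence = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(!|$)", lines)]
  out <- lapply(dag, function(o) list())
  dropped <- 0L
  for (line in lines) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9L) stop("malformed GAF row (fewer than 9 columns): ", line)
    if (grepl("NOT", f[4], fixed = TRUE)) next
    if (!is.null(exclude_evidence) && length(f) >= 7L && f[7] %in% exclude_evidence) next
    aspect <- GAF_ASPECTS[[f[9]]]
    if (is.null(aspect) || is.null(dag[[aspect]])) { dropped <- dropped + 1L; next }
    if (!(f[5] %in% dag[[aspect]]$terms)) { dropped <- dropped + 1L; next }
    prot <- f[2]
    out[[aspect]][[prot]] <- union(out[[aspect]][[prot]], f[5])
  }
  if (dropped > 0L) message("dropped ", dropped, " annotation(s) to unknown or obsolete terms")
  out
}

#' Write a minimal GAF 2.2 file
#'
#' @param annotations Named list per aspect (as returned by
#'   [read_annotations()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(annotations, path) {
  aspect_code <- c(BP = "P", MF = "F", CC = "C")
  lines <- "!gaf-version: 2.2"
  for (aspect in names(annotations)) {
    ann <- annotations[[aspect]]
    for (prot in names(ann)) {
      for (term in ann[[prot]]) {
        lines <- c(lines, paste("DB", prot, prot, "", term, "REF", "IEA", "",
                                aspect_code[[aspect]], "", "", "protein",
                                "taxon:4932", "20190101", "DB", "", "",
                                sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
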