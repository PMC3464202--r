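#' Build a propagated Gene Ontology index
#'
#' Parses an OBO 1.2 ontology and a GAF 2.x annotation file, restricts
#' to one namespace, and propagates annotations up `is_a` / `part_of`
#' edges (the true-path rule): a gene annotated to a term is annotated
#' to every ancestor of that term. Obsolete terms are excluded;
#' annotations with a `NOT` qualifier are skipped.
#'
#' @param obo_path OBO 1.2 ontology file.
#' @param gaf_path GAF 2.x annotation file (gene ids taken from the
#'   DB Object ID column, falling back to the symbol column when empty).
#' @param namespace GO namespace to index (default biological_process).
#' @param exclude_iea Drop IEA (electronic) annotations.
#' @param gene_universe Optional character vector of known gene ids;
#'   annotated genes absent from it are kept but listed in
#'   `$unknown_genes`.
#' @return An object of class `go_index`: terms table, parent edges,
#'   ancestor closures, propagated `term_genes` map, and the annotated
#'   gene set.
#' @export
build_go_index <- function(obo_path, gaf_path,
                           namespace = "biological_process",
                           exclude_iea = FALSE, gene_universe = NULL) {
  obo <- parse_obo(obo_path)
  terms <- obo$terms[!obo$terms$obsolete, , drop = FALSE]
  terms <- terms[terms$namespace == namespace, , drop = FALSE]
  if (!nrow(terms)) stop("no non-obsolete terms in namespace ", namespace)
  parents <- obo$parents[terms$id]
  names(parents) <- terms$id
  parents <- lapply(parents, function(p) p[p %in% terms$id])
  anc <- ancestor_closure(parents)

  gaf <- parse_gaf(gaf_path)
  if (exclude_iea) gaf <- gaf[gaf$evidence != "IEA", , drop = FALSE]
  gaf <- gaf[gaf$term %in% terms$id, , drop = FALSE]
  if (!nrow(gaf)) stop("empty annotation set after filtering")

  ## true-path propagation, vectorised: each (gene, term) pair is
  ## replicated onto the term's ancestors
  pairs <- unique(gaf[, c("gene", "term")])
  up <- anc[pairs$term]
  all_terms <- c(pairs$term, unlist(up, use.names = FALSE))
  all_genes <- c(pairs$gene, rep(pairs$gene, lengths(up)))
  tg <- lapply(split(all_genes, all_terms), function(g) sort(unique(g)))
  genes <- sort(unique(gaf$gene))
  unknown <- if (is.null(gene_universe)) character(0) else
    setdiff(genes, gene_universe)
  structure(
    list(terms = terms, parents = parents, ancestors = anc,
         term_genes = tg, genes = genes, namespace = namespace,
         unknown_genes = unknown),
    class = "go_index"
  )
}

#' @exportS3Method base::print
print.go_index <- function(x, ...) {
  cat(sprintf("go_index: %d %s terms (%d annotated), %d genes\n",
              nrow(x$terms), x$namespace, length(x$term_genes),
              length(x$genes)))
  if (length(x$unknown_genes)) {
    cat("  ", length(x$unknown_genes),
        "annotated gene(s) absent from the gene model set\n")
  }
  invisible(x)
}

parse_obo <- function(path) {
  lines <- readLines(path)
  ## split into stanzas
  starts <- grep("^\\[", lines)
  if (!length(starts)) stop("no stanzas in OBO file ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  ids <- character(0); names_ <- character(0); ns <- character(0)
  obs <- logical(0); parents <- list()
  for (s in seq_along(starts)) {
    if (lines[starts[s]] != "[Term]") next
    block <- lines[(starts[s] + 1L):ends[s]]
    getv <- function(key) {
      v <- block[startsWith(block, paste0(key, ":"))]
      trimws(sub(paste0("^", key, ":\\s*"), "", v))
    }
    id <- getv("id")[1]
    if (is.na(id)) next
    isa <- sub("\\s*!.*$", "", getv("is_a"))
    rel <- getv("relationship")
    po <- sub("\\s*!.*$", "", sub("^part_of\\s+", "",
                                  rel[startsWith(rel, "part_of")]))
    ids <- c(ids, id)
    nm <- getv("name")[1]
    names_ <- c(names_, if (is.na(nm)) id else nm)
    nsv <- getv("namespace")[1]
    ns <- c(ns, if (is.na(nsv)) "biological_process" else nsv)
    obs <- c(obs, identical(getv("is_obsolete")[1], "true"))
    parents[[id]] <- unique(c(isa, po))
  }
  list(terms = data.frame(id = ids, name = names_, namespace = ns,
                          obsolete = obs, stringsAsFactors = FALSE),
       parents = parents)
}

## transitive closure of the parent relation; errors on cycles
ancestor_closure <- function(parents) {
  anc <- vector("list", length(parents))
  names(anc) <- names(parents)
  state <- integer(length(parents))  # 0 new, 1 in progress, 2 done
  names(state) <- names(parents)
  visit <- function(t) {
    if (state[[t]] == 1L) stop("cycle in ontology at term ", t)
    if (state[[t]] == 2L) return(anc[[t]])
    state[[t]] <<- 1L
    up <- character(0)
    for (p in parents[[t]]) {
      if (!p %in% names(parents)) next
      up <- c(up, p, visit(p))
    }
    anc[[t]] <<- unique(up)
    state[[t]] <<- 2L
    anc[[t]]
  }
  for (t in names(parents)) visit(t)
  anc
}

parse_gaf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines)) stop("empty annotation set in ", path)
  f <- strsplit(lines, "\t")
  bad <- lengths(f) < 7L
  if (any(bad)) stop("malformed GAF line ", which(bad)[1])
  gene <- vapply(f, `[[`, "", 2L)
  sym <- vapply(f, `[[`, "", 3L)
  gene <- ifelse(nzchar(gene), gene, sym)
  qual <- vapply(f, `[[`, "", 4L)
  term <- vapply(f, `[[`, "", 5L)
  ev <- vapply(f, `[[`, "", 7L)
  keep <- !grepl("(^|\\|)NOT($|\\|)", qual)
  data.frame(gene = gene[keep], term = term[keep], evidence = ev[keep],
             stringsAsFactors = FALSE)
}

#' Write an OBO / GAF pair (synthetic-annotation output)
#'
#' Minimal writers for the dialects [build_go_index()] reads.
#'
#' @param terms Data frame `id`, `name`, `namespace`, and optional
#'   list-column `parents` of `is_a` parent ids.
#' @param path Output file.
#' @export
write_obo <- function(terms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(terms))) {
    writeLines(c("", "[Term]", paste0("id: ", terms$id[i]),
                 paste0("name: ", terms$name[i]),
                 paste0("namespace: ", terms$namespace[i])), con)
    if (!is.null(terms$parents)) {
      for (p in terms$parents[[i]]) writeLines(paste0("is_a: ", p), con)
    }
  }
  invisible(path)
}

#' @param annot Data frame with columns `gene`, `term` (and optionally
#'   `evidence`, default `IDA`).
#' @rdname write_obo
#' @export
write_gaf <- function(annot, path) {
  ev <- if (is.null(annot$evidence)) rep("IDA", nrow(annot)) else
    annot$evidence
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("!gaf-version: 2.1", con)
  writeLines(paste("SYN", annot$gene, annot$gene, "", annot$term,
                   "SYN:0000", ev, "", "P", "", "", "gene", "taxon:0",
                   "20120101", "SYN", sep = "\t"), con)
  invisible(path)
}
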