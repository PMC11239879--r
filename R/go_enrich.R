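#' Ontology DAG (term parent-child structure)
#'
#' Minimal directed acyclic graph of ontology terms: child -> parent
#' (`is_a`) edges plus one namespace per term (e.g. `"BP"`, `"CC"`).
#'
#' @param parents named list mapping each term id to a character vector of
#'   its direct parents (possibly empty).
#' @param namespace named character vector mapping each term id to its
#'   namespace.
#' @return an object of class `ontology_dag`.
#' @export
ontology_dag <- function(parents, namespace) {
  terms <- names(parents)
  if (is.null(terms) || any(!nzchar(terms)))
    stopf("`parents` must be a named list keyed by term id")
  allp <- unlist(parents, use.names = FALSE)
  if (length(allp) && !all(allp %in% terms))
    stopf("edge endpoints missing from the term set: %s",
          paste(head(setdiff(allp, terms), 3L), collapse = ", "))
  if (!all(terms %in% names(namespace)))
    stopf("every term needs a namespace")
  namespace <- namespace[terms]
  ## Kahn topological sort doubles as the cycle check
  indeg <- setNames(integer(length(terms)), terms)
  for (t in terms) for (p in parents[[t]]) indeg[[p]] <- indeg[[p]] + 1L
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  topo <- character(length(terms))
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    topo[seen] <- t
    for (p in parents[[t]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (seen != length(terms)) stopf("ontology contains a cycle")
  structure(list(parents = parents, namespace = namespace,
                 topo_children_first = topo),
            class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("<ontology_dag> %d terms (%s)\n", length(x$parents),
              paste(sprintf("%s: %d", names(table(x$namespace)),
                            table(x$namespace)), collapse = ", ")))
  invisible(x)
}

#' Read an ontology from a term-parent TSV edge list
#'
#' Expected columns: `term`, `parent` (empty parent for roots),
#' `namespace`.
#'
#' @param path TSV path.
#' @return an [ontology_dag()].
#' @export
read_ontology_edges <- function(path) {
  df <- read.delim(path, colClasses = "character")
  need <- c("term", "parent", "namespace")
  if (!all(need %in% names(df)))
    stopf("edge list needs columns: %s", paste(need, collapse = ", "))
  terms <- unique(df$term)
  parents <- lapply(setNames(terms, terms), function(t)
    setdiff(df$parent[df$term == t], ""))
  ns <- setNames(df$namespace[match(terms, df$term)], terms)
  ontology_dag(parents, ns)
}

#' Read a minimal OBO subset
#'
#' Parses only `[Term]` stanzas with their `id`, `namespace` and `is_a`
#' fields; everything else (other relationship types, obsolete handling) is
#' ignored. Namespaces `biological_process` / `cellular_component` /
#' `molecular_function` are abbreviated to BP / CC / MF.
#'
#' @param path OBO file path.
#' @return an [ontology_dag()].
#' @export
read_obo_minimal <- function(path) {
  lines <- readLines(path)
  parents <- list()
  ns <- character()
  id <- NULL
  in_term <- FALSE
  flush <- function() {}
  for (ln in c(lines, "[Term]")) {
    if (startsWith(ln, "[")) {
      in_term <- identical(ln, "[Term]")
      id <- NULL
      next
    }
    if (!in_term) next
    if (startsWith(ln, "id: ")) {
      id <- sub("^id: ", "", ln)
      parents[[id]] <- character()
      ns[[id]] <- NA_character_
    } else if (!is.null(id) && startsWith(ln, "namespace: ")) {
      v <- sub("^namespace: ", "", ln)
      ns[[id]] <- switch(v, biological_process = "BP",
                         cellular_component = "CC",
                         molecular_function = "MF", v)
    } else if (!is.null(id) && startsWith(ln, "is_a: ")) {
      p <- sub("\\s*!.*$", "", sub("^is_a: ", "", ln))
      parents[[id]] <- c(parents[[id]], p)
    }
  }
  if (any(is.na(ns))) ns[is.na(ns)] <- "BP"
  ontology_dag(parents, ns)
}

## full ancestor sets (excluding the term itself), children-first dynamic
## programme over the topological order
term_ancestors <- function(dag) {
  anc <- setNames(vector("list", length(dag$parents)), names(dag$parents))
  ## process parents before children: reverse of the children-first order
  for (t in rev(dag$topo_children_first)) {
    ps <- dag$parents[[t]]
    anc[[t]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  anc
}

#' Close gene annotations under the true-path rule
#'
#' A gene annotated to a term is implicitly annotated to all of that term's
#' ancestors; this closes each gene's direct annotation set under ancestry.
#'
#' @param dag an [ontology_dag()].
#' @param annotations data.frame with columns `gene`, `term` (direct
#'   annotations), or a named list gene -> terms.
#' @return named list gene -> character vector of annotated terms (direct
#'   terms plus all ancestors).
#' @export
propagate_annotations <- function(dag, annotations) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (is.data.frame(annotations))
    annotations <- split(annotations$term, annotations$gene)
  bad <- setdiff(unique(unlist(annotations, use.names = FALSE)),
                 names(dag$parents))
  if (length(bad))
    stopf("annotation to unknown term(s): %s",
          paste(head(bad, 3L), collapse = ", "))
  anc <- term_ancestors(dag)
  lapply(annotations, function(ts) {
    ts <- unique(ts)
    sort(unique(c(ts, unlist(anc[ts], use.names = FALSE))))
  })
}

#' Fisher-exact term enrichment
#'
#' For every term of the requested namespace annotated to at least one
#' background gene, builds the 2x2 table (in study / not) x (annotated /
#' not) and reports the one-sided (enrichment) Fisher exact p-value
#' together with the sample odds ratio
#' `(k / (n - k)) / ((K - k) / (N - K - n + k))` (infinite when a
#' denominator cell is empty). The background is the full protein universe
#' of the analysis.
#'
#' @param study_set character vector of study genes (e.g. the Tier 1 set);
#'   must be non-empty and a subset of `background_set`.
#' @param background_set character vector of background genes.
#' @param annotations propagated annotation list from
#'   [propagate_annotations()].
#' @param dag an [ontology_dag()].
#' @param namespace namespace to test (e.g. `"BP"` or `"CC"`).
#' @param two_sided use the two-sided Fisher test instead of the one-sided
#'   enrichment test.
#' @return data.frame with columns `term`, `k`, `K`, `n`, `N`,
#'   `odds_ratio`, `fisher_p`, sorted by term id.
#' @export
fisher_enrich <- function(study_set, background_set, annotations, dag,
                          namespace, two_sided = FALSE) {
  stopifnot(inherits(dag, "ontology_dag"))
  study_set <- unique(study_set)
  background_set <- unique(background_set)
  if (length(study_set) == 0L) stopf("empty study set")
  if (!all(study_set %in% background_set))
    stopf("study set must be a subset of the background")
  ns_terms <- names(dag$namespace)[dag$namespace == namespace]
  n <- length(study_set)
  N <- length(background_set)
  ann_bg <- annotations[intersect(names(annotations), background_set)]
  term_genes <- split(rep(names(ann_bg), lengths(ann_bg)),
                      unlist(ann_bg, use.names = FALSE))
  term_genes <- term_genes[intersect(names(term_genes), ns_terms)]
  if (length(term_genes) == 0L)
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), odds_ratio = numeric(),
                      fisher_p = numeric()))
  rows <- lapply(sort(names(term_genes)), function(tm) {
    g <- term_genes[[tm]]
    K <- length(g)
    k <- sum(g %in% study_set)
    a <- k; b <- n - k; c_ <- K - k; d <- N - K - n + k
    or <- if (b == 0L && d == 0L) 1  # degenerate margin: all genes annotated
    else if (b == 0L || c_ == 0L) Inf
    else (a * d) / (b * c_)
    p <- fisher.test(matrix(c(a, b, c_, d), 2L),
                     alternative = if (two_sided) "two.sided" else "greater")$p.value
    data.frame(term = tm, k = k, K = K, n = n, N = N, odds_ratio = or,
               fisher_p = p)
  })
  do.call(rbind, rows)
}

#' Rank enriched terms and prune ancestral redundancy
#'
#' Within one namespace: corrects the Fisher p-values (Benjamini-Hochberg
#' by default; `adjust = "none"` keeps raw p), keeps terms with corrected
#' p < `alpha`, sorts by odds ratio (descending; ties by p ascending, then
#' term id), truncates to the top `top_n`, and finally drops every retained
#' term that is an ancestor of another retained term, so that only the most
#' specific term of each lineage survives.
#'
#' @param rows output of [fisher_enrich()] for one namespace.
#' @param dag an [ontology_dag()].
#' @param top_n maximum number of terms kept before pruning (default 30).
#' @param alpha significance cut on the (corrected) p-value (default 0.05,
#'   strict).
#' @param adjust `"BH"` (default) or `"none"`.
#' @return the selected rows (at most `top_n`), with columns `p_adj` and
#'   `retained` (FALSE for pruned ancestors), in ranking order.
#' @export
rank_and_prune <- function(rows, dag, top_n = 30L, alpha = 0.05,
                           adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  rows$p_adj <- if (adjust == "BH") p.adjust(rows$fisher_p, "BH")
               else rows$fisher_p
  sel <- rows[rows$p_adj < alpha, , drop = FALSE]
  if (nrow(sel) == 0L) {
    sel$retained <- logical(0)
    return(sel)
  }
  ord <- order(-sel$odds_ratio, sel$fisher_p, sel$term)
  sel <- sel[ord, , drop = FALSE]
  sel <- head(sel, top_n)
  anc <- term_ancestors(dag)
  kept <- sel$term
  is_ancestor <- vapply(kept, function(tm)
    any(vapply(setdiff(kept, tm), function(o) tm %in% anc[[o]], NA)), NA)
  sel$retained <- !is_ancestor
  rownames(sel) <- NULL
  sel
}
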