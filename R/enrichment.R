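#' GO term enrichment of a candidate gene set
#'
#' Per term, the hypergeometric upper-tail p-value for the overlap between
#' the candidate set and the term's gene set within the annotated
#' universe; a term is enriched at p < \code{alpha} (the term-level
#' threshold used throughout the pipeline).
#'
#' @param candidates character vector of candidate gene ids (must be a
#'   subset of the universe).
#' @param terms GO term list as from \code{\link{go_terms}}.
#' @param universe gene universe (default: union of all term gene sets).
#' @param alpha term-level threshold (default 0.05).
#' @return object of class \code{enrichment_report} with a per-term table.
#' @export
term_enrichment <- function(candidates, terms,
                            universe = sort(unique(unlist(lapply(terms, `[[`, "genes")))),
                            alpha = 0.05) {
  candidates <- unique(as.character(candidates))
  if (!length(candidates)) stop("empty candidate set")
  extra <- setdiff(candidates, universe)
  if (length(extra)) stop("candidates outside the annotated universe: ",
                          paste(utils::head(extra, 5), collapse = ", "))
  N <- length(universe)
  n <- length(candidates)
  tab <- do.call(rbind, lapply(terms, function(tm) {
    gs <- intersect(tm$genes, universe)
    k <- length(intersect(gs, candidates))
    # upper tail including the observed overlap
    p <- stats::phyper(k - 1, length(gs), N - length(gs), n, lower.tail = FALSE)
    data.frame(term_id = tm$term_id, name = tm$name, term_size = length(gs),
               overlap = k, p = p, stringsAsFactors = FALSE)
  }))
  tab$enriched <- tab$p < alpha
  rownames(tab) <- NULL
  structure(list(table = tab, level = "term", alpha = alpha,
                 candidates = candidates, universe_size = N),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("enrichment_report (%s level): %d rows, %d significant\n",
              x$level, nrow(x$table),
              sum(x$table[[if (x$level == "term") "enriched" else "significant"]])))
  invisible(x)
}

#' Assign GO terms to flight-relevant functional categories
#'
#' A term joins a category iff any of the category's keywords matches
#' (case-insensitive substring; word-boundary mode available) against the
#' term name or definition. Multi-category membership is allowed; terms
#' matching nothing stay uncategorized ("n/a"). The mapping is
#' deterministic and blind to which analysis produced the term.
#'
#' @param terms GO term list (with name/definition) or a character vector
#'   of term ids indexing \code{defs}.
#' @param scheme a \code{\link{category_scheme}}.
#' @param word_boundary require keyword matches at word boundaries.
#' @return named list: term_id -> character vector of category names
#'   (possibly empty).
#' @export
categorize_terms <- function(terms, scheme, word_boundary = FALSE) {
  out <- lapply(terms, function(tm) {
    txt <- tolower(paste(tm$name, tm$definition))
    hits <- names(scheme)[vapply(scheme, function(kws) {
      any(vapply(kws, function(k) {
        if (word_boundary) grepl(paste0("\\b", k, "\\b"), txt, perl = TRUE)
        else grepl(k, txt, fixed = TRUE)
      }, logical(1)))
    }, logical(1))]
    hits
  })
  names(out) <- vapply(terms, `[[`, "", "term_id")
  out
}

#' Category over-representation by one-tailed binomial tests
#'
#' For each category the null proportion p0 is its share of the reference
#' (whole-annotation) term set; the observed count is how many of the n
#' enriched terms fall in the category (unique terms; a term in several
#' categories counts once per category). The one-tailed upper p-value
#' P(Binomial(n, p0) >= k) is BH-adjusted across the categories of the
#' scheme (FDR 5% by default).
#'
#' @param enriched_categories categorization (from
#'   \code{\link{categorize_terms}}) of the enriched terms.
#' @param reference_categories categorization of the reference term set.
#' @param scheme the \code{category_scheme} used for both.
#' @param fdr adjusted-p significance level (default 0.05).
#' @return an \code{enrichment_report} at category level.
#' @export
category_overrepresentation <- function(enriched_categories,
                                        reference_categories, scheme,
                                        fdr = 0.05) {
  n <- length(enriched_categories)
  n_ref <- length(reference_categories)
  cats <- names(scheme)
  count_in <- function(catz, cat) sum(vapply(catz, function(h) cat %in% h, logical(1)))
  tab <- do.call(rbind, lapply(cats, function(cat) {
    k <- count_in(enriched_categories, cat)
    kr <- count_in(reference_categories, cat)
    p0 <- kr / n_ref
    degenerate <- (p0 == 0 && k > 0)
    p <- if (p0 == 0) as.numeric(k > 0) * 0 + as.numeric(k == 0) else
      stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
    data.frame(category = cat, observed = k, n = n,
               background_count = kr, background_prop = p0,
               p = p, degenerate = degenerate, stringsAsFactors = FALSE)
  }))
  tab$p_adj <- adjust_p(tab$p)
  tab$significant <- tab$p_adj < fdr
  rownames(tab) <- NULL
  structure(list(table = tab, level = "category", alpha = fdr),
            class = "enrichment_report")
}

#' Build the enriched-term overlap graph
#'
#' Nodes are enriched terms; edge weight is the overlap coefficient
#' |A intersect B| / min(|A|, |B|) of their gene sets; edges below the
#' threshold are omitted.
#'
#' @param terms GO term list restricted to the enriched terms.
#' @param threshold minimum overlap coefficient for an edge (default 0.5).
#' @return list(nodes, adjacency): symmetric weighted adjacency matrix.
#' @export
build_term_graph <- function(terms, threshold = 0.5) {
  ids <- vapply(terms, `[[`, "", "term_id")
  k <- length(terms)
  A <- matrix(0, k, k, dimnames = list(ids, ids))
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      gi <- terms[[i]]$genes; gj <- terms[[j]]$genes
      w <- length(intersect(gi, gj)) / min(length(gi), length(gj))
      if (w >= threshold) A[i, j] <- A[j, i] <- w
    }
  }
  list(nodes = ids, adjacency = A)
}

#' Markov clustering (MCL) of a weighted graph
#'
#' Standard MCL: self-loops are added at the maximum incident weight,
#' columns are normalised to a stochastic matrix, and expansion (matrix
#' squaring) alternates with inflation (elementwise power and
#' renormalisation), pruning entries below 1e-6, until the maximum column
#' change falls below 1e-8 or 200 iterations elapse (the current
#' clustering is returned with a warning at the cap). Clusters are the
#' connected components of the converged attractor structure; singletons
#' are allowed, the clusters partition the node set, and the result does
#' not depend on node order.
#'
#' @param graph list(nodes, adjacency) as from
#'   \code{\link{build_term_graph}}.
#' @param inflation inflation exponent, > 1 (default 2).
#' @param max_iter,tol,prune iteration controls.
#' @return list of character vectors of node ids (the clusters).
#' @export
mcl_cluster <- function(graph, inflation = 2.0, max_iter = 200,
                        tol = 1e-8, prune = 1e-6) {
  A <- graph$adjacency
  n <- nrow(A)
  if (n == 0) stop("empty graph")
  if (inflation <= 1) stop("inflation must exceed 1")
  if (n == 1) return(list(graph$nodes))
  loop <- apply(A, 2, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  norm_cols <- function(M) sweep(M, 2, colSums(M), "/")
  M <- norm_cols(A)
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M          # expansion
    M2 <- M2^inflation     # inflation
    M2[M2 < prune] <- 0
    M2 <- norm_cols(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
  }
  if (delta >= tol) warning("MCL did not converge within the iteration cap")
  # attractor structure: treat remaining mass as undirected support and
  # take connected components
  S <- (M > prune) | t(M > prune)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    cid <- cid + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[u])) next
      comp[u] <- cid
      queue <- c(queue, which(S[u, ] & is.na(comp)))
    }
  }
  unname(split(graph$nodes, comp))
}

DEFAULT_STOPWORDS <- c(
  "a", "an", "and", "are", "as", "at", "be", "by", "for", "from", "in",
  "into", "is", "it", "its", "of", "on", "or", "that", "the", "this",
  "to", "via", "with", "which", "other", "involved", "any", "not", "process")

#' Descriptors and support tallies for term clusters
#'
#' Each cluster's descriptor is the four most common non-stopword,
#' lower-cased tokens across its member term definitions (ties broken by
#' frequency then alphabetically; fewer than four if the vocabulary is
#' exhausted). Category hit counts tally member terms per category; gene
#' support is the min-max range of supporting genes per member term. A
#' cluster is flagged well-supported if it receives 10 or more category
#' hits and/or support from 5 or more unique genes.
#'
#' @param clusters list of term-id vectors (from
#'   \code{\link{mcl_cluster}}).
#' @param terms full GO term list (for definitions and gene sets).
#' @param categorization term -> categories map (from
#'   \code{\link{categorize_terms}}).
#' @param candidates optional candidate gene ids; when given, per-term
#'   supporting genes are the term's candidate genes, else all its genes.
#' @param stopwords stopword list (GO boilerplate removal is minimal:
#'   tokens like "regulation" are kept).
#' @return data.frame, one row per cluster, with descriptor, category
#'   hits, gene support range and the well-supported flag.
#' @export
describe_clusters <- function(clusters, terms, categorization,
                              candidates = NULL,
                              stopwords = DEFAULT_STOPWORDS) {
  rows <- lapply(seq_along(clusters), function(ci) {
    ids <- clusters[[ci]]
    mem <- terms[ids]
    toks <- unlist(lapply(mem, function(tm) {
      tk <- strsplit(tolower(tm$definition), "[^a-z0-9]+")[[1]]
      tk[nchar(tk) > 0 & !(tk %in% stopwords)]
    }))
    freq <- sort(table(toks), decreasing = TRUE)
    if (length(freq)) {
      ord <- order(-as.integer(freq), names(freq))
      descr <- names(freq)[ord][seq_len(min(4, length(freq)))]
    } else descr <- character(0)
    cat_hits <- table(unlist(categorization[ids]))
    n_hits <- sum(cat_hits)
    support <- vapply(mem, function(tm) {
      g <- if (is.null(candidates)) tm$genes else intersect(tm$genes, candidates)
      length(g)
    }, integer(1))
    uniq_genes <- length(unique(unlist(lapply(mem, function(tm) {
      if (is.null(candidates)) tm$genes else intersect(tm$genes, candidates)
    }))))
    data.frame(
      cluster = ci,
      descriptor = paste(descr, collapse = ", "),
      n_terms = length(ids),
      category_hits = n_hits,
      categories = if (length(cat_hits)) {
        paste(sprintf("%s (%d)", names(cat_hits), as.integer(cat_hits)),
              collapse = "; ")
      } else "n/a",
      gene_support_min = if (length(support)) min(support) else 0L,
      gene_support_max = if (length(support)) max(support) else 0L,
      unique_genes = uniq_genes,
      well_supported = n_hits >= 10 || uniq_genes >= 5,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
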