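#' Build an annotation collection
#'
#' @param terms named list of character vectors (term -> member proteins).
#' @param background character vector of all assayed proteins; every term is
#'   intersected with it. Defaults to the union of all term members.
#' @param category optional named character of term categories (e.g.
#'   immune-inflammatory / cell-cell signaling / metabolic / other).
#' @return list of class `annotationCollection`.
#' @export
annotationCollection <- function(terms, background = NULL, category = NULL) {
  if (!length(terms) || is.null(names(terms)))
    stop("terms must be a non-empty named list", call. = FALSE)
  background <- unique(background %||% unlist(terms, use.names = FALSE))
  terms <- lapply(terms, function(m) unique(intersect(m, background)))
  terms <- terms[lengths(terms) > 0]
  if (!length(terms))
    stop("no term overlaps the background", call. = FALSE)
  cat <- setNames(rep("other", length(terms)), names(terms))
  if (!is.null(category)) {
    hit <- intersect(names(category), names(terms))
    cat[hit] <- category[hit]
  }
  structure(list(terms = terms, background = background, category = cat),
            class = "annotationCollection")
}

#' Read gene sets from a GMT file
#'
#' Sets are parsed with [fgsea::gmtPathways()]; the GMT description field
#' (second column) is kept as the term's category label.
#'
#' @param path path to the GMT file.
#' @param background optional background protein set (defaults to the union
#'   of all members).
#' @return an [annotationCollection()].
#' @export
readGMT <- function(path, background = NULL) {
  terms <- fgsea::gmtPathways(path)
  desc <- vapply(strsplit(readLines(path), "\t"), `[`, "", 2L)
  names(desc) <- names(terms)
  annotationCollection(terms, background = background, category = desc)
}

#' Hypergeometric over-representation analysis
#'
#' For every annotation term with at least one query hit, computes the fold
#' enrichment `(k/n) / (K/N)` and the exact one-sided hypergeometric upper
#' tail `P[X >= k]` for `k` query hits out of a query of size `n`, a term of
#' size `K` and a background of size `N`. P-values are Benjamini-Hochberg
#' adjusted across the tested (k >= 1) terms; terms with `fdr < alpha` are
#' flagged significant.
#'
#' @param query character vector of proteins, a subset of the background.
#' @param collection an [annotationCollection()].
#' @param alpha FDR threshold for the significance flag.
#' @return data.frame ordered by p: `term`, `category`, `k`, `n`, `K`, `N`,
#'   `fold_enrichment`, `p`, `fdr`, `significant`.
#' @export
enrich <- function(query, collection, alpha = 0.05) {
  stopifnot(inherits(collection, "annotationCollection"))
  query <- unique(query)
  if (!length(query)) stop("query is empty", call. = FALSE)
  out <- setdiff(query, collection$background)
  if (length(out))
    stop("query proteins outside the background: ",
         paste(out, collapse = ", "), call. = FALSE)
  N <- length(collection$background)
  n <- length(query)
  rows <- lapply(names(collection$terms), function(tm) {
    members <- collection$terms[[tm]]
    k <- length(intersect(query, members))
    if (k == 0) return(NULL)
    K <- length(members)
    data.frame(term = tm, category = unname(collection$category[tm]),
               k = k, n = n, K = K, N = N,
               fold_enrichment = (k / n) / (K / N),
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(term = character(0), category = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), fold_enrichment = numeric(0),
                      p = numeric(0), fdr = numeric(0),
                      significant = logical(0)))
  res$fdr <- bhFDR(res$p)
  res$significant <- res$fdr < alpha
  res[order(res$p, res$term), , drop = FALSE]
}

#' Tally significant terms per category
#'
#' @param enrichment data.frame from [enrich()].
#' @return data.frame `category`, `n_significant`.
#' @export
categoryTally <- function(enrichment) {
  sig <- enrichment[enrichment$significant, , drop = FALSE]
  tab <- table(sig$category)
  data.frame(category = names(tab), n_significant = as.integer(tab))
}
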