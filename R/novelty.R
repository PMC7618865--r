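#' k-nearest-neighbour novelty score on embedding vectors
#'
#' Density-based anomaly score for a domain embedding relative to a
#' reference set of known-domain embeddings. The raw statistic is the
#' Euclidean distance to the k-th nearest reference; it is calibrated to
#' `[0, 100]` through the right-continuous empirical CDF of the
#' references' own leave-one-out k-NN distances, so a domain farther
#' from the reference density than every reference is from its own
#' scores 100 ("close to 100" means novel) and a domain inside the
#' density scores near 0.
#'
#' @param query numeric embedding vector (or list with `domain_id` and
#'   `vector`).
#' @param refs numeric matrix of reference embeddings, one row each
#'   (rownames are ids); must share the query's dimensionality and have
#'   more than `k` rows.
#' @param k neighbour rank (default 5).
#' @return object of class `novelty_score`: `domain_id`, `score` in
#'   `[0, 100]` and `knn_dist`.
#' @export
knn_novelty <- function(query, refs, k = 5) {
  domain_id <- NA_character_
  if (is.list(query) && !is.null(query$vector)) {
    domain_id <- query$domain_id %||% NA_character_
    query <- query$vector
  }
  query <- as.numeric(query)
  refs <- as.matrix(refs)
  if (ncol(refs) != length(query))
    stop("embedding dimensionality mismatch: query ", length(query),
         ", references ", ncol(refs))
  if (k < 1L || k >= nrow(refs))
    stop("need 1 <= k < number of references")
  d_query <- sqrt(rowSums(sweep(refs, 2, query)^2))
  knn_dist <- unname(sort(d_query)[k])
  ref_knn <- ref_loo_knn(refs, k)
  score <- 100 * ecdf(ref_knn)(knn_dist)
  structure(list(domain_id = domain_id, score = score, knn_dist = knn_dist),
            class = "novelty_score")
}

# Leave-one-out k-NN distance of every reference to the other references.
ref_loo_knn <- function(refs, k) {
  dm <- as.matrix(stats::dist(refs))
  diag(dm) <- Inf
  apply(dm, 1, function(row) sort(row)[k])
}

#' Route a structure by internal symmetry
#'
#' High-symmetry structures (repeat architectures such as beta
#' propellers and extruded repeats) are sequestered into their own
#' category before novelty ranking: a symmetry Z-score strictly greater
#' than `z_min` routes to the repeat category.
#'
#' @param sym a `symmetry_result` from [symmetry_scan()] or a bare
#'   Z-score.
#' @param z_min gate threshold (default 9, strict inequality).
#' @return "repeat_category" or "novel_candidate".
#' @export
symmetry_gate <- function(sym, z_min = 9) {
  z <- if (inherits(sym, "symmetry_result")) sym$zscore else as.numeric(sym)
  if (!is.na(z) && z > z_min) "repeat_category" else "novel_candidate"
}

#' Triage unlabelled cluster representatives
#'
#' Routes each representative of an unlabelled cluster to exactly one
#' bin: non-globular (poor quality) choppings are discarded first, then
#' high-symmetry structures are sequestered as repeats, and the
#' remainder are ranked as novel candidates with a k-NN novelty score.
#'
#' @param reps list of records, each with `domain_id`, `zscore` (or a
#'   `symmetry_result` as `sym`), `globularity` and `embedding`.
#' @param refs reference embedding matrix, see [knn_novelty()].
#' @param k neighbour rank for the novelty score (default 5).
#' @param z_min symmetry gate (default 9).
#' @param glob_max globularity threshold above which a chopping is
#'   discarded as poor quality (default 1.5).
#' @return data.frame with one row per representative: `domain_id`,
#'   `route` ("discarded_poor_quality", "repeat_category",
#'   "novel_candidate"), `globularity`, `zscore`, `novelty_score`,
#'   `knn_dist` (scores NA outside the novel bin).
#' @export
triage_unlabelled <- function(reps, refs, k = 5, z_min = 9, glob_max = 1.5) {
  rows <- lapply(reps, function(rep) {
    z <- if (!is.null(rep$sym)) rep$sym$zscore else rep$zscore
    out <- data.frame(domain_id = rep$domain_id, route = NA_character_,
                      globularity = rep$globularity, zscore = z,
                      novelty_score = NA_real_, knn_dist = NA_real_,
                      stringsAsFactors = FALSE)
    if (rep$globularity > glob_max) {
      out$route <- "discarded_poor_quality"
    } else if (symmetry_gate(z, z_min) == "repeat_category") {
      out$route <- "repeat_category"
    } else {
      ns <- knn_novelty(rep$embedding, refs, k)
      out$route <- "novel_candidate"
      out$novelty_score <- ns$score
      out$knn_dist <- ns$knn_dist
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
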