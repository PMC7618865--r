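#' Intersection-over-union of two residue sets
#'
#' The agreement measure used to decide whether two segmentation methods
#' identified "the same" domain.
#'
#' @param a,b nonempty integer vectors of residue numbers.
#' @return `|a n b| / |a u b|` in `[0, 1]`.
#' @export
domain_iou <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("domain_iou requires nonempty residue sets")
  a <- unique(a); b <- unique(b)
  length(intersect(a, b)) / length(union(a, b))
}

# IoU matrix between the domains of two choppings.
iou_matrix <- function(res_x, res_y) {
  outer(seq_along(res_x), seq_along(res_y),
        Vectorize(function(i, j) domain_iou(res_x[[i]], res_y[[j]])))
}

#' Match the domains of two choppings
#'
#' Finds the one-to-one assignment of domains between two choppings that
#' maximises total IoU, restricted to pairs with IoU at or above
#' `iou_min`. Ties are broken deterministically in favour of the
#' lexicographically smallest pair set. Exact search is used up to 8
#' domains per chopping; beyond that a greedy descent on IoU is used.
#'
#' @param x,y `chopping` objects on the same chain.
#' @param iou_min minimum IoU for two domains to count as matched.
#' @return data.frame with columns `i` (domain index in `x`), `j` (index
#'   in `y`) and `iou`; zero rows if nothing matches.
#' @export
match_choppings <- function(x, y, iou_min = 0.7) {
  res_x <- chopping_residues(x)
  res_y <- chopping_residues(y)
  empty <- data.frame(i = integer(0), j = integer(0), iou = numeric(0))
  if (length(res_x) == 0L || length(res_y) == 0L) return(empty)
  iou <- iou_matrix(res_x, res_y)
  allowed <- iou >= iou_min
  if (!any(allowed)) return(empty)

  if (min(dim(iou)) <= 8L) {
    best <- list(total = -Inf, pairs = NULL)
    used <- rep(FALSE, ncol(iou))
    pairs <- matrix(NA_integer_, nrow = nrow(iou), ncol = 2)
    # branch-and-bound upper bound: best per-row IoU among allowed pairs
    row_max <- apply(iou * allowed, 1, max)
    tail_bound <- rev(cumsum(rev(row_max)))
    recurse <- function(i, npair, total) {
      if (i > nrow(iou)) {
        if (total > best$total + 1e-12)
          best <<- list(total = total,
                        pairs = pairs[seq_len(npair), , drop = FALSE])
        return(invisible())
      }
      if (total + tail_bound[i] <= best$total + 1e-12) return(invisible())
      for (j in seq_len(ncol(iou))) {
        if (allowed[i, j] && !used[j]) {
          used[j] <<- TRUE
          pairs[npair + 1L, ] <<- c(i, j)
          recurse(i + 1L, npair + 1L, total + iou[i, j])
          used[j] <<- FALSE
        }
      }
      recurse(i + 1L, npair, total)  # leave domain i unmatched
    }
    recurse(1L, 0L, 0)
    if (is.null(best$pairs) || nrow(best$pairs) == 0L) return(empty)
    out <- data.frame(i = best$pairs[, 1], j = best$pairs[, 2])
  } else {
    ord <- order(-iou[allowed],
                 row(iou)[allowed], col(iou)[allowed])
    cand <- cbind(row(iou)[allowed], col(iou)[allowed])[ord, , drop = FALSE]
    used_i <- rep(FALSE, nrow(iou)); used_j <- rep(FALSE, ncol(iou))
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!used_i[i] && !used_j[j]) {
        keep[k] <- TRUE; used_i[i] <- TRUE; used_j[j] <- TRUE
      }
    }
    out <- data.frame(i = cand[keep, 1], j = cand[keep, 2])
  }
  out <- out[order(out$i), , drop = FALSE]
  out$iou <- iou[cbind(out$i, out$j)]
  rownames(out) <- NULL
  out
}

# One consensus domain: residue set plus provenance.
consensus_domain <- function(residues, confidence, supporting_methods,
                             avg_plddt = NA_real_) {
  residues <- sort(unique(as.integer(residues)))
  stopifnot(length(residues) > 0L, confidence %in% c("high", "medium"))
  structure(list(residues = residues,
                 segments = segments_from_residues(residues),
                 confidence = confidence,
                 supporting_methods = sort(supporting_methods),
                 avg_plddt = avg_plddt),
            class = "consensus_domain")
}

consensus_result <- function(chain_id, domains, ndr_residues) {
  all_dom <- unlist(lapply(domains, `[[`, "residues"))
  if (anyDuplicated(all_dom))
    stop("consensus domains overlap at residue ",
         all_dom[duplicated(all_dom)][1])
  structure(list(chain_id = chain_id, domains = domains,
                 ndr_residues = sort(unique(as.integer(ndr_residues)))),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result %s: %d domain(s), %d NDR residue(s)>\n",
              x$chain_id, length(x$domains), length(x$ndr_residues)))
  for (d in x$domains)
    cat(sprintf("  %-6s %s (%d residues; %s)\n", d$confidence,
                format_chopping(chopping(list(d$segments))),
                length(d$residues),
                paste(d$supporting_methods, collapse = "+")))
  invisible(x)
}

#' Consensus domain assignment from three segmentation methods
#'
#' Merges three per-method choppings of one chain into consensus domains.
#' Domains are grouped across methods by maximum-IoU matching; a group
#' supported by all three methods is a high-confidence domain, a group
#' supported by exactly two is medium. Within a group the consensus
#' residue set is a per-residue vote: a residue is kept if at least two of
#' a high group's three domains contain it, or both domains of a medium
#' group. Voted groups shorter than `min_len` residues are discarded.
#' Residues in no kept consensus domain are non-domain residues (NDR).
#'
#' If two pairwise matches share a domain but the implied third match is
#' absent (failed transitivity), the pair with the larger IoU forms a
#' medium group and the remaining domain is left unmatched.
#'
#' @param m1,m2,m3 `chopping` objects for the same chain.
#' @param iou_min domain agreement threshold (default 0.7).
#' @param min_len minimum consensus domain size in residues (default 25).
#' @param chain optional [residue_chain()]; supplies the full residue set
#'   (for the NDR complement) and per-domain mean plDDT.
#' @param chain_id identifier used when `chain` is absent.
#' @return a `consensus_result`: consensus domains plus the NDR set.
#' @export
consensus_assign <- function(m1, m2, m3, iou_min = 0.7, min_len = 25,
                             chain = NULL, chain_id = "") {
  chops <- list(m1, m2, m3)
  res <- lapply(chops, chopping_residues)
  all_res <- sort(unique(unlist(res)))
  if (!is.null(chain)) {
    chain_id <- chain$chain_id
    missing <- setdiff(all_res, chain$residue_numbers)
    if (length(missing) > 0L)
      stop("chopping residues absent from chain: ",
           paste(utils::head(missing, 5), collapse = ", "))
    chain_residues <- chain$residue_numbers
  } else chain_residues <- all_res

  matchings <- list(
    `12` = match_choppings(chops[[1]], chops[[2]], iou_min),
    `13` = match_choppings(chops[[1]], chops[[3]], iou_min),
    `23` = match_choppings(chops[[2]], chops[[3]], iou_min))

  # Triples: i~j (1,2), i~k (1,3), j~k (2,3) mutually consistent.
  triples <- list()
  m12 <- matchings[["12"]]; m13 <- matchings[["13"]]; m23 <- matchings[["23"]]
  drop12 <- logical(nrow(m12)); drop13 <- logical(nrow(m13)); drop23 <- logical(nrow(m23))
  for (r in seq_len(nrow(m12))) {
    i <- m12$i[r]; j <- m12$j[r]
    r13 <- which(m13$i == i); r23 <- which(m23$i == j)
    if (length(r13) == 1L && length(r23) == 1L && m13$j[r13] == m23$j[r23]) {
      triples[[length(triples) + 1L]] <- c(i, j, m13$j[r13])
      drop12[r] <- TRUE; drop13[r13] <- TRUE; drop23[r23] <- TRUE
    }
  }

  # Remaining pairs compete greedily by IoU for medium groups.
  tag_mp <- function(mp, df) {
    df <- df[, c("i", "j", "iou"), drop = FALSE]
    df$mp <- rep(mp, nrow(df))
    df
  }
  leftover <- rbind(tag_mp(1L, m12[!drop12, , drop = FALSE]),
                    tag_mp(2L, m13[!drop13, , drop = FALSE]),
                    tag_mp(3L, m23[!drop23, , drop = FALSE]))
  mp_methods <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  pairs <- list()
  if (nrow(leftover) > 0L) {
    # ties in IoU are broken on the first residues of the two domains
    # (content-based, hence invariant to the order of the input methods)
    start_of <- function(m, d) res[[m]][[d]][1]
    s1 <- mapply(function(mp, i) start_of(mp_methods[[mp]][1], i),
                 leftover$mp, leftover$i)
    s2 <- mapply(function(mp, j) start_of(mp_methods[[mp]][2], j),
                 leftover$mp, leftover$j)
    leftover <- leftover[order(-leftover$iou, pmin(s1, s2), pmax(s1, s2),
                               leftover$mp, leftover$i, leftover$j), ,
                         drop = FALSE]
    used <- matrix(FALSE, nrow = 3, ncol = max(vapply(res, length, integer(1)), 1L))
    for (tr in triples) for (m in 1:3) used[m, tr[m]] <- TRUE
    for (r in seq_len(nrow(leftover))) {
      ms <- mp_methods[[leftover$mp[r]]]
      di <- leftover$i[r]; dj <- leftover$j[r]
      if (!used[ms[1], di] && !used[ms[2], dj]) {
        pairs[[length(pairs) + 1L]] <- list(methods = ms, idx = c(di, dj))
        used[ms[1], di] <- TRUE; used[ms[2], dj] <- TRUE
      }
    }
  }

  sources <- vapply(seq_along(chops), function(m) {
    s <- chops[[m]]$source
    if (nzchar(s)) s else paste0("m", m)
  }, character(1))

  vote_keep <- function(members, need) {
    counts <- table(unlist(lapply(members, unique)))
    as.integer(names(counts)[counts >= need])
  }

  domains <- list()
  for (tr in triples) {
    members <- lapply(1:3, function(m) res[[m]][[tr[m]]])
    kept <- vote_keep(members, 2L)
    if (length(kept) >= min_len)
      domains[[length(domains) + 1L]] <-
        consensus_domain(kept, "high", sources)
  }
  for (p in pairs) {
    members <- list(res[[p$methods[1]]][[p$idx[1]]],
                    res[[p$methods[2]]][[p$idx[2]]])
    kept <- vote_keep(members, 2L)
    if (length(kept) >= min_len)
      domains[[length(domains) + 1L]] <-
        consensus_domain(kept, "medium", sources[p$methods])
  }
  ord <- order(vapply(domains, function(d) d$residues[1], integer(1)))
  domains <- domains[ord]

  if (!is.null(chain)) {
    for (k in seq_along(domains)) {
      idx <- match(domains[[k]]$residues, chain$residue_numbers)
      domains[[k]]$avg_plddt <- mean(chain$plddt[idx])
    }
  }
  ndr <- setdiff(chain_residues, unlist(lapply(domains, `[[`, "residues")))
  consensus_result(chain_id, domains, ndr)
}

#' Summarise domain composition over a set of targets
#'
#' Tabulates what fraction of targets have zero, one, or multiple
#' consensus domains, the per-target NDR fraction, and the domain-count
#' histogram.
#'
#' @param results nonempty list of `consensus_result` objects.
#' @return list with `n_targets`, `counts` and `fractions` (named
#'   zero/single/multi), `ndr_fraction` (per target), and
#'   `domain_count_histogram` (named table).
#' @export
summarize_targets <- function(results) {
  if (length(results) == 0L) stop("no consensus results supplied")
  n_dom <- vapply(results, function(r) length(r$domains), integer(1))
  ndr_frac <- vapply(results, function(r) {
    tot <- length(r$ndr_residues) + sum(vapply(r$domains, function(d)
      length(d$residues), integer(1)))
    length(r$ndr_residues) / tot
  }, numeric(1))
  counts <- c(zero = sum(n_dom == 0L), single = sum(n_dom == 1L),
              multi = sum(n_dom > 1L))
  list(n_targets = length(results),
       counts = counts,
       fractions = counts / length(results),
       ndr_fraction = ndr_frac,
       domain_count_histogram = table(n_dom))
}
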