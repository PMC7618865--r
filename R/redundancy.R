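#' Maximum pairwise RMSD within a cluster of identical sequences
#'
#' Superposed (Kabsch) Calpha RMSD over every unordered member pair.
#' For clusters up to `max_exact` members all pairs are enumerated;
#' beyond that the maximum RMSD to the medoid is reported instead, with
#' the approximation flagged.
#'
#' @param members list of [residue_chain()] objects (or n x 3 matrices)
#'   with identical length and residue numbering; at least 2.
#' @param max_exact largest cluster for exact all-pairs enumeration
#'   (default 50).
#' @return list with `max_rmsd` (Angstrom), `pair` (member indices
#'   attaining it) and `exact` (FALSE when the medoid approximation was
#'   used).
#' @export
max_pairwise_rmsd <- function(members, max_exact = 50) {
  coords <- member_coords(members)
  n <- length(coords)
  if (n < 2L) stop("need at least 2 members")
  if (n <= max_exact) {
    best <- c(0, 1, 2); found <- FALSE
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      r <- kabsch(coords[[i]], coords[[j]])$rmsd
      if (!found || r > best[1]) { best <- c(r, i, j); found <- TRUE }
    }
    list(max_rmsd = best[1], pair = as.integer(best[2:3]), exact = TRUE)
  } else {
    med <- medoid(members)
    r <- vapply(seq_len(n), function(i)
      if (i == med) 0 else kabsch(coords[[i]], coords[[med]])$rmsd,
      numeric(1))
    i <- which.max(r)
    list(max_rmsd = r[i], pair = sort(c(med, i)), exact = FALSE)
  }
}

member_coords <- function(members) {
  coords <- lapply(members, function(m)
    if (inherits(m, "residue_chain")) m$ca_coords else as.matrix(m))
  lens <- vapply(coords, nrow, integer(1))
  if (length(unique(lens)) != 1L)
    stop("members differ in length: ", paste(unique(lens), collapse = ", "))
  numbering <- lapply(members, function(m)
    if (inherits(m, "residue_chain")) m$residue_numbers else NULL)
  numbering <- numbering[!vapply(numbering, is.null, logical(1))]
  if (length(numbering) > 1L &&
      !all(vapply(numbering[-1], identical, logical(1), numbering[[1]])))
    stop("members differ in residue numbering")
  coords
}

#' Medoid member of a cluster
#'
#' The member minimising the sum of superposed RMSDs to all other
#' members; ties break to the lowest index.
#'
#' @param members list of [residue_chain()] objects (or coordinate
#'   matrices) of equal length; at least 1.
#' @return 1-based member index.
#' @export
medoid <- function(members) {
  coords <- member_coords(members)
  n <- length(coords)
  if (n == 1L) return(1L)
  rms <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    r <- kabsch(coords[[i]], coords[[j]])$rmsd
    rms[i, j] <- r; rms[j, i] <- r
  }
  which.min(rowSums(rms))  # which.min takes the first (lowest index) tie
}

#' Consensus chopping across an identical-sequence cluster
#'
#' Members of a cluster of identical sequences are independently
#' segmented; this derives one cluster-level chopping by strict
#' per-residue majority vote. The member with the most domains anchors
#' the vote; every other member's domains are matched to the anchor's by
#' IoU (see [match_choppings()]) and a residue is kept in an anchor
#' domain if more than half of all members place it in the matched
#' domain. Residues without a majority become NDR.
#'
#' @param choppings list of `chopping` objects, one per member.
#' @param iou_min domain matching threshold (default 0.7).
#' @param chain_residues full residue set of the (shared) chain; default
#'   is the union of all chopping residues.
#' @param chain_id identifier for the returned result.
#' @return a `consensus_result`; domain confidence is "high" when every
#'   member contributed a matched domain, otherwise "medium".
#' @export
cluster_consensus_domains <- function(choppings, iou_min = 0.7,
                                      chain_residues = NULL, chain_id = "") {
  n <- length(choppings)
  if (n == 0L) stop("no choppings supplied")
  all_res <- sort(unique(unlist(lapply(choppings, chopping_residues))))
  if (is.null(chain_residues)) chain_residues <- all_res
  if (length(setdiff(all_res, chain_residues)) > 0L)
    stop("chopping residues outside the shared chain numbering")
  n_dom <- vapply(choppings, function(ch) length(ch$domains), integer(1))
  anchor <- which.max(n_dom)
  anchor_res <- chopping_residues(choppings[[anchor]])

  matches <- lapply(seq_len(n), function(m) {
    if (m == anchor) NULL
    else match_choppings(choppings[[anchor]], choppings[[m]], iou_min)
  })
  member_res <- lapply(choppings, chopping_residues)

  domains <- list()
  for (d in seq_along(anchor_res)) {
    members <- list(anchor_res[[d]])
    n_support <- 1L
    for (m in seq_len(n)) {
      if (m == anchor) next
      row <- which(matches[[m]]$i == d)
      if (length(row) == 1L) {
        members[[length(members) + 1L]] <- member_res[[m]][[matches[[m]]$j[row]]]
        n_support <- n_support + 1L
      }
    }
    counts <- table(unlist(members))
    kept <- as.integer(names(counts)[counts > n / 2])
    if (length(kept) > 0L)
      domains[[length(domains) + 1L]] <- consensus_domain(
        kept, confidence = if (n_support == n) "high" else "medium",
        supporting_methods = paste0("member", seq_len(n_support)))
  }
  ord <- order(vapply(domains, function(d) d$residues[1], integer(1)))
  ndr <- setdiff(chain_residues, unlist(lapply(domains, `[[`, "residues")))
  consensus_result(chain_id, domains[ord], ndr)
}
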