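#' Calpha contact test between two domains
#'
#' Two domains are in contact when at least `min_pairs` Calpha-Calpha
#' pairs lie within `dist_max` Angstrom.
#'
#' @param coords_a,coords_b nonempty n x 3 coordinate matrices.
#' @param dist_max contact distance cutoff in Angstrom (default 8).
#' @param min_pairs minimum number of close pairs (default 3).
#' @return list with `contact` (logical), `min_ca_dist` and `n_pairs`
#'   (pairs within `dist_max`).
#' @export
detect_contact <- function(coords_a, coords_b, dist_max = 8, min_pairs = 3) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) == 0L || nrow(coords_b) == 0L)
    stop("empty coordinate set")
  d2 <- outer(rowSums(coords_a^2), rowSums(coords_b^2), "+") -
    2 * coords_a %*% t(coords_b)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  n_close <- sum(d <= dist_max)
  list(contact = n_close >= min_pairs,
       min_ca_dist = min(d),
       n_pairs = n_close)
}

#' Mean inter-domain predicted aligned error
#'
#' Symmetrised mean of the two off-diagonal PAE blocks between two
#' disjoint residue index sets (a->b and b->a).
#'
#' @param pae a `pae_matrix`.
#' @param idx_a,idx_b disjoint 1-based matrix index sets.
#' @return mean PAE in Angstrom.
#' @export
inter_domain_pae <- function(pae, idx_a, idx_b) {
  n <- nrow(pae)
  if (any(idx_a < 1L | idx_a > n) || any(idx_b < 1L | idx_b > n))
    stop("residue index outside PAE matrix")
  if (length(intersect(idx_a, idx_b)) > 0L)
    stop("residue sets overlap at ", intersect(idx_a, idx_b)[1])
  mean(c(pae[idx_a, idx_b], pae[idx_b, idx_a]))
}

# Canonical unordered key for a superfamily pair.
isp_key <- function(code_a, code_b) {
  a <- as.character(code_a); b <- as.character(code_b)
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Extract interacting domain pair instances
#'
#' Scans each chain's consensus domains and records one instance per
#' unordered pair of H-labelled, high/medium-confidence domains that (a)
#' are in Calpha contact and (b) have a favourable inter-domain PAE
#' (block mean at most `pae_max`). Domains without superfamily labels are
#' skipped.
#'
#' @param chains list of records, each a list with elements `chain`
#'   ([residue_chain()]), `consensus` (`consensus_result`), `labels`
#'   (data.frame `domain_id`, `code` of H-level CATH codes) and `pae`
#'   (`pae_matrix`, may be NULL when `pae_max = Inf`).
#' @param dist_max,min_pairs contact definition, see [detect_contact()].
#' @param pae_max maximum favourable inter-domain PAE in Angstrom
#'   (default 10); set `Inf` to disable the PAE filter.
#' @return data.frame of instances: chain, domain ids, codes, ISP key,
#'   minimum Calpha distance, inter-domain PAE, and both centres of mass.
#' @export
extract_isps <- function(chains, dist_max = 8, min_pairs = 3, pae_max = 10) {
  rows <- list()
  for (rec in chains) {
    chain <- rec$chain; cons <- rec$consensus
    labels <- rec$labels
    keep <- which(vapply(cons$domains, function(d)
      d$confidence %in% c("high", "medium"), logical(1)))
    if (length(keep) < 2L) next
    dom_ids <- paste0(chain$chain_id, "_D",
                      formatC(seq_along(cons$domains), width = 2, flag = "0"))
    codes <- setNames(as.character(labels$code), labels$domain_id)
    labelled <- keep[dom_ids[keep] %in% names(codes)]
    if (length(labelled) < 2L) next
    if (is.finite(pae_max) && is.null(rec$pae))
      stop("PAE filter requested but no PAE matrix for chain ",
           chain$chain_id)
    for (ii in seq_along(labelled)) for (jj in seq_along(labelled)) {
      if (jj <= ii) next
      i <- labelled[ii]; j <- labelled[jj]
      res_i <- cons$domains[[i]]$residues
      res_j <- cons$domains[[j]]$residues
      ci <- chain_coords(chain, res_i); cj <- chain_coords(chain, res_j)
      contact <- detect_contact(ci, cj, dist_max, min_pairs)
      if (!contact$contact) next
      ipae <- if (is.finite(pae_max)) {
        inter_domain_pae(rec$pae,
                         match(res_i, chain$residue_numbers),
                         match(res_j, chain$residue_numbers))
      } else NA_real_
      if (is.finite(pae_max) && ipae > pae_max) next
      com_i <- center_of_mass(ci); com_j <- center_of_mass(cj)
      rows[[length(rows) + 1L]] <- data.frame(
        chain_id = chain$chain_id,
        domain_a_id = dom_ids[i], domain_b_id = dom_ids[j],
        code_a = codes[[dom_ids[i]]], code_b = codes[[dom_ids[j]]],
        isp_key = isp_key(codes[[dom_ids[i]]], codes[[dom_ids[j]]]),
        min_ca_dist = contact$min_ca_dist,
        inter_pae = ipae,
        com_a_x = com_i[1], com_a_y = com_i[2], com_a_z = com_i[3],
        com_b_x = com_j[1], com_b_y = com_j[2], com_b_z = com_j[3],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(chain_id = character(0), domain_a_id = character(0),
                      domain_b_id = character(0), code_a = character(0),
                      code_b = character(0), isp_key = character(0),
                      min_ca_dist = numeric(0), inter_pae = numeric(0),
                      com_a_x = numeric(0), com_a_y = numeric(0),
                      com_a_z = numeric(0), com_b_x = numeric(0),
                      com_b_y = numeric(0), com_b_z = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise instances into interacting superfamily pairs
#'
#' @param instances data.frame from [extract_isps()].
#' @return data.frame with one row per ISP key: `isp_key`,
#'   `n_instances`, `homotypic`.
#' @export
summarize_isps <- function(instances) {
  if (nrow(instances) == 0L)
    return(data.frame(isp_key = character(0), n_instances = integer(0),
                      homotypic = logical(0)))
  tab <- table(instances$isp_key)
  keys <- sort(names(tab))
  homo <- vapply(strsplit(keys, "|", fixed = TRUE),
                 function(p) p[1] == p[2], logical(1))
  data.frame(isp_key = keys, n_instances = as.integer(tab[keys]),
             homotypic = homo, stringsAsFactors = FALSE)
}

#' Conservation of interaction orientation (CIO) for one ISP
#'
#' Measures how consistently the two superfamilies of an ISP adopt the
#' same relative geometry across instances. In each instance a reference
#' domain is chosen (the domain whose superfamily code sorts first; for
#' homotypic pairs the larger domain, then the one starting earlier).
#' The instance whose reference domain has the most residues is the
#' master. Each instance's reference is Kabsch-aligned onto the master
#' reference and the fitted transform is applied to the tag-along
#' domain, bringing all pairs into a common frame; the unit vectors from
#' reference to tag-along centre of mass are then pooled and CIO is
#' their mean resultant length `||sum v_i|| / n`, so CIO is 1 for a
#' perfectly conserved orientation and near 0 for isotropic geometry.
#'
#' References differing in length are aligned over their common-length
#' prefix; instances whose reference shares less than half the master's
#' length are dropped with a warning.
#'
#' @param instances data.frame of instances of a single ISP (rows from
#'   [extract_isps()]), at least 2.
#' @param domain_coords named list mapping each `domain_id` to its n x 3
#'   Calpha coordinate matrix.
#' @return object of class `cio_result`: `pair`, `n`, `master_instance`,
#'   `unit_vectors` (n x 3) and `cio` in `[0, 1]`.
#' @export
cio <- function(instances, domain_coords) {
  if (nrow(instances) < 2L)
    stop("CIO requires at least 2 instances")
  if (length(unique(instances$isp_key)) != 1L)
    stop("instances must all belong to one ISP")

  pick_ref <- function(row) {
    na <- nrow(domain_coords[[row$domain_a_id]])
    nb <- nrow(domain_coords[[row$domain_b_id]])
    if (row$code_a < row$code_b) "a"
    else if (row$code_b < row$code_a) "b"
    else if (na != nb) { if (na > nb) "a" else "b" }
    else if (row$domain_a_id <= row$domain_b_id) "a" else "b"
  }
  refs <- vapply(seq_len(nrow(instances)), function(r)
    pick_ref(instances[r, ]), character(1))
  ref_id <- ifelse(refs == "a", instances$domain_a_id, instances$domain_b_id)
  tag_id <- ifelse(refs == "a", instances$domain_b_id, instances$domain_a_id)
  ref_len <- vapply(ref_id, function(id) nrow(domain_coords[[id]]), integer(1))
  master_row <- order(-ref_len, ref_id)[1]
  master_coords <- domain_coords[[ref_id[master_row]]]
  m_len <- nrow(master_coords)

  vecs <- matrix(NA_real_, nrow = nrow(instances), ncol = 3)
  kept <- logical(nrow(instances))
  for (r in seq_len(nrow(instances))) {
    rc <- domain_coords[[ref_id[r]]]
    if (nrow(rc) < 0.5 * m_len) {
      warning("dropping instance ", r, ": reference shares <50% of master length")
      next
    }
    k <- min(nrow(rc), m_len)
    fit <- kabsch(rc[seq_len(k), , drop = FALSE],
                  master_coords[seq_len(k), , drop = FALSE])
    ref_m <- apply_transform(fit, rc)
    tag_m <- apply_transform(fit, domain_coords[[tag_id[r]]])
    v <- center_of_mass(tag_m) - center_of_mass(ref_m)
    nv <- sqrt(sum(v^2))
    if (nv == 0) {
      warning("dropping instance ", r, ": coincident centres of mass")
      next
    }
    vecs[r, ] <- v / nv
    kept[r] <- TRUE
  }
  if (sum(kept) < 2L) stop("fewer than 2 alignable instances")
  vecs <- vecs[kept, , drop = FALSE]
  structure(list(pair = instances$isp_key[1],
                 n = nrow(vecs),
                 master_instance = master_row,
                 unit_vectors = vecs,
                 cio = sqrt(sum(colSums(vecs)^2)) / nrow(vecs)),
            class = "cio_result")
}

#' @export
print.cio_result <- function(x, ...) {
  cat(sprintf("<cio_result %s: CIO = %.3f over %d instances>\n",
              x$pair, x$cio, x$n))
  invisible(x)
}

#' Instance-count enrichment of an ISP between two datasets
#'
#' @param n_ted,n_cath instance counts (>= 1) of the same ISP in the two
#'   datasets being compared.
#' @return `log2(n_ted / n_cath)`.
#' @export
enrichment <- function(n_ted, n_cath) {
  if (any(c(n_ted, n_cath) < 1))
    stop("enrichment is defined only for ISPs present in both sets")
  log2(n_ted / n_cath)
}

#' Hub class of a superfamily from its partner count
#'
#' Thresholds follow the Ekman et al. convention: small (< 4
#' connections), medium (4-7), large (>= 8).
#'
#' @param n_partners integer vector of distinct interaction partners.
#' @return character vector of "small", "medium", "large".
#' @export
classify_hub <- function(n_partners) {
  if (any(n_partners < 0)) stop("partner counts must be non-negative")
  ifelse(n_partners < 4, "small", ifelse(n_partners <= 7, "medium", "large"))
}

#' Compare two sets of interacting superfamily pairs
#'
#' Pairs are unordered: `(x, y)` equals `(y, x)`.
#'
#' @param set_a,set_b character vectors of ISP keys, or two-column
#'   matrices/data.frames of code pairs (canonicalised internally).
#' @return list with `common`, `only_a`, `only_b` (sorted key vectors)
#'   and `counts`.
#' @export
compare_isp_sets <- function(set_a, set_b) {
  canon <- function(s) {
    if (is.matrix(s) || is.data.frame(s)) {
      s <- as.data.frame(s)
      s <- isp_key(as.character(s[[1]]), as.character(s[[2]]))
    }
    sort(unique(as.character(s)))
  }
  a <- canon(set_a); b <- canon(set_b)
  out <- list(common = intersect(a, b),
              only_a = setdiff(a, b),
              only_b = setdiff(b, a))
  out$counts <- vapply(out, length, integer(1))
  out
}

#' Export an ISP network as edge and node tables
#'
#' Each ISP contributes one edge between its two superfamilies (a
#' self-loop if homotypic); node degree is the number of distinct
#' partner superfamilies (a homotypic interaction counts the superfamily
#' itself as one partner), and nodes carry their hub class.
#'
#' @param summaries data.frame from [summarize_isps()] (needs `isp_key`
#'   and `n_instances`).
#' @return list of deterministic data.frames: `edges` (node_a, node_b,
#'   n_instances; sorted by key) and `nodes` (node, n_partners,
#'   hub_class; sorted by node).
#' @export
export_interaction_graph <- function(summaries) {
  keys <- sort(summaries$isp_key)
  parts <- strsplit(keys, "|", fixed = TRUE)
  edges <- data.frame(node_a = vapply(parts, `[`, character(1), 1),
                      node_b = vapply(parts, `[`, character(1), 2),
                      n_instances = summaries$n_instances[match(keys, summaries$isp_key)],
                      stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  n_partners <- vapply(nodes, function(nd) {
    partners <- c(edges$node_b[edges$node_a == nd],
                  edges$node_a[edges$node_b == nd])
    length(unique(partners))
  }, integer(1))
  list(edges = edges,
       nodes = data.frame(node = nodes, n_partners = n_partners,
                          hub_class = classify_hub(n_partners),
                          stringsAsFactors = FALSE, row.names = NULL))
}
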