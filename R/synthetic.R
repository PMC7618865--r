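#' Synthetic structure and table generators
#'
#' Deterministic, seeded generators for every input dialect the toolkit
#' consumes: Calpha chains with domain layouts and plDDT, cyclically
#' symmetric chains, block-structured PAE matrices, two-domain
#' interaction ensembles with controlled orientation dispersion, and
#' identical-sequence clusters with or without a planted hinge motion.
#' Domains are compact 3.8-Angstrom-step random walks confined to a
#' sphere sized so the radius of gyration matches the collapsed-chain
#' expectation; every tested statistic (IoU, RMSD, centre-of-mass
#' geometry, PAE block means, shift periodicity) is geometry-level, so
#' no secondary structure or energetics is modelled. All generators are
#' pure functions of their arguments and `seed`.
#'
#' @name synthetic_fixtures
NULL

random_unit_vector <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# Compact self-avoiding random walk: 3.8 A steps confined to a sphere
# sized so Rg tracks the collapsed-chain expectation, with a hard-sphere
# clash distance to all previous residues (excluded volume, as in real
# Calpha traces). If the walk jams, the clash distance is relaxed.
compact_walk <- function(n, step = 3.8, clash = 3.6) {
  radius <- sqrt(5 / 3) * 2.2 * n^0.38
  coords <- matrix(0, nrow = n, ncol = 3)
  for (i in seq_len(n)[-1]) {
    p <- coords[i - 1L, ]
    prev <- coords[seq_len(i - 1L), , drop = FALSE]
    cand <- NULL
    for (cl in c(clash, clash * 0.8, 0)) {
      for (try in 1:60) {
        prop <- p + step * random_unit_vector()
        if (sqrt(sum(prop^2)) > radius) {
          if (sqrt(sum(p^2)) > 1e-9)
            prop <- p + step * (-p / sqrt(sum(p^2)))
          else next
        }
        if (cl == 0 ||
            min(sqrt(rowSums(sweep(prev, 2, prop)^2))) >= cl) {
          cand <- prop
          break
        }
      }
      if (!is.null(cand)) break
    }
    coords[i, ] <- cand
  }
  sweep(coords, 2, colMeans(coords))
}

# Rotation matrix from axis and angle (Rodrigues).
rotation_about_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

random_rigid_motion <- function(coords, max_shift = 50) {
  R <- rotation_about_axis(random_unit_vector(), runif(1, 0, 2 * pi))
  t <- runif(3, -max_shift, max_shift)
  sweep(coords %*% t(R), 2, t, "+")
}

#' Generate a multi-domain chain with ground-truth chopping
#'
#' Concatenates compact random-walk domains with 5-residue linkers;
#' plDDT is drawn high (90-98) inside domains and low (30-50) in
#' linkers, mimicking well-folded predicted domains joined by
#' low-confidence linkers.
#'
#' @param layout integer vector of domain lengths (each >= 10).
#' @param seed RNG seed.
#' @param chain_id identifier for the chain.
#' @param linker_len linker length in residues between consecutive
#'   domains (default 5).
#' @return list with `chain` (a [residue_chain()]) and `chopping` (the
#'   ground-truth `chopping`).
#' @export
make_chain <- function(layout, seed = 1, chain_id = "SYN", linker_len = 5) {
  stopifnot(all(layout >= 10))
  with_seed(seed, {
    coords <- NULL
    plddt <- numeric(0)
    segments <- list()
    pos <- 0L
    for (d in seq_along(layout)) {
      dom <- compact_walk(layout[d])
      if (is.null(coords)) {
        coords <- dom
      } else {
        prev_end <- coords[nrow(coords), ]
        u <- random_unit_vector()
        gap <- 3.8 * (linker_len + 1L)
        start_target <- prev_end + gap * u
        dom <- sweep(dom, 2, start_target - dom[1L, ], "+")
        link <- t(vapply(seq_len(linker_len), function(i)
          prev_end + (i / (linker_len + 1)) * (start_target - prev_end),
          numeric(3)))
        coords <- rbind(coords, link, dom)
        plddt <- c(plddt, runif(linker_len, 30, 50))
        pos <- pos + linker_len
      }
      segments[[d]] <- c(pos + 1L, pos + layout[d])
      plddt <- c(plddt, runif(layout[d], 90, 98))
      pos <- pos + layout[d]
    }
    chain <- residue_chain(chain_id, seq_len(pos), coords, plddt)
    truth <- chopping(lapply(segments, function(s) matrix(s, ncol = 2)),
                      source = "truth")
    list(chain = chain, chopping = truth)
  })
}

#' Generate a cyclically symmetric chain
#'
#' One asymmetric random-walk unit is replicated by rotation about a
#' common axis (360/n degrees per copy) at a fixed radius and serially
#' connected, emulating repeat architectures such as propellers and
#' extruded cyclic repeats.
#'
#' @param n_copies number of copies (>= 2).
#' @param unit_len residues per asymmetric unit.
#' @param radius distance of the unit centre from the symmetry axis in
#'   Angstrom (default 15).
#' @param seed RNG seed.
#' @param chain_id identifier.
#' @return a [residue_chain()] of `n_copies * unit_len` residues.
#' @export
make_cn_symmetric <- function(n_copies, unit_len, radius = 15, seed = 1,
                              chain_id = "CN") {
  stopifnot(n_copies >= 2)
  with_seed(seed, {
    unit <- compact_walk(unit_len)
    unit <- sweep(unit, 2, c(radius, 0, 0), "+")
    coords <- do.call(rbind, lapply(seq_len(n_copies) - 1L, function(k) {
      unit %*% t(rotation_about_axis(c(0, 0, 1), 2 * pi * k / n_copies))
    }))
    residue_chain(chain_id, seq_len(n_copies * unit_len), coords,
                  rep(90, n_copies * unit_len))
  })
}

#' Generate a block-structured PAE matrix
#'
#' Intra-domain blocks at `intra_level`, inter-domain blocks at
#' `inter_level`, optional additive Gaussian noise truncated at 3 sigma
#' and clamped at zero; the diagonal is set near zero as in real PAE
#' maps. Entries are quantised to 0.01 Angstrom, the precision at which
#' PAE is serialised in AFDB JSON, so written fixtures round-trip
#' bit-exactly.
#'
#' @param layout integer vector of block (domain) lengths; the matrix
#'   has `sum(layout)` rows.
#' @param intra_level,inter_level block levels in Angstrom.
#' @param noise_sigma noise standard deviation (default 0).
#' @param seed RNG seed.
#' @param symmetric mirror the upper triangle onto the lower (default
#'   TRUE); set FALSE for deliberately asymmetric blocks.
#' @return a `pae_matrix`.
#' @export
make_pae <- function(layout, intra_level = 3, inter_level = 15,
                     noise_sigma = 0, seed = 1, symmetric = TRUE) {
  stopifnot(intra_level >= 0, inter_level >= 0)
  with_seed(seed, {
    n <- sum(layout)
    block <- rep(seq_along(layout), layout)
    m <- matrix(inter_level, n, n)
    same <- outer(block, block, "==")
    m[same] <- intra_level
    if (noise_sigma > 0) {
      noise <- matrix(rnorm(n * n, 0, noise_sigma), n, n)
      noise <- pmin(pmax(noise, -3 * noise_sigma), 3 * noise_sigma)
      m <- pmax(m + noise, 0)
    }
    if (symmetric) m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- pmin(diag(m), 0.2)
    pae_matrix(round(m, 2))
  })
}

# von Mises-Fisher sample on the unit sphere (Wood's method); kappa = 0
# is uniform, kappa = Inf returns the mean direction exactly.
rvmf <- function(mu, kappa) {
  mu <- mu / sqrt(sum(mu^2))
  if (is.infinite(kappa)) return(mu)
  if (kappa == 0) return(random_unit_vector())
  u <- runif(1)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  # orthonormal basis completing mu
  a <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * mu) * mu; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(mu[2] * e1[3] - mu[3] * e1[2],
          mu[3] * e1[1] - mu[1] * e1[3],
          mu[1] * e1[2] - mu[2] * e1[1])
  phi <- runif(1, 0, 2 * pi)
  w * mu + sqrt(1 - w^2) * (cos(phi) * e1 + sin(phi) * e2)
}

#' Generate an ensemble of two-domain interaction instances
#'
#' Builds `n_instances` copies of a reference two-domain chain in which
#' the tag-along domain is placed along a direction drawn from a von
#' Mises-Fisher distribution of concentration `kappa` about a fixed mean
#' direction (`kappa = 0` is uniform on the sphere; `kappa = Inf` gives
#' exact copies). Each instance is then moved by a random global rigid
#' motion, so downstream orientation statistics must genuinely align
#' into a common frame. Domains are placed in contact and the generated
#' PAE has a favourable inter-domain block, so every instance passes the
#' default extraction filters.
#'
#' @param n_instances number of instances (>= 2).
#' @param kappa orientation concentration (>= 0, or Inf).
#' @param seed RNG seed.
#' @param len_a,len_b domain lengths (defaults 60 and 50).
#' @param code_a,code_b superfamily codes attached to the two domains.
#' @return list of instance records, each with `chain`, `consensus`,
#'   `labels` and `pae`, ready for [extract_isps()]; plus attribute
#'   `domain_coords` (named list for [cio()]).
#' @export
make_isp_ensemble <- function(n_instances, kappa, seed = 1,
                              len_a = 60, len_b = 50,
                              code_a = "3.40.50.300", code_b = "2.60.40.10") {
  stopifnot(n_instances >= 2, kappa >= 0)
  with_seed(seed, {
    dom_a <- compact_walk(len_a)
    dom_b <- compact_walk(len_b)
    mu <- c(1, 0, 0)
    instances <- vector("list", n_instances)
    domain_coords <- list()
    for (i in seq_len(n_instances)) {
      v <- rvmf(mu, kappa)
      # slab separation along v guarantees a >= gap clearance; shrink the
      # gap until the Calpha contact criterion is met
      d_a <- max(dom_a %*% v)
      d_b <- -min(dom_b %*% v)
      placed_b <- NULL
      for (gap in seq(2, 0.5, by = -0.25)) {
        shift <- (d_a + d_b + gap) * v
        cand <- sweep(dom_b, 2, shift, "+")
        if (detect_contact(dom_a, cand, 8, 3)$contact) { placed_b <- cand; break }
      }
      if (is.null(placed_b))
        placed_b <- sweep(dom_b, 2, (d_a + d_b + 0.5) * v, "+")
      coords <- random_rigid_motion(rbind(dom_a, placed_b))
      chain_id <- sprintf("ISP%04d", i)
      n <- len_a + len_b
      chain <- residue_chain(chain_id, seq_len(n), coords, rep(92, n))
      cons <- consensus_result(chain_id, list(
        consensus_domain(seq_len(len_a), "high", c("m1", "m2", "m3"),
                         avg_plddt = 92),
        consensus_domain(seq.int(len_a + 1L, n), "high", c("m1", "m2", "m3"),
                         avg_plddt = 92)),
        ndr_residues = integer(0))
      ids <- paste0(chain_id, c("_D01", "_D02"))
      labels <- data.frame(domain_id = ids, code = c(code_a, code_b),
                           stringsAsFactors = FALSE)
      pae <- make_pae(c(len_a, len_b), intra_level = 3, inter_level = 6,
                      noise_sigma = 0, seed = seed + i)
      domain_coords[[ids[1]]] <- coords[seq_len(len_a), , drop = FALSE]
      domain_coords[[ids[2]]] <- coords[seq.int(len_a + 1L, n), , drop = FALSE]
      instances[[i]] <- list(chain = chain, consensus = cons,
                             labels = labels, pae = pae)
    }
    attr(instances, "domain_coords") <- domain_coords
    instances
  })
}

#' Generate a cluster of identical-sequence models
#'
#' Copies of one two-domain chain with sub-Angstrom coordinate jitter;
#' when `divergent`, one member's second domain is additionally rotated
#' about the inter-domain hinge, producing a maximum pairwise RMSD well
#' above 1 Angstrom (the divergence signature of redundant predicted
#' models).
#'
#' @param n_members cluster size (>= 2).
#' @param divergent plant a hinge motion in one member (default FALSE).
#' @param seed RNG seed.
#' @param layout domain layout of the shared chain (default c(60, 60)).
#' @param jitter_sigma per-coordinate Gaussian jitter in Angstrom
#'   (default 0.05).
#' @param hinge_angle hinge rotation in radians for the divergent member
#'   (default 30 degrees).
#' @return list with `members` (list of [residue_chain()]), `divergent`
#'   and `layout`.
#' @export
make_redundant_cluster <- function(n_members, divergent = FALSE, seed = 1,
                                   layout = c(60, 60), jitter_sigma = 0.05,
                                   hinge_angle = pi / 6) {
  stopifnot(n_members >= 2)
  with_seed(seed, {
    base <- make_chain(layout, seed = seed + 1e4, chain_id = "RED")$chain
    n <- length(base$residue_numbers)
    members <- lapply(seq_len(n_members), function(m) {
      coords <- base$ca_coords + matrix(rnorm(3 * n, 0, jitter_sigma), n, 3)
      if (divergent && m == n_members) {
        dom2 <- seq.int(layout[1] + 6L, n)  # second domain, after the linker
        pivot <- coords[layout[1], ]
        R <- rotation_about_axis(random_unit_vector(), hinge_angle)
        coords[dom2, ] <- sweep(sweep(coords[dom2, , drop = FALSE], 2, pivot) %*% t(R),
                                2, pivot, "+")
      }
      residue_chain(sprintf("RED_M%02d", m), base$residue_numbers, coords,
                    base$plddt)
    })
    list(members = members, divergent = divergent, layout = layout)
  })
}

#' Generate an embedding reference set
#'
#' Standard-normal embedding vectors for known-domain references, plus
#' helper queries at controlled distance from the reference density.
#'
#' @param n number of vectors.
#' @param dim embedding dimensionality (default 16).
#' @param seed RNG seed.
#' @param center scalar added to every coordinate (default 0); place
#'   queries far from the origin to make them novel.
#' @return n x dim numeric matrix with rownames `E0001...`.
#' @export
make_embeddings <- function(n, dim = 16, seed = 1, center = 0) {
  with_seed(seed, {
    m <- matrix(rnorm(n * dim) + center, nrow = n)
    rownames(m) <- sprintf("E%04d", seq_len(n))
    m
  })
}
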