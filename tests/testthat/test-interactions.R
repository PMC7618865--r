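test_that("contact detection counts close Calpha pairs", {
  a <- matrix(c(0, 0, 0), 1)
  far <- matrix(c(40, 0, 0), 1)
  r <- detect_contact(a, far, dist_max = 8, min_pairs = 1)
  expect_false(r$contact)
  expect_equal(r$min_ca_dist, 40)

  near <- matrix(c(7.9, 0, 0), 1)
  expect_true(detect_contact(a, near, dist_max = 8, min_pairs = 1)$contact)

  set.seed(51)
  A <- matrix(rnorm(60, sd = 3), ncol = 3)
  B <- sweep(matrix(rnorm(60, sd = 3), ncol = 3), 2, c(6, 0, 0), "+")
  r2 <- detect_contact(A, B, dist_max = 8, min_pairs = 3)
  d <- as.matrix(dist(rbind(A, B)))[1:20, 21:40]
  expect_equal(r2$n_pairs, sum(d <= 8))
  expect_equal(r2$min_ca_dist, min(d))
  expect_equal(r2$contact, sum(d <= 8) >= 3)
})

test_that("inter-domain PAE is the symmetrised off-block mean", {
  pae <- pae_matrix(matrix(5, 10, 10))
  expect_equal(inter_domain_pae(pae, 1:5, 6:10), 5)

  m <- matrix(3, 10, 10)
  m[1:5, 6:10] <- 4; m[6:10, 1:5] <- 8
  expect_equal(inter_domain_pae(pae_matrix(m), 1:5, 6:10), 6)

  blk <- make_pae(c(30, 25), intra_level = 3, inter_level = 15, seed = 1)
  expect_equal(inter_domain_pae(blk, 1:30, 31:55), 15)
  expect_error(inter_domain_pae(pae, 1:5, 5:10), "overlap")
  expect_error(inter_domain_pae(pae, 1:5, 9:12), "outside")
})

test_that("ISP extraction applies contact and PAE filters per domain pair", {
  ens <- make_isp_ensemble(3, Inf, seed = 61)
  isps <- extract_isps(ens)
  expect_equal(nrow(isps), 3)
  expect_true(all(isps$inter_pae <= 10))
  expect_true(all(isps$min_ca_dist <= 8))
  expect_equal(unique(isps$isp_key), "2.60.40.10|3.40.50.300")

  # unfavourable PAE removes the instance
  bad <- lapply(ens, function(rec) {
    rec$pae <- make_pae(c(60, 50), intra_level = 3, inter_level = 18, seed = 1)
    rec
  })
  expect_equal(nrow(extract_isps(bad)), 0)

  # domains without H labels are skipped
  unlab <- lapply(ens, function(rec) { rec$labels <- rec$labels[0, ]; rec })
  expect_equal(nrow(extract_isps(unlab)), 0)

  nopae <- lapply(ens, function(rec) { rec$pae <- NULL; rec })
  expect_error(extract_isps(nopae), "no PAE")
  expect_equal(nrow(extract_isps(nopae, pae_max = Inf)), 3)
})

test_that("ISP extraction equals brute-force all-pairs filtering", {
  # build one chain with 3 domains where only consecutive pairs touch
  set.seed(62)
  d1 <- domainkit:::compact_walk(40)
  d2 <- sweep(domainkit:::compact_walk(40), 2, c(14, 0, 0), "+")
  d3 <- sweep(domainkit:::compact_walk(40), 2, c(28, 0, 0), "+")
  coords <- rbind(d1, d2, d3)
  chain <- residue_chain("TRI", 1:120, coords, rep(92, 120))
  cons <- domainkit:::consensus_result("TRI", list(
    domainkit:::consensus_domain(1:40, "high", c("m1", "m2", "m3")),
    domainkit:::consensus_domain(41:80, "high", c("m1", "m2", "m3")),
    domainkit:::consensus_domain(81:120, "high", c("m1", "m2", "m3"))),
    integer(0))
  labels <- data.frame(domain_id = paste0("TRI_D0", 1:3),
                       code = c("1.10.10.10", "2.60.40.10", "3.40.50.300"))
  rec <- list(chain = chain, consensus = cons, labels = labels,
              pae = make_pae(c(40, 40, 40), intra_level = 3, inter_level = 6,
                             seed = 3))
  isps <- extract_isps(list(rec))
  # brute force over all unordered pairs
  doms <- list(1:40, 41:80, 81:120)
  expected <- character(0)
  for (i in 1:2) for (j in (i + 1):3) {
    d <- as.matrix(dist(rbind(coords[doms[[i]], ], coords[doms[[j]], ])))
    d <- d[seq_along(doms[[i]]), length(doms[[i]]) + seq_along(doms[[j]])]
    if (sum(d <= 8) >= 3)
      expected <- c(expected, paste0("TRI_D0", i, ":TRI_D0", j))
  }
  got <- paste0(isps$domain_a_id, ":", isps$domain_b_id)
  expect_setequal(got, expected)
})

test_that("CIO is 1 for identical instances and 0 for antipodal pairs", {
  ens <- make_isp_ensemble(8, Inf, seed = 63)
  isps <- extract_isps(ens)
  r <- cio(isps, attr(ens, "domain_coords"))
  expect_equal(r$cio, 1.0, tolerance = 1e-9)
  expect_equal(nrow(r$unit_vectors), 8)

  # two instances with exactly opposite inter-domain directions
  set.seed(64)
  ref <- domainkit:::compact_walk(40)
  tag <- domainkit:::compact_walk(30)
  up <- sweep(tag, 2, c(0, 0, 25), "+")
  dn <- sweep(tag, 2, c(0, 0, -25), "+")
  dc <- list(I1_D01 = ref, I1_D02 = up, I2_D01 = ref, I2_D02 = dn)
  inst <- data.frame(chain_id = c("I1", "I2"),
                     domain_a_id = c("I1_D01", "I2_D01"),
                     domain_b_id = c("I1_D02", "I2_D02"),
                     code_a = "1.10.10.10", code_b = "2.60.40.10",
                     isp_key = "1.10.10.10|2.60.40.10",
                     min_ca_dist = 5, inter_pae = 5,
                     com_a_x = 0, com_a_y = 0, com_a_z = 0,
                     com_b_x = 0, com_b_y = 0, com_b_z = 0)
  expect_equal(cio(inst, dc)$cio, 0.0, tolerance = 1e-9)
  expect_error(cio(inst[1, ], dc), "at least 2")
})

test_that("CIO tracks orientation concentration and ignores rigid motion", {
  cios <- vapply(c(0, 5, 50), function(kappa) {
    ens <- make_isp_ensemble(100, kappa, seed = 65)
    cio(extract_isps(ens), attr(ens, "domain_coords"))$cio
  }, numeric(1))
  expect_true(all(diff(cios) > 0))
  expect_lt(cios[1], 0.2)
  expect_gt(cios[3], 0.9)

  # global rigid motion of every chain leaves CIO unchanged
  ens <- make_isp_ensemble(20, 5, seed = 66)
  isps <- extract_isps(ens)
  dc <- attr(ens, "domain_coords")
  base <- cio(isps, dc)$cio
  R <- oracle_rotation(c(2, -1, 1), 1.3)
  dc_moved <- lapply(dc, function(x) sweep(x %*% t(R), 2, c(30, -12, 7), "+"))
  expect_equal(cio(isps, dc_moved)$cio, base, tolerance = 1e-6)
  # instance order is irrelevant
  expect_equal(cio(isps[sample(nrow(isps)), ], dc)$cio, base,
               tolerance = 1e-12)
})

test_that("enrichment, hub classes and ISP set comparison follow their definitions", {
  expect_equal(enrichment(8, 2), 2)
  expect_equal(enrichment(5, 5), 0)
  expect_equal(enrichment(4, 8), -enrichment(8, 4))
  expect_error(enrichment(0, 5), "present in both")

  expect_equal(classify_hub(c(0, 3, 4, 7, 8, 20)),
               c("small", "small", "medium", "medium", "large", "large"))
  expect_error(classify_hub(-1), "non-negative")

  a <- c("A|B", "A|C")
  expect_equal(compare_isp_sets(a, a)$counts,
               c(common = 2L, only_a = 0L, only_b = 0L))
  m1 <- data.frame(x = "1.10.10.10", y = "2.60.40.10")
  m2 <- data.frame(x = "2.60.40.10", y = "1.10.10.10")
  expect_equal(compare_isp_sets(m1, m2)$counts[["common"]], 1L)
})

test_that("interaction graph export reports degrees and hub classes", {
  one <- data.frame(isp_key = "A|B", n_instances = 4L, homotypic = FALSE)
  g1 <- export_interaction_graph(one)
  expect_equal(nrow(g1$edges), 1)
  expect_equal(g1$nodes$n_partners, c(1L, 1L))
  expect_equal(g1$nodes$hub_class, c("small", "small"))

  star <- data.frame(isp_key = paste0("HUB|P", 1:9),
                     n_instances = 1L, homotypic = FALSE)
  gs <- export_interaction_graph(star)
  expect_equal(gs$nodes$hub_class[gs$nodes$node == "HUB"], "large")
  expect_equal(gs$nodes$n_partners[gs$nodes$node == "HUB"], 9L)

  set.seed(67)
  nodes <- sprintf("N%02d", 1:8)
  edges <- t(combn(nodes, 2))
  pick <- sample(nrow(edges), 12)
  summ <- data.frame(isp_key = apply(edges[pick, ], 1, function(p)
    paste(sort(p), collapse = "|")), n_instances = 1L)
  gr <- export_interaction_graph(summ)
  deg <- table(c(edges[pick, 1], edges[pick, 2]))
  expect_equal(gr$nodes$n_partners[match(names(deg), gr$nodes$node)],
               unname(as.integer(deg)))
})
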