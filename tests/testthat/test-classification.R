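test_that("CATH codes parse, format and report their level", {
  h <- cath_code("3.40.50.300")
  expect_equal(cath_level(h), "H")
  expect_equal(format(h), "3.40.50.300")
  t <- cath_code("3.40.50")
  expect_equal(cath_level(t), "T")
  expect_equal(format(cath_topology(h)), "3.40.50")
  expect_error(cath_code("3.40"), "malformed")
  expect_error(cath_code("3.40.x.1"), "malformed")
})

test_that("label assignment routes H, T and none with deterministic tie-breaks", {
  expect_equal(assign_label(data.frame(query = character(0),
                                       target_code = character(0),
                                       score = numeric(0),
                                       kind = character(0)))$level, "none")

  nn <- data.frame(query = "d1", target_code = "3.40.50.300", score = 0.9,
                   kind = "nearest_neighbour")
  lab <- assign_label(nn)
  expect_equal(lab$level, "T")
  expect_equal(format(lab$code), "3.40.50")

  hit <- data.frame(query = "d1", target_code = "3.40.50.300", score = 0.8,
                    kind = "structure_search")
  labh <- assign_label(hit)
  expect_equal(labh$level, "H")
  expect_equal(format(labh$code), "3.40.50.300")

  # below score_min a structure hit cannot label at all
  expect_equal(assign_label(transform(hit, score = 0.3))$level, "none")

  tie <- data.frame(query = "d1",
                    target_code = c("1.10.8.10", "1.10.10.10"),
                    score = c(0.8, 0.8), kind = "structure_search")
  expect_equal(format(assign_label(tie)$code), "1.10.10.10")

  mixed <- data.frame(query = "d1",
                      target_code = c("3.40.50", "2.60.40.10"),
                      score = c(0.9, 0.6),
                      kind = c("structure_search", "structure_search"))
  labm <- assign_label(mixed)
  expect_equal(labm$level, "H")
  expect_equal(format(labm$code), "2.60.40.10")
  expect_error(assign_label(transform(hit, kind = "blast")), "unknown hit kind")
})

test_that("cluster label propagation partitions clusters completely", {
  clusters <- data.frame(
    cluster_id = rep(c("c1", "c2", "c3"), times = c(3, 5, 2)),
    domain_id = paste0("d", 1:10))
  labels <- setNames(c("H", rep("none", 9)), paste0("d", 1:10))
  part <- propagate_cluster_labels(clusters, labels)
  expect_equal(part$labelled_clusters, "c1")
  expect_setequal(part$unlabelled_clusters, c("c2", "c3"))
  expect_setequal(c(part$labelled_clusters, part$unlabelled_clusters),
                  unique(clusters$cluster_id))
  expect_equal(unname(part$member_counts[c("c1", "c2", "c3")]), c(3L, 5L, 2L))
  expect_error(propagate_cluster_labels(clusters, labels[-1]), "no label record")

  set.seed(41)
  gen <- data.frame(cluster_id = rep(sprintf("g%02d", 1:10), each = 3),
                    domain_id = sprintf("gd%02d", 1:30))
  planted <- rep(c("H", "none"), times = c(7, 3))[order(runif(10))]
  lv <- setNames(rep("none", 30), gen$domain_id)
  for (i in 1:10) if (planted[i] == "H")
    lv[gen$domain_id[gen$cluster_id == sprintf("g%02d", i)][1]] <- "H"
  p2 <- propagate_cluster_labels(gen, lv)
  expect_length(p2$labelled_clusters, 7)
  expect_length(p2$unlabelled_clusters, 3)
})

test_that("HMM validation distinguishes superfamily, fold and mismatch", {
  expect_equal(validate_with_hmm("3.40.50.300", "3.40.50.300"),
               "confirmed_superfamily")
  expect_equal(validate_with_hmm("3.40.50.300", "3.40.50.720"),
               "confirmed_fold")
  expect_equal(validate_with_hmm("3.40.50.300", "2.60.40.10"), "unconfirmed")
  expect_equal(validate_with_hmm("3.40.50.300", NULL), "no_hmm_hit")
  # T-level structure label against an H-level HMM hit: fold agreement
  expect_equal(validate_with_hmm("3.40.50", "3.40.50.300"), "confirmed_fold")
  # fold-level symmetry: swapping the H digits never breaks a fold match
  expect_equal(validate_with_hmm("3.40.50.720", "3.40.50.300"),
               "confirmed_fold")
})

test_that("plDDT bins follow the AFDB boundaries with closed lower bounds", {
  expect_equal(plddt_bin(92), "very_high")
  expect_equal(plddt_bin(90), "very_high")
  expect_equal(plddt_bin(70), "high")
  expect_equal(plddt_bin(50), "low")
  expect_equal(plddt_bin(49.99), "very_low")
  expect_error(plddt_bin(101), "\\[0, 100\\]")
  expect_error(plddt_bin(-2), "\\[0, 100\\]")
  # total monotone step function over the whole range
  grid <- seq(0, 100, by = 0.25)
  bins <- plddt_bin(grid)
  lev <- c(very_low = 1, low = 2, high = 3, very_high = 4)
  expect_true(all(diff(lev[bins]) >= 0))
})
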