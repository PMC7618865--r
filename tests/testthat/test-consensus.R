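test_that("domain IoU follows set arithmetic", {
  expect_equal(domain_iou(1:100, 1:100), 1.0)
  expect_equal(domain_iou(1:100, 51:150), 50 / 150)
  expect_equal(domain_iou(c(1:50, 120:180), 1:60), 50 / 121)
  expect_error(domain_iou(integer(0), 1:5), "nonempty")
})

test_that("matching picks the maximum-IoU assignment above the threshold", {
  x <- parse_chopping("1-100,101-200")
  m_id <- match_choppings(x, x)
  expect_equal(m_id$i, 1:2)
  expect_equal(m_id$j, 1:2)
  expect_equal(m_id$iou, c(1, 1))

  y <- parse_chopping("1-200")
  expect_equal(nrow(match_choppings(x, y, iou_min = 0.7)), 0)
  m_low <- match_choppings(x, y, iou_min = 0.4)
  expect_equal(nrow(m_low), 1)
  expect_equal(m_low$iou, 0.5)
})

test_that("matching agrees with the exhaustive assignment oracle", {
  set.seed(7)
  for (rep in 1:40) {
    triple <- random_chopping_triple()
    x <- triple[[1]]; y <- triple[[2]]
    for (thr in c(0.5, 0.7)) {
      got <- match_choppings(x, y, thr)
      ora <- oracle_match(x, y, thr)
      expect_equal(got[c("i", "j")], ora, ignore_attr = TRUE)
    }
  }
})

test_that("three-way consensus votes residues and tiers confidence", {
  # all three agree exactly
  m <- parse_chopping("1-100,101-200")
  r <- consensus_assign(m, m, m)
  expect_length(r$domains, 2)
  expect_true(all(vapply(r$domains, `[[`, "", "confidence") == "high"))
  expect_length(r$ndr_residues, 0)

  # per-residue vote across jittered boundaries
  r2 <- consensus_assign(parse_chopping("1-100"), parse_chopping("3-98"),
                         parse_chopping("5-103"))
  expect_length(r2$domains, 1)
  expect_identical(r2$domains[[1]]$residues, 3:100)
  expect_equal(r2$domains[[1]]$confidence, "high")
  expect_identical(r2$ndr_residues, c(1:2, 101:103))

  # 2-vs-1 split: two medium domains from the agreeing pair
  r3 <- consensus_assign(parse_chopping("1-100,101-200"),
                         parse_chopping("1-100,101-200"),
                         parse_chopping("1-200"))
  expect_length(r3$domains, 2)
  expect_true(all(vapply(r3$domains, `[[`, "", "confidence") == "medium"))
  expect_identical(r3$domains[[1]]$residues, 1:100)
  expect_identical(r3$domains[[2]]$residues, 101:200)
})

test_that("consensus voting drops short groups and reports chain NDR", {
  # voted intersection shorter than min_len is discarded
  r <- consensus_assign(parse_chopping("1-30"), parse_chopping("11-40"),
                        parse_chopping("200-260"), min_len = 25)
  expect_length(r$domains, 0)

  fx <- make_chain(c(60, 60), seed = 3)
  m <- fx$chopping
  r2 <- consensus_assign(m, m, m, chain = fx$chain)
  expect_length(r2$domains, 2)
  expect_identical(r2$ndr_residues, 61:65)  # the linker
  expect_true(all(vapply(r2$domains, `[[`, 0, "avg_plddt") >= 90))
  bad <- chopping(list(matrix(c(1, 200), ncol = 2)))
  expect_error(consensus_assign(m, m, bad, chain = fx$chain), "absent from chain")
})

test_that("consensus is invariant to the order of input methods", {
  set.seed(11)
  for (rep in 1:25) {
    tr <- random_chopping_triple()
    base <- consensus_assign(tr[[1]], tr[[2]], tr[[3]])
    for (p in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
      alt <- consensus_assign(tr[[p[1]]], tr[[p[2]]], tr[[p[3]]])
      expect_equal(lapply(base$domains, `[[`, "residues"),
                   lapply(alt$domains, `[[`, "residues"))
      expect_identical(base$ndr_residues, alt$ndr_residues)
    }
  }
})

test_that("raising the agreement threshold never adds consensus domains", {
  set.seed(13)
  for (rep in 1:20) {
    tr <- random_chopping_triple()
    n_dom <- vapply(c(0.5, 0.7, 0.9), function(thr)
      length(consensus_assign(tr[[1]], tr[[2]], tr[[3]], iou_min = thr)$domains),
      integer(1))
    expect_true(all(diff(n_dom) <= 0))
  }
})

test_that("domains plus NDR partition the chain exactly", {
  set.seed(17)
  for (rep in 1:20) {
    tr <- random_chopping_triple()
    r <- consensus_assign(tr[[1]], tr[[2]], tr[[3]])
    pieces <- c(unlist(lapply(r$domains, `[[`, "residues")), r$ndr_residues)
    expect_false(anyDuplicated(pieces) > 0)
    expect_setequal(pieces, unique(unlist(lapply(tr, function(ch)
      unlist(chopping_residues(ch))))))
  }
})

test_that("target summaries recover composition and NDR fractions", {
  one <- consensus_assign(parse_chopping("1-100"), parse_chopping("1-100"),
                          parse_chopping("1-100"))
  s1 <- summarize_targets(rep(list(one), 10))
  expect_equal(unname(s1$fractions["single"]), 1.0)

  two <- consensus_assign(parse_chopping("1-100,101-200"),
                          parse_chopping("1-100,101-200"),
                          parse_chopping("1-100,101-200"))
  none <- consensus_assign(parse_chopping("1-30"), parse_chopping("50-80"),
                           parse_chopping("100-130"))
  s3 <- summarize_targets(list(one, two, none))
  expect_equal(unname(s3$fractions), rep(1 / 3, 3))
  expect_equal(unname(s3$counts), c(1L, 1L, 1L))
  expect_equal(s3$ndr_fraction[3], 1.0)
})
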