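# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive implementations (exhaustive enumeration, explicit
# set arithmetic) that share no code with the package internals.

# All permutations of 1..n as a matrix (rows), lexicographic order.
perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  out <- NULL
  for (i in seq_len(n)) {
    sub <- perms(n - 1L)
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Exhaustive maximum-total-IoU one-to-one matching between two choppings,
# restricted to pairs with IoU >= iou_min. Enumerates every injective
# assignment of a subset of x-domains onto y-domains.
oracle_match <- function(x, y, iou_min = 0.7) {
  rx <- chopping_residues(x); ry <- chopping_residues(y)
  nx <- length(rx); ny <- length(ry)
  if (nx == 0L || ny == 0L)
    return(data.frame(i = integer(0), j = integer(0)))
  iou <- matrix(0, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny))
    iou[i, j] <- length(intersect(rx[[i]], ry[[j]])) /
      length(union(rx[[i]], ry[[j]]))
  best_total <- -Inf; best_pairs <- NULL
  k_max <- min(nx, ny)
  for (k in 0:k_max) {
    if (k == 0L) { cand_sets <- list(integer(0)) } else {
      cand_sets <- utils::combn(nx, k, simplify = FALSE)
    }
    for (xs in cand_sets) {
      if (k == 0L) {
        if (0 > best_total) { best_total <- 0; best_pairs <- cbind(integer(0), integer(0)) }
        next
      }
      for (ys in utils::combn(ny, k, simplify = FALSE)) {
        pm <- if (k == 1L) matrix(1L) else perms(k)
        for (r in seq_len(nrow(pm))) {
          js <- ys[pm[r, ]]
          vals <- iou[cbind(xs, js)]
          if (all(vals >= iou_min)) {
            tot <- sum(vals)
            if (tot > best_total + 1e-12) {
              best_total <- tot
              best_pairs <- cbind(xs, js)
            }
          }
        }
      }
    }
  }
  ord <- order(best_pairs[, 1])
  data.frame(i = best_pairs[ord, 1], j = best_pairs[ord, 2])
}

# Brute-force consensus: oracle matchings for the three pairs, triple
# detection, greedy medium groups, explicit per-residue voting with
# logical masks over the residue range.
oracle_consensus <- function(m1, m2, m3, iou_min = 0.7, min_len = 25) {
  chops <- list(m1, m2, m3)
  res <- lapply(chops, chopping_residues)
  all_res <- sort(unique(unlist(res)))
  mm <- list(`12` = oracle_match(m1, m2, iou_min),
             `13` = oracle_match(m1, m3, iou_min),
             `23` = oracle_match(m2, m3, iou_min))
  iou_of <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  triples <- list()
  used <- list(rep(FALSE, length(res[[1]])), rep(FALSE, length(res[[2]])),
               rep(FALSE, length(res[[3]])))
  for (r in seq_len(nrow(mm$`12`))) {
    i <- mm$`12`$i[r]; j <- mm$`12`$j[r]
    k13 <- mm$`13`$j[mm$`13`$i == i]
    k23 <- mm$`23`$j[mm$`23`$i == j]
    if (length(k13) == 1L && length(k23) == 1L && k13 == k23) {
      triples[[length(triples) + 1L]] <- c(i, j, k13)
      used[[1]][i] <- TRUE; used[[2]][j] <- TRUE; used[[3]][k13] <- TRUE
    }
  }
  leftover <- list()
  add_left <- function(mp, ms, df) {
    for (r in seq_len(nrow(df))) {
      a <- df$i[r]; b <- df$j[r]
      if (used[[ms[1]]][a] || used[[ms[2]]][b]) next
      leftover[[length(leftover) + 1L]] <<- list(
        mp = mp, ms = ms, idx = c(a, b),
        iou = iou_of(res[[ms[1]]][[a]], res[[ms[2]]][[b]]))
    }
  }
  add_left(1L, c(1L, 2L), mm$`12`)
  add_left(2L, c(1L, 3L), mm$`13`)
  add_left(3L, c(2L, 3L), mm$`23`)
  pairs <- list()
  if (length(leftover) > 0L) {
    st <- vapply(leftover, function(l)
      sort(c(res[[l$ms[1]]][[l$idx[1]]][1], res[[l$ms[2]]][[l$idx[2]]][1])),
      numeric(2))
    ord <- order(-vapply(leftover, `[[`, numeric(1), "iou"),
                 st[1, ], st[2, ],
                 vapply(leftover, `[[`, numeric(1), "mp"),
                 vapply(leftover, function(l) l$idx[1], numeric(1)),
                 vapply(leftover, function(l) l$idx[2], numeric(1)))
    for (l in leftover[ord]) {
      if (used[[l$ms[1]]][l$idx[1]] || used[[l$ms[2]]][l$idx[2]]) next
      used[[l$ms[1]]][l$idx[1]] <- TRUE
      used[[l$ms[2]]][l$idx[2]] <- TRUE
      pairs[[length(pairs) + 1L]] <- l
    }
  }
  doms <- list()
  for (tr in triples) {
    votes <- table(c(res[[1]][[tr[1]]], res[[2]][[tr[2]]], res[[3]][[tr[3]]]))
    kept <- as.integer(names(votes)[votes >= 2])
    if (length(kept) >= min_len)
      doms[[length(doms) + 1L]] <- list(residues = sort(kept), confidence = "high")
  }
  for (p in pairs) {
    kept <- intersect(res[[p$ms[1]]][[p$idx[1]]], res[[p$ms[2]]][[p$idx[2]]])
    if (length(kept) >= min_len)
      doms[[length(doms) + 1L]] <- list(residues = sort(kept), confidence = "medium")
  }
  doms <- doms[order(vapply(doms, function(d) d$residues[1], integer(1)))]
  list(domains = doms,
       ndr = setdiff(all_res, unlist(lapply(doms, `[[`, "residues"))))
}

# Random chopping triple on a chain of <= 300 residues, <= 5 domains per
# method: jittered boundaries, occasional domain merges and drops.
random_chopping_triple <- function() {
  n_dom <- sample(1:4, 1)
  lens <- sample(30:65, n_dom, replace = TRUE)
  gaps <- sample(0:8, n_dom, replace = TRUE)
  starts <- cumsum(c(1L, (lens + gaps)[-n_dom]))
  ends <- starts + lens - 1L
  make_method <- function() {
    segs <- cbind(starts, ends)
    if (n_dom >= 2L && runif(1) < 0.2) {       # merge two adjacent domains
      i <- sample(n_dom - 1L, 1)
      segs[i, 2] <- segs[i + 1L, 2]
      segs <- segs[-(i + 1L), , drop = FALSE]
    }
    if (nrow(segs) >= 2L && runif(1) < 0.15)   # drop one domain
      segs <- segs[-sample(nrow(segs), 1), , drop = FALSE]
    for (r in seq_len(nrow(segs))) {           # jitter without overlap
      lo <- if (r == 1L) 1L else segs[r - 1L, 2] + 1L
      hi <- if (r == nrow(segs)) segs[r, 2] + 4L else segs[r + 1L, 1] - 1L
      segs[r, 1] <- max(lo, segs[r, 1] + sample(-4:4, 1))
      segs[r, 2] <- min(hi, max(segs[r, 1] + 5L, segs[r, 2] + sample(-4:4, 1)))
    }
    chopping(lapply(seq_len(nrow(segs)), function(r)
      matrix(segs[r, ], ncol = 2)))
  }
  list(make_method(), make_method(), make_method())
}

# Rotation matrix from axis/angle, written independently of the package
# (quaternion form rather than Rodrigues).
oracle_rotation <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  q <- c(cos(angle / 2), sin(angle / 2) * axis)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Compare a consensus_result with an oracle_consensus result.
consensus_equal <- function(pkg, ora) {
  if (length(pkg$domains) != length(ora$domains)) return(FALSE)
  for (k in seq_along(pkg$domains)) {
    if (!identical(pkg$domains[[k]]$residues, ora$domains[[k]]$residues))
      return(FALSE)
    if (pkg$domains[[k]]$confidence != ora$domains[[k]]$confidence)
      return(FALSE)
  }
  identical(pkg$ndr_residues, as.integer(ora$ndr))
}
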