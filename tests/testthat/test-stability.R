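# The four per-gene algorithms on hand-computable toys plus the structural
# invariants they share.

test_that("delta-Ct mSD matches the hand-computed 3-gene toy", {
  r <- delta_ct_msd(toy_ct())
  # A-B constant => SD 0; A-C and B-C are (0,-1,1,-1)-type vectors
  expect_equal(unname(r$extras$pair_sd["A", "B"]), 0)
  expect_equal(unname(r$extras$pair_sd["A", "C"]), 0.9574271, tolerance = 1e-6)
  expect_equal(unname(r$scores["A"]), 0.4787136, tolerance = 1e-6)
  expect_equal(unname(r$scores["B"]), 0.4787136, tolerance = 1e-6)
  expect_equal(unname(r$scores["C"]), 0.9574271, tolerance = 1e-6)
  expect_identical(r$orientation, "lower_is_stabler")
  expect_identical(r$ranking[3], "C")
})

test_that("delta-Ct requires at least two genes and two samples", {
  m <- matrix(c(20, 21), 1, 2, dimnames = list("A", c("s1", "s2")))
  expect_error(delta_ct_msd(ct_matrix(m)), ">= 2 genes")
})

test_that("duplicating every sample leaves pairwise SDs unchanged", {
  ct <- toy_ct()
  dup <- cbind(ct$ct, ct$ct)
  colnames(dup) <- paste0("s", 1:8)
  r1 <- delta_ct_msd(ct)
  r2 <- delta_ct_msd(ct_matrix(dup))
  # identical duplicates change only the SD denominator (n-1): recompute
  # the expected rescale by brute force on one pair
  d <- ct$ct["A", ] - ct$ct["C", ]
  expect_equal(unname(r2$extras$pair_sd["A", "C"]), sd(c(d, d)),
               tolerance = 1e-12)
  expect_identical(r1$ranking, r2$ranking)
})

test_that("BestKeeper reproduces the descriptive-statistics toy", {
  m <- rbind(G = c(20, 22, 24, 26),
             H = c(25, 25.5, 26, 26.5))
  colnames(m) <- paste0("s", 1:4)
  bk <- bestkeeper(ct_matrix(m))
  st <- bk$extras$stats
  expect_equal(st$AM[st$gene == "G"], 23)
  expect_equal(st$SD[st$gene == "G"], 2.0)           # (3+1+1+3)/4
  expect_equal(st$CV[st$gene == "G"], 8.695652, tolerance = 1e-6)
  # classic mode uses the n-1 standard deviation instead
  bk2 <- bestkeeper(ct_matrix(m), sd_mode = "classic")
  expect_equal(bk2$extras$stats$SD[1], sd(m["G", ]))
})

test_that("BestKeeper index and correlations behave on degenerate panels", {
  # two identical genes: index equals their Ct, correlations are 1
  m <- rbind(A = c(20, 21, 23, 25), B = c(20, 21, 23, 25))
  colnames(m) <- paste0("s", 1:4)
  bk <- bestkeeper(ct_matrix(m))
  expect_equal(unname(bk$extras$index), unname(m["A", ]), tolerance = 1e-12)
  expect_equal(unname(bk$scores), c(1, 1), tolerance = 1e-12)
  # constant gene: SD = CV = 0, r undefined, ranked last with a warning
  m2 <- rbind(A = c(20, 21, 23, 25), B = c(25, 25, 25, 25))
  colnames(m2) <- paste0("s", 1:4)
  expect_warning(bk2 <- bestkeeper(ct_matrix(m2)), "undefined")
  expect_equal(bk2$extras$stats$SD[2], 0)
  expect_true(is.na(bk2$scores["B"]))
  expect_identical(bk2$ranking[2], "B")
})

test_that("geNorm removes the noisy gene first and ties the final pair", {
  q <- q_of(toy_ct())
  g <- genorm(q)
  expect_identical(g$extras$trace$removed, "C")
  expect_equal(unname(g$scores["C"]), 0.9574271, tolerance = 1e-6)
  # after C's removal, A and B have a constant log ratio: mutual V = 0
  expect_equal(unname(g$scores["A"]), 0)
  expect_equal(unname(g$scores["B"]), 0)
  expect_identical(g$ranking, c("A", "B", "C"))
  expect_true(setequal(g$ties[[1]], c("A", "B")))
})

test_that("scalar-multiple profiles give all-zero M and full-panel ties", {
  base <- c(1, 0.5, 0.25, 0.8)
  m <- rbind(A = 25 - log2(base), B = 28 - log2(base), C = 21 - log2(base))
  colnames(m) <- paste0("s", 1:4)
  g <- genorm(q_of(ct_matrix(m)))
  expect_equal(unname(g$scores), rep(0, 3), tolerance = 1e-12)
})

test_that("full-panel geNorm M equals delta-Ct mSD when E = 2", {
  for (seed in 1:5) {
    ct <- random_ct(sample(4:9, 1), sample(4:12, 1), seed = seed)
    msd <- delta_ct_msd(ct)$scores
    m0 <- genorm(q_of(ct))$extras$initial_m
    expect_equal(m0[names(msd)], msd, tolerance = 1e-9)
  }
})

test_that("geNorm ranking is exactly the reverse removal order", {
  ct <- random_ct(8, 10, seed = 21)
  g <- genorm(q_of(ct))
  removed <- g$extras$trace$removed
  expect_identical(rev(g$ranking[-(1:2)]), removed)
  expect_setequal_chr(g$ranking[1:2], setdiff(ct$gene_ids, removed))
})

test_that("the V-curve flags how many genes suffice", {
  # gene 3 identical to gene 1: adding it to NF2 changes nothing much;
  # construct 3 near-identical stable genes plus noise genes
  set.seed(9)
  base <- rnorm(8, 0, 1)
  m <- rbind(S1 = 25 - base, S2 = 27 - base, S3 = 23 - base,
             N1 = 25 - rnorm(8, 0, 1.5), N2 = 26 - rnorm(8, 0, 1.5))
  colnames(m) <- paste0("s", 1:8)
  q <- q_of(ct_matrix(m))
  vc <- genorm_v_curve(q, genorm(q))
  expect_equal(vc$recommended_n, 2)
  expect_true(vc$v["V2/3"] < 0.15)
  # a gene whose quantity equals NF_n sample-by-sample adds zero variation
  lq <- rbind(A = base, B = base + 2, C = (base + (base + 2)) / 2,
              D = rnorm(8))
  m2 <- 25 - lq
  colnames(m2) <- paste0("s", 1:8)
  q2 <- q_of(ct_matrix(m2))
  vc2 <- genorm_v_curve(q2, c("A", "B", "C", "D"))
  expect_equal(unname(vc2$v["V2/3"]), 0, tolerance = 1e-12)
})

test_that("NormFinder gives zero SV to identical profiles and tracks shifts", {
  base <- c(24, 25, 26, 23, 24.5, 25.5)
  m <- rbind(A = base, B = base + 2, C = base - 1)
  colnames(m) <- paste0("s", 1:6)
  nf <- normfinder(q_of(ct_matrix(m)))
  expect_equal(unname(nf$scores), rep(0, 3), tolerance = 1e-12)

  # grouped: a pure between-group shift of +/-0.5 log2 units on one gene of
  # a G-gene panel leaves, after sample centering, |z| = 0.5 * (G-1)/G for
  # that gene and 0.5/G for the others; intra-group variance is zero
  G <- 4
  m2 <- matrix(25, G, 6, dimnames = list(paste0("g", 1:G), paste0("s", 1:6)))
  m2["g1", 1:3] <- 25 - 0.5   # higher expression in group 1
  m2["g1", 4:6] <- 25 + 0.5
  sheet <- sample_sheet(data.frame(sample_id = paste0("s", 1:6),
                                   group = rep(c("a", "b"), each = 3),
                                   is_control = rep(c(TRUE, FALSE), each = 3)))
  nf2 <- normfinder(q_of(ct_matrix(m2)), sheet)
  expect_equal(unname(nf2$scores["g1"]), 0.5 * (G - 1) / G, tolerance = 1e-9)
  expect_equal(unname(nf2$scores["g2"]), 0.5 / G, tolerance = 1e-9)
  expect_identical(nf2$ranking[G], "g1")
})

test_that("NormFinder enforces its minimum panel and group sizes", {
  m <- matrix(25 + rnorm(4), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(normfinder(q_of(ct_matrix(m))), ">= 3")
  ct <- random_ct(4, 5, seed = 2)
  sheet <- sample_sheet(data.frame(sample_id = paste0("s", 1:5),
                                   group = c("a", "a", "a", "b", "b"),
                                   is_control = c(TRUE, TRUE, TRUE, FALSE, FALSE)))
  expect_error(normfinder(q_of(ct), sheet), "more than two samples per group")
})

test_that("adding noise to one gene of an identical panel raises only its SV", {
  worst_is_noisy <- 0
  for (seed in 1:100) {
    set.seed(seed)
    base <- rnorm(9, 25, 1)
    m <- rbind(A = base, B = base + 1, C = base - 1, D = base + 0.5)
    m["D", ] <- m["D", ] + rnorm(9, 0, 0.4)
    colnames(m) <- paste0("s", 1:9)
    nf <- normfinder(q_of(ct_matrix(m)))
    worst_is_noisy <- worst_is_noisy + (nf$ranking[4] == "D")
  }
  expect_gte(worst_is_noisy, 99)
})

test_that("all four algorithms are invariant to gene and sample permutation", {
  ct <- random_ct(6, 8, seed = 31)
  set.seed(1)
  gp <- sample(ct$gene_ids)
  sp <- sample(ct$sample_ids)
  perm <- ct_matrix(ct$ct[gp, sp])
  for (fn in list(function(x) delta_ct_msd(x)$scores,
                  function(x) bestkeeper(x)$scores,
                  function(x) genorm(q_of(x))$scores,
                  function(x) normfinder(q_of(x))$scores)) {
    a <- fn(ct); b <- fn(perm)
    expect_equal(b[names(a)], a, tolerance = 1e-9)
  }
})

test_that("per-sample loading offsets cancel everywhere except BestKeeper", {
  ct <- random_ct(6, 8, seed = 32)
  offs <- seq(-1.5, 2, length.out = 8)
  shifted <- ct_matrix(sweep(ct$ct, 2, offs, "+"))
  expect_equal(delta_ct_msd(shifted)$scores, delta_ct_msd(ct)$scores,
               tolerance = 1e-9)
  expect_equal(genorm(q_of(shifted))$scores, genorm(q_of(ct))$scores,
               tolerance = 1e-9)
  expect_equal(normfinder(q_of(shifted))$scores, normfinder(q_of(ct))$scores,
               tolerance = 1e-9)
  # BestKeeper's raw-Ct statistics do change (the documented exception)
  expect_false(isTRUE(all.equal(bestkeeper(shifted)$extras$stats$SD,
                                bestkeeper(ct)$extras$stats$SD,
                                tolerance = 1e-9)))
})

test_that("a per-gene constant shifts BestKeeper's CV but nothing else", {
  ct <- random_ct(5, 8, seed = 33)
  shifted <- ct$ct
  shifted["g1", ] <- shifted["g1", ] + 4
  sct <- ct_matrix(shifted)
  expect_equal(delta_ct_msd(sct)$scores, delta_ct_msd(ct)$scores,
               tolerance = 1e-9)
  expect_equal(genorm(q_of(sct))$scores, genorm(q_of(ct))$scores,
               tolerance = 1e-9)
  expect_equal(normfinder(q_of(sct))$scores, normfinder(q_of(ct))$scores,
               tolerance = 1e-9)
  cv1 <- bestkeeper(ct)$extras$stats$CV
  cv2 <- bestkeeper(sct)$extras$stats$CV
  expect_false(isTRUE(all.equal(cv1[1], cv2[1])))
})
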