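test_that("normalization factors are geometric means anchored at the control", {
  p <- toy_responsive_panel()
  q <- q_of(p$ct)
  nf <- normalization_factor(q, c("F1", "F2", "F3"), p$sheet)
  expect_equal(unname(nf), rep(1, 4), tolerance = 1e-12)
  # geometric-mean symmetry: quantities (0.5, 2) and (0.5, 0.5, 4) both give 1
  lq <- rbind(A = c(0, -1), B = c(0, 1), C = c(0, 2))  # log2 Q relative s1
  m <- 25 - lq
  colnames(m) <- c("s1", "s2")
  sheet <- sample_sheet(data.frame(sample_id = c("s1", "s2"),
                                   group = c("ctl", "trt"),
                                   is_control = c(TRUE, FALSE)))
  qq <- q_of(ct_matrix(m))
  expect_equal(unname(normalization_factor(qq, c("A", "B"), sheet)["s2"]), 1,
               tolerance = 1e-12)
  lq3 <- rbind(A = c(0, -1), B = c(0, -1), C = c(0, 2))
  q3 <- q_of(ct_matrix(structure(25 - lq3,
                                 dimnames = list(c("A", "B", "C"),
                                                 c("s1", "s2")))))
  expect_equal(unname(normalization_factor(q3, c("A", "B", "C"), sheet)["s2"]),
               1, tolerance = 1e-12)
  expect_error(normalization_factor(qq, character(0), sheet), "empty")
  expect_error(normalization_factor(qq, "Z", sheet), "not in panel")
})

test_that("a target one cycle below the calibrator mean is a two-fold change", {
  m <- rbind(T1 = c(25, 25, 24, 24),
             R1 = c(22, 22, 22, 22))
  colnames(m) <- paste0("s", 1:4)
  sheet <- sample_sheet(data.frame(sample_id = paste0("s", 1:4),
                                   group = c("ctl", "ctl", "trt", "trt"),
                                   is_control = c(TRUE, TRUE, FALSE, FALSE)))
  ct <- ct_matrix(m)
  q <- q_of(ct_matrix(m["R1", , drop = FALSE]))
  nf <- normalization_factor(q, "R1", sheet)
  rex <- relative_expression(ct, "T1", NULL, nf, sheet)
  expect_equal(rex$groups$mean_fold[rex$groups$group == "ctl"], 1)
  expect_equal(rex$groups$mean_fold[rex$groups$group == "trt"], 2,
               tolerance = 1e-12)
  expect_equal(rex$groups$se[rex$groups$group == "trt"], 0, tolerance = 1e-12)
})

test_that("a shared loading offset cancels between target and references", {
  m <- rbind(T1 = c(25, 25, 24, 24),
             R1 = c(22, 22, 22, 22),
             R2 = c(27, 27, 27, 27))
  colnames(m) <- paste0("s", 1:4)
  m_loaded <- m
  m_loaded[, "s3"] <- m_loaded[, "s3"] + 1   # one sample under-loaded
  sheet <- sample_sheet(data.frame(sample_id = paste0("s", 1:4),
                                   group = c("ctl", "ctl", "trt", "trt"),
                                   is_control = c(TRUE, TRUE, FALSE, FALSE)))
  folds <- lapply(list(m, m_loaded), function(mm) {
    ct <- ct_matrix(mm)
    q <- q_of(ct_matrix(mm[c("R1", "R2"), ]))
    nf <- normalization_factor(q, c("R1", "R2"), sheet)
    relative_expression(ct, "T1", NULL, nf, sheet)$samples$fold
  })
  expect_equal(folds[[1]], folds[[2]], tolerance = 1e-12)
})

test_that("group summaries report mean, SE over replicates and n", {
  set.seed(2)
  m <- rbind(T1 = 25 + rnorm(6, 0, 0.2), R1 = rep(22, 6))
  colnames(m) <- paste0("s", 1:6)
  sheet <- sample_sheet(data.frame(sample_id = paste0("s", 1:6),
                                   group = rep(c("ctl", "trt"), each = 3),
                                   is_control = rep(c(TRUE, FALSE), each = 3)))
  ct <- ct_matrix(m)
  rex <- relative_expression(ct, "T1", NULL, NULL, sheet)
  trt <- rex$samples$fold[rex$samples$group == "trt"]
  expect_equal(rex$groups$mean_fold[2], mean(trt))
  expect_equal(rex$groups$se[2], sd(trt) / sqrt(3))
  expect_equal(rex$groups$n, c(3, 3))
  expect_equal(rex$groups$mean_fold[1], 1, tolerance = 1e-12)
})

test_that("stable references recover a simulated fold better than unstable ones", {
  err_s <- err_u <- numeric(20)
  for (i in 1:20) {
    ds <- generate_dataset(synthetic_spec(seed = 500 + i))
    panel <- setdiff(ds$ct$gene_ids, "TGT1")
    q <- relative_quantities(ct_matrix(ds$ct$ct[panel, ]), ds$eff)
    nf_s <- normalization_factor(q, c("S1", "S2", "S3"), ds$sheet)
    nf_u <- normalization_factor(q, c("U4", "U5"), ds$sheet)
    f_s <- relative_expression(ds$ct, "TGT1", ds$eff, nf_s, ds$sheet)
    f_u <- relative_expression(ds$ct, "TGT1", ds$eff, nf_u, ds$sheet)
    err_s[i] <- abs(f_s$groups$mean_fold[f_s$groups$group == "treatB"] - 4)
    err_u[i] <- abs(f_u$groups$mean_fold[f_u$groups$group == "treatB"] - 4)
  }
  expect_lt(mean(err_s), mean(err_u))
})
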