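# Shared fixtures, built in code.

# The 3-gene hand toy: A and B differ by a constant; C wobbles.
toy_ct <- function() {
  m <- rbind(A = c(20, 21, 22, 23),
             B = c(25, 26, 27, 28),
             C = c(20, 22, 21, 24))
  colnames(m) <- paste0("s", 1:4)
  ct_matrix(m)
}

# Random complete Ct matrix in a plausible cycle range.
random_ct <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(stats::runif(n_genes * n_samples, 18, 34), n_genes, n_samples,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  ct_matrix(m)
}

# Quantity matrix straight from a Ct matrix with E = 2 everywhere.
q_of <- function(ct) relative_quantities(ct)

# A flat 4-gene panel with one treatment-responsive gene (doubles in the
# "treat" group); no noise. Used by the GrayNorm toys.
toy_responsive_panel <- function(fold_gene = "R1", log2_shift = 1) {
  samples <- c("c1", "c2", "t1", "t2")
  m <- matrix(25, 4, 4, dimnames = list(c("F1", "F2", "F3", fold_gene), samples))
  m[fold_gene, c("t1", "t2")] <- 25 - log2_shift  # lower Ct = more template
  sheet <- sample_sheet(data.frame(
    sample_id = samples,
    group = c("control", "control", "treat", "treat"),
    is_control = c(TRUE, TRUE, FALSE, FALSE)))
  list(ct = ct_matrix(m), sheet = sheet)
}

expect_setequal_chr <- function(a, b) expect_true(setequal(a, b))
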