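test_that("cell QC removes boundary cells: UMI <= 700 and mito >= 10%", {
  # cell 1: total exactly 700 (removed); cell 2: mito exactly 10% (removed);
  # cell 3: 701 UMIs, mito just under 10% (kept)
  counts <- cbind(c(650, 50, 0), c(895, 5, 100), c(631, 0, 70))
  rownames(counts) <- c("G1", "G2", "mt1")
  sce <- make_sce(counts, mito = c(FALSE, FALSE, TRUE))
  kept <- suppressMessages(filter_cells(sce))
  expect_equal(colnames(kept), "c003")
  expect_equal(unname(kept$total_counts), 701)
  expect_lt(kept$mito_frac, 0.10)
  rep <- attr(kept, "qc_report")
  expect_equal(rep$removed_low_umi + rep$removed_high_mito, 2)
})

test_that("gene filter removes genes detected in 3 or fewer cells", {
  counts <- rbind(in3 = c(1, 1, 1, 0, 0),
                  in4 = c(1, 2, 1, 5, 0),
                  zero = c(0, 0, 0, 0, 0))
  sce <- make_sce(counts)
  kept <- suppressMessages(filter_genes(sce))
  expect_equal(rownames(kept), "in4")
})

test_that("log-normalization follows ln(1 + count/total * 1e4)", {
  counts <- rbind(c(1, 2), c(9999, 19998))   # totals 10000, 20000
  sce <- log_normalize(make_sce(counts))
  ln <- as.matrix(SummarizedExperiment::assay(sce, "logcounts"))
  expect_equal(ln[1, 1], log(2))
  # doubling all counts of a cell leaves normalized values unchanged
  expect_equal(ln[, 1], ln[, 2], ignore_attr = TRUE)
  # zeros map to exact zeros
  counts2 <- rbind(c(0, 3), c(5, 4))
  ln2 <- as.matrix(SummarizedExperiment::assay(
    log_normalize(make_sce(counts2)), "logcounts"))
  expect_identical(ln2[1, 1], 0)
  # monotone in counts within a cell
  expect_true(ln2[1, 2] < ln2[2, 1] ||
                counts2[1, 2] / 7 > counts2[2, 1] / 5)
  expect_error(log_normalize(make_sce(rbind(c(0, 1), c(0, 2)))),
               "zero total")
})

test_that("variable-gene selection honours the mean window and dispersion", {
  set.seed(42)
  n <- 400
  # Poisson-like peers across a continuum of means (so every dispersion
  # bin is populated) vs one NB-inflated gene
  mus <- seq(1, 9, length.out = 60)
  peers <- t(sapply(mus, function(mu) rpois(n, mu)))
  inflated <- rnbinom(n, mu = 5, size = 0.5)
  lowmean <- rpois(n, 0.005)          # mean below 0.0125: always excluded
  constant <- rep(3, n)               # no dispersion: always excluded
  counts <- rbind(peers, inflated = inflated, lowmean = lowmean,
                  constant = constant)
  rownames(counts) <- c(paste0("peer", 1:60), "inflated", "lowmean",
                        "constant")
  sce <- make_sce(counts)
  # bypass library-size differences: normalize against constant totals
  SummarizedExperiment::assay(sce, "logcounts", withDimnames = FALSE) <-
    methods::as(Matrix::Matrix(log1p(counts), sparse = TRUE), "CsparseMatrix")
  hvg <- find_variable_genes(sce, mean_high = 10)
  expect_true("inflated" %in% hvg)
  expect_false("lowmean" %in% hvg)
  expect_false("constant" %in% hvg)

  # brute-force recomputation of the binned dispersion statistic
  ln <- log1p(counts)
  mu <- rowMeans(ln)
  v <- apply(ln, 1, var)
  d <- log(v / mu)
  expressed <- mu > 0 & is.finite(d)
  brk <- seq(min(mu[mu > 0]), max(mu[mu > 0]), length.out = 21)
  bin <- cut(mu, brk, include.lowest = TRUE)
  z <- rep(NA_real_, length(mu))
  for (lv in levels(bin)) {
    i <- which(bin == lv & expressed)
    if (length(i) >= 2 && sd(d[i]) > 0) z[i] <- (d[i] - mean(d[i])) / sd(d[i])
    else if (length(i)) z[i] <- 0
  }
  # compare away from the cutoff so float noise in the two variance
  # implementations cannot flip boundary genes
  clear <- !is.na(z) & abs(z - 0.5) > 0.01
  manual <- rownames(counts)[which(mu > 0.0125 & mu < 10 & clear & z > 0.5)]
  expect_setequal(intersect(hvg, rownames(counts)[clear]), manual)

  # plain standard-deviation mode
  hvg_sd <- find_variable_genes(sce, mean_high = 10, method = "sd")
  expect_setequal(hvg_sd,
                  rownames(counts)[mu > 0.0125 & mu < 10 &
                                     apply(ln, 1, sd) > 0.5])
})

test_that("covariate regression matches the closed-form OLS solution", {
  set.seed(7)
  n <- 5
  libsize <- c(1000, 1500, 2000, 2500, 3000)
  mito <- c(0.01, 0.03, 0.02, 0.05, 0.04)
  y1 <- c(0.5, 1.2, 0.8, 1.9, 1.4)              # hand-built gene
  y2 <- 2 + 0.003 * libsize                      # exact function of libsize
  counts <- rbind(g1 = rep(1, n), g2 = rep(1, n))
  sce <- make_sce(counts)
  SummarizedExperiment::assay(sce, "logcounts", withDimnames = FALSE) <-
    methods::as(Matrix::Matrix(rbind(g1 = y1, g2 = y2), sparse = TRUE),
                "CsparseMatrix")
  sce$total_counts <- libsize
  sce$mito_frac <- mito
  sm <- regress_and_scale(sce, c("g1", "g2"))
  # independent normal-equation oracle for g1
  x <- cbind(1, libsize, mito)
  beta <- solve(t(x) %*% x, t(x) %*% y1)
  res <- as.vector(y1 - x %*% beta)
  expect_equal(unname(sm["g1", ]), res / sd(res), tolerance = 1e-10)
  expect_equal(mean(sm["g1", ]), 0, tolerance = 1e-10)
  expect_equal(sd(sm["g1", ]), 1, tolerance = 1e-10)
  # exact linear function of a covariate: all-zero row
  expect_equal(unname(sm["g2", ]), rep(0, n), tolerance = 1e-10)
})

test_that("genes uncorrelated with covariates are simply standardized", {
  set.seed(8)
  n <- 200
  y <- rnorm(n)
  sce <- make_sce(rbind(g = rep(1, n)))
  SummarizedExperiment::assay(sce, "logcounts", withDimnames = FALSE) <-
    methods::as(Matrix::Matrix(rbind(g = y), sparse = TRUE), "CsparseMatrix")
  sce$total_counts <- rep(5000, n)   # zero-variance: dropped with warning
  sce$mito_frac <- rnorm(n, 0.05, 1e-3)
  expect_warning(sm <- regress_and_scale(sce, "g"), "zero variance")
  expect_equal(mean(sm["g", ]), 0, tolerance = 1e-10)
  expect_equal(sd(sm["g", ]), 1, tolerance = 1e-10)
})

test_that("PCA recovers the analytic eigenstructure of a 2-gene toy", {
  # sample covariance exactly [[2,1],[1,2]]: eigenvalues 3 and 1
  v1 <- c(1, 1) / sqrt(2); v2 <- c(1, -1) / sqrt(2)
  s1 <- c(1, 1, -1, -1) * 1.5
  s2 <- c(1, -1, 1, -1) * sqrt(3) / 2
  x <- outer(s1, v1) + outer(s2, v2)             # cells x genes
  sm <- t(x)
  dimnames(sm) <- list(c("g1", "g2"), paste0("c", 1:4))
  p <- run_pca(sm, 2)
  expect_equal(unname(p$sdev^2), c(3, 1), tolerance = 1e-12)
  expect_equal(unname(p$var_explained), c(0.75, 0.25), tolerance = 1e-12)
  # a single varying gene explains everything
  sm1 <- rbind(g1 = c(-3, -1, 1, 3), g2 = rep(0, 4), g3 = rep(0, 4))
  colnames(sm1) <- paste0("c", 1:4)
  p1 <- run_pca(sm1, 2)
  expect_gt(p1$var_explained[1], 0.999)
  expect_error(run_pca(sm1, 4), "exceeds")
})

test_that("PCA is equivariant under cell permutations and has decreasing
           reconstruction error", {
  set.seed(10)
  sm <- matrix(rnorm(40 * 30), 40, 30,
               dimnames = list(paste0("g", 1:40), paste0("c", 1:30)))
  sm <- sm - rowMeans(sm)
  p <- run_pca(sm, 5)
  perm <- sample(30)
  p2 <- run_pca(sm[, perm], 5)
  expect_equal(abs(p2$scores), abs(p$scores[perm, ]), tolerance = 1e-8,
               ignore_attr = TRUE)
  errs <- sapply(1:5, function(k) {
    pk <- run_pca(sm, k)
    sum((t(sm) - pk$scores %*% t(pk$loadings))^2)
  })
  expect_true(all(diff(errs) < 1e-8))
})

test_that("jackstraw selects a planted factor and respects alpha = 0", {
  set.seed(3)
  f <- rnorm(100)
  load <- rep(0, 150); load[1:30] <- 3
  sm <- outer(load, f) + matrix(rnorm(150 * 100), 150, 100)
  sm <- t(scale(t(sm)))
  dimnames(sm) <- list(paste0("g", 1:150), paste0("c", 1:100))
  p <- run_pca(sm, 8)
  js <- jackstraw(sm, p, n_reps = 50, prop = 0.02, seed = 4)
  expect_true(1 %in% js$selected_pcs)
  expect_true(all(js$p_values >= 0 & js$p_values <= 1))
  js0 <- jackstraw(sm, p, n_reps = 50, prop = 0.02, alpha = 0, seed = 4)
  expect_length(js0$selected_pcs, 0)
  expect_error(jackstraw(sm, p, prop = 1e-4), "no genes to permute")
})

test_that("repeated QC reaches a stable fixpoint", {
  ds <- generate_dataset(tiny_spec(seed = 4))
  ds <- generate_qc_outliers(ds, tiny_spec(seed = 4), 4, 2)
  sce <- merge_stages(ds$stages)
  pass <- function(x) suppressMessages(filter_genes(filter_cells(x)))
  a <- pass(sce)
  b <- pass(a)
  c <- pass(b)
  expect_identical(dim(c), dim(b))
  expect_identical(colnames(c), colnames(b))
  expect_identical(rownames(c), rownames(b))
})
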