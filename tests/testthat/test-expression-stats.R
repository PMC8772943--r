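mat <- function(x, ids, samples = sprintf("s%d",
                                          seq_len(length(x) / length(ids)))) {
  expression_matrix(matrix(x, nrow = length(ids), byrow = TRUE,
                           dimnames = list(ids, samples)))
}

test_that("correlation screen recovers exact correlations and flags alpha", {
  a <- mat(c(1, 2, 3, 4), "g1")
  expect_equal(correlation_screen(a, a + 0)$r, numeric(0))  # self-pair drop
  b <- mat(c(2, 4, 6, 8), "m1")
  res <- correlation_screen(a, b)
  expect_equal(res$r, 1)
  expect_equal(res$p, 0)
  expect_true(res$significant)

  anti <- correlation_screen(mat(c(1, 2, 3), "g1"), mat(c(3, 2, 1), "m1"))
  expect_equal(anti$r, -1)

  expect_error(correlation_screen(mat(1:3, "g"), mat(1:4, "m")),
               "sample ids")
  expect_error(correlation_screen(mat(c(1, 2), "g", c("s1", "s2")),
                                  mat(c(1, 2), "m", c("s1", "s2"))),
               "3 samples")
})

test_that("r and p match cor.test and the textbook formula to 1e-12", {
  set.seed(59)
  for (rep in 1:60) {
    n <- sample(4:20, 1)
    x <- runif(n, 0, 100)
    y <- runif(n, 0, 100)
    res <- correlation_screen(mat(x, "g"), mat(y, "m"))
    ct <- cor.test(x, y)
    expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p, ct$p.value, tolerance = 1e-12)
    o <- oracle_pearson(x, y)
    expect_equal(res$r, o$r, tolerance = 1e-12)
    expect_equal(res$p, o$p, tolerance = 1e-12)
  }
})

test_that("r is invariant under positive affine transforms and symmetric", {
  set.seed(61)
  x <- runif(8); y <- runif(8)
  r0 <- correlation_screen(mat(x, "g"), mat(y, "m"))$r
  expect_equal(correlation_screen(mat(3.2 * x + 7, "g"), mat(y, "m"))$r, r0)
  expect_equal(correlation_screen(mat(x, "g"), mat(0.5 * y + 1, "m"))$r, r0)

  a <- mat(c(runif(8), runif(8), runif(8)), c("f1", "f2", "f3"))
  res <- correlation_screen(a, a)
  expect_equal(nrow(res), 6)  # no self-pairs
  r12 <- res$r[res$feature_a == "f1" & res$feature_b == "f2"]
  r21 <- res$r[res$feature_a == "f2" & res$feature_b == "f1"]
  expect_equal(r12, r21)
})

test_that("zero-variance features are excluded and reported", {
  a <- mat(c(1, 1, 1, 1, 1, 2, 3, 4), c("flat", "g2"))
  b <- mat(c(4, 3, 2, 1), "m1")
  res <- correlation_screen(a, b)
  expect_equal(res$feature_a, "g2")
  expect_equal(attr(res, "zero_variance"), "flat")
})

test_that("BH adjustment is available but off by default", {
  set.seed(67)
  a <- mat(runif(40), sprintf("g%d", 1:10), sprintf("s%d", 1:4))
  b <- mat(runif(40), sprintf("m%d", 1:10), sprintf("s%d", 1:4))
  plain <- correlation_screen(a, b)
  expect_false("p_adj" %in% names(plain))
  adj <- correlation_screen(a, b, adjust = "BH")
  expect_equal(adj$p_adj, p.adjust(adj$p, "BH"))
})

test_that("k-medians separates well-separated profile groups for any seed", {
  ids <- sprintf("f%02d", 1:20)
  x <- rbind(matrix(rep(c(0, 0, 10, 10), 10), 10, byrow = TRUE),
             matrix(rep(c(10, 10, 0, 0), 10), 10, byrow = TRUE))
  rownames(x) <- ids; colnames(x) <- sprintf("s%d", 1:4)
  m <- expression_matrix(x)
  for (seed in c(1, 7, 99, 1234)) {
    fit <- kmeans_manhattan(m, k = 2, seed = seed)
    cl <- fit$assignments
    expect_length(unique(cl[1:10]), 1)
    expect_length(unique(cl[11:20]), 1)
    expect_true(cl[1] != cl[11])
    # deterministic given the seed
    expect_identical(kmeans_manhattan(m, k = 2, seed = seed)$assignments, cl)
  }
  expect_error(kmeans_manhattan(m, k = 21, seed = 1), "between 1")
})

test_that("k = 1 centroid is the component-wise median of centered rows", {
  set.seed(71)
  x <- matrix(runif(35, 0, 100), 7, 5,
              dimnames = list(sprintf("f%d", 1:7), sprintf("s%d", 1:5)))
  fit <- kmeans_manhattan(expression_matrix(x), k = 1, seed = 3)
  centered <- x - rowMeans(x)
  expect_equal(as.numeric(fit$centroids),
               unname(apply(centered, 2, median)))
  expect_equal(fit$objective,
               sum(abs(sweep(centered, 2, apply(centered, 2, median)))))
})

test_that("the k-medians objective never increases and restarts only help", {
  set.seed(73)
  for (rep in 1:50) {
    nf <- sample(6:20, 1); ns <- sample(3:8, 1)
    k <- sample(2:4, 1)
    x <- matrix(runif(nf * ns, 0, 50), nf, ns,
                dimnames = list(sprintf("f%d", 1:nf), sprintf("s%d", 1:ns)))
    m <- expression_matrix(x)
    fit <- kmeans_manhattan(m, k = min(k, nf), seed = rep)
    expect_true(all(diff(fit$objective_trace) <= 1e-9))
    expect_true(all(fit$assignments %in% seq_len(min(k, nf))))
    # objective is reproducible from assignments + centroids
    cx <- x - rowMeans(x)
    obj <- sum(vapply(seq_along(fit$assignments), function(i) {
      sum(abs(cx[i, ] - fit$centroids[fit$assignments[i], ]))
    }, numeric(1)))
    expect_equal(obj, fit$objective)
    one <- kmeans_manhattan(m, k = min(k, nf), restarts = 1, seed = rep)
    expect_lte(fit$objective, one$objective + 1e-9)
  }
})

test_that("ddCt reproduces the comparative-method closed forms", {
  tab <- data.frame(
    sample = rep(c("a1", "a2", "b1", "b2"), each = 2),
    group = rep(c("FW", "FW", "SW", "SW"), each = 2),
    gene = rep(c("atp1a", "efa"), 4),
    ct = rep(20, 8))
  out <- ddct(tab, reference_gene = "efa", calibrator_group = "FW")
  expect_equal(out$relative_expression, rep(1, 4))  # null case

  # target one cycle lower in treatment, reference unchanged
  tab2 <- tab
  tab2$ct[tab2$gene == "atp1a" & tab2$group == "SW"] <- 19
  out2 <- ddct(tab2, "efa", "FW")
  expect_equal(out2$relative_expression[out2$group == "SW"], c(2, 2))
  expect_equal(out2$relative_expression[out2$group == "FW"], c(1, 1))

  expect_error(ddct(tab[tab$gene != "efa" | tab$sample != "a1", ],
                    "efa", "FW"), "a1")
  expect_error(ddct(tab, "nope", "FW"), "reference gene")
  expect_error(ddct(tab, "efa", "nope"), "calibrator")
})

test_that("ddCt matches a spreadsheet-style recomputation on random tables", {
  set.seed(79)
  for (rep in 1:20) {
    tab <- expand.grid(sample = sprintf("s%d", 1:6),
                       gene = c("g1", "g2", "ref"),
                       stringsAsFactors = FALSE)
    tab$group <- rep(c("ctl", "ctl", "ctl", "trt", "trt", "trt"), 3)
    tab$ct <- round(runif(nrow(tab), 15, 30), 2)
    out <- ddct(tab, "ref", "ctl")
    want <- oracle_ddct(tab, "ref", "ctl")
    key <- paste(out$sample, out$gene)
    expect_equal(out$relative_expression,
                 want$re[match(key, paste(want$sample, want$gene))],
                 tolerance = 1e-12)
    # shifting every Ct of one sample cancels through the reference
    tab3 <- tab
    tab3$ct[tab3$sample == "s2"] <- tab3$ct[tab3$sample == "s2"] + 3.7
    out3 <- ddct(tab3, "ref", "ctl")
    i <- out$sample == "s2"
    expect_equal(out3$relative_expression[i], out$relative_expression[i],
                 tolerance = 1e-9)
  }
})

test_that("TPM matrices round-trip through TSV", {
  set.seed(83)
  m <- expression_matrix(matrix(runif(12, 0, 500), 3, 4,
                                dimnames = list(c("g1", "g2", "g3"),
                                                sprintf("s%d", 1:4))))
  p <- tempfile(fileext = ".tsv")
  write_tpm(m, p)
  expect_equal(unclass(read_tpm(p)), unclass(m), tolerance = 1e-9)
  expect_error(expression_matrix(matrix(-1, 1, 1,
                                        dimnames = list("g", "s"))),
               ">= 0")
})
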