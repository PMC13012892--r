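test_that("loop metrics match a constructed fixture", {
  # CDR3-beta residues 105..108 contacting peptide residues 3,4,5 by 5 edges
  n <- 12
  g <- toy_graph(n, rbind(c(1, 2)), "cdr", seed = 2)
  g$nodes$role <- c(rep("PEPTIDE", 5), rep("TCRB", 5), "MHC", "TCRA")
  g$nodes$res_seq <- c(1:5, 105:109, 50L, 40L)
  edges <- rbind(c(3, 6), c(3, 7), c(4, 7), c(5, 8), c(5, 9))
  g$edge_index <- t(edges)
  g$edge_feats <- g$edge_feats[rep(1, 5), , drop = FALSE]
  g$edge_feats[, "dist"] <- c(5, 6, 6, 7, 6)
  m <- loop_contact_metrics(g, "TCRB", "CDR3")
  expect_equal(m$mean_contact_dist, 6.0)
  expect_equal(m$n_partner_residues, 3)
  expect_equal(m$n_cdr_residues, 4)
  expect_equal(m$n_edges, 5)
  # a loop with no contacts
  m2 <- loop_contact_metrics(g, "TCRA", "CDR1")
  expect_true(is.na(m2$mean_contact_dist))
  expect_equal(m2$n_partner_residues, 0)
  expect_equal(m2$n_cdr_residues, 0)
  expect_error(loop_contact_metrics(g, "TCRX", "CDR1"))
})

test_that("loop metrics equal a brute-force edge scan on random fixtures", {
  d <- cdr_imgt_default()
  for (s in 1:50) {
    set.seed(700 + s)
    n <- sample(15:30, 1)
    edges <- t(combn(n, 2))
    edges <- edges[sample(nrow(edges), sample(8:25, 1)), , drop = FALSE]
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
    g <- toy_graph(n, edges, seed = s)
    g$nodes$role <- sample(c("MHC", "PEPTIDE", "TCRA", "TCRB"), n,
                           replace = TRUE)
    g$nodes$res_seq <- sample(1:120, n)
    ann <- d[sample(nrow(d), 1), ]
    m <- loop_contact_metrics(g, ann$chain, ann$loop, ann$start, ann$end)
    partner <- if (ann$loop == "CDR3") "PEPTIDE" else "MHC"
    in_cdr <- g$nodes$role == ann$chain & g$nodes$res_seq >= ann$start &
      g$nodes$res_seq <= ann$end
    hits <- c()
    parts <- cdrs <- integer(0)
    for (e in seq_len(ncol(g$edge_index))) {
      i <- g$edge_index[1, e]; j <- g$edge_index[2, e]
      if (in_cdr[i] && g$nodes$role[j] == partner) {
        hits <- c(hits, e); parts <- c(parts, j); cdrs <- c(cdrs, i)
      } else if (in_cdr[j] && g$nodes$role[i] == partner) {
        hits <- c(hits, e); parts <- c(parts, i); cdrs <- c(cdrs, j)
      }
    }
    expect_equal(m$n_edges, length(hits))
    expect_equal(m$n_partner_residues, length(unique(parts)))
    expect_equal(m$n_cdr_residues, length(unique(cdrs)))
    if (length(hits)) {
      expect_equal(m$mean_contact_dist, mean(g$edge_feats[hits, "dist"]))
    }
  }
})

test_that("Cliff's delta matches brute-force pair counting", {
  expect_equal(compare_distributions(1:3, 4:6)$cliffs_delta, -1)
  expect_equal(compare_distributions(1:3, 2:4)$cliffs_delta, -5 / 9)
  expect_equal(compare_distributions(1:5, 1:5)$cliffs_delta, 0)
  set.seed(4)
  for (i in 1:20) {
    x <- sample(1:8, sample(3:10, 1), replace = TRUE)
    y <- sample(1:8, sample(3:10, 1), replace = TRUE)
    brute <- (sum(outer(x, y, ">")) - sum(outer(x, y, "<"))) /
      (length(x) * length(y))
    r <- compare_distributions(x, y)
    expect_equal(r$cliffs_delta, brute)
    expect_equal(compare_distributions(y, x)$cliffs_delta, -brute)
  }
})

test_that("exact Mann-Whitney p matches enumeration on the toy sample", {
  r <- compare_distributions(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$method, "exact")
  expect_equal(r$p_two_sided, 1 / 3)
})

test_that("U statistics of the two directions sum to nm", {
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1))
    if (i %% 3 == 0) y[1] <- x[1]  # inject ties
    expect_equal(compare_distributions(x, y)$U +
                   compare_distributions(y, x)$U,
                 length(x) * length(y))
  }
})

test_that("exact and normal-approximation p agree for 6 vs 6 samples", {
  set.seed(6)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(6, 0.5)
    exact <- compare_distributions(x, y)
    expect_equal(exact$method, "exact")
    # force the normal path by replicating the comparison at larger n and
    # checking the same U configuration: use internal approximation directly
    n <- 6; m <- 6; N <- 12
    U <- exact$U
    sigma2 <- n * m / 12 * (N + 1)
    z <- sign(U - 18) * max(0, abs(U - 18) - 0.5) / sqrt(sigma2)
    p_norm <- min(1, 2 * pnorm(-abs(z)))
    expect_lt(abs(exact$p_two_sided - p_norm), 0.02)
  }
})

test_that("Mann-Whitney agrees with wilcox.test on untied large samples", {
  set.seed(7)
  x <- rnorm(30); y <- rnorm(25, 0.4)
  r <- compare_distributions(x, y)
  w <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(r$U, unname(w$statistic))
  expect_equal(r$p_two_sided, w$p.value, tolerance = 1e-6)
})

test_that("CDR annotation CSV validation rejects overlapping ranges", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("complex_id,chain,loop,start,end",
               "c1,TCRA,CDR1,27,38", "c1,TCRA,CDR2,30,65"), tf)
  expect_error(read_cdr_annotations(tf), "overlap")
})
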