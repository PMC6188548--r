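# Gene-set statistics: Fisher enrichment, true-path propagation, the
# classic/elim/weight algorithms, and the exact multi-set intersection
# distribution against enumeration and Monte-Carlo oracles.

test_that("Fisher enrichment equals the hypergeometric tail", {
  # study 10 of 100; term hits 5 in study, 10 in background
  p <- fisher_exact_enrichment(5, 10, 10, 100)
  direct <- sum(stats::dhyper(5:10, 10, 90, 10))
  expect_equal(p, direct, tolerance = 1e-12)
  ft <- stats::fisher.test(matrix(c(5, 5, 5, 85), 2), alternative = "greater")
  expect_equal(p, ft$p.value, tolerance = 1e-9)
  expect_equal(fisher_exact_enrichment(10, 10, 100, 100), 1)
  expect_equal(fisher_exact_enrichment(0, 10, 10, 100), 1)
  expect_error(fisher_exact_enrichment(11, 10, 20, 100), "inconsistent")
  # random small tables against fisher.test
  set.seed(1)
  for (i in 1:20) {
    N <- sample(10:40, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    tab <- matrix(c(k, K - k, n - k, N - K - n + k), 2)
    if (any(tab < 0)) next
    expect_equal(fisher_exact_enrichment(k, n, K, N),
                 stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("annotation propagation follows the true-path rule", {
  edges <- data.frame(child = c("C", "B"), parent = c("B", "A"))
  ann <- data.frame(gene = "g1", term = "C")
  g <- annotation_graph(edges, ann)
  g <- propagate_annotations(g)
  expect_true(all(c("A", "B", "C") %in%
                    names(Filter(function(x) "g1" %in% x, g$term_genes))))
  # diamond: no duplicates
  edges2 <- data.frame(child = c("D", "D", "B", "C"),
                       parent = c("B", "C", "A", "A"))
  ann2 <- data.frame(gene = c("g1", "g2"), term = c("D", "D"))
  g2 <- propagate_annotations(annotation_graph(edges2, ann2))
  expect_identical(sort(g2$term_genes$A), c("g1", "g2"))
  # idempotence
  g3 <- propagate_annotations(g2)
  expect_identical(g2$term_genes, g3$term_genes)
  # cycles are rejected
  expect_error(annotation_graph(
    data.frame(child = c("A", "B"), parent = c("B", "A")),
    data.frame(gene = "g", term = "A")), "cycle")
})

# constructed DAG: root R; parent P with child C; unrelated U.
# The study signal lives entirely in C's genes.
elim_fixture <- local({
  edges <- data.frame(child = c("P", "U", "C"), parent = c("R", "R", "P"))
  genes <- sprintf("g%02d", 1:40)
  ann <- rbind(
    data.frame(gene = genes[1:8], term = "C"),      # C genes (the signal)
    data.frame(gene = genes[9:20], term = "P"),     # P-only genes
    data.frame(gene = genes[21:40], term = "U"))
  graph <- propagate_annotations(annotation_graph(edges, ann))
  study <- genes[c(1:7, 21)]   # 7 of 8 C genes + 1 noise gene
  list(graph = graph, study = study)
})

test_that("elim demotes a parent whose signal comes from its child", {
  fx <- elim_fixture
  cl <- go_enrichment(fx$study, fx$graph, "classic")
  el <- go_enrichment(fx$study, fx$graph, "elim")
  pc <- function(d, t) d$p[d$term == t]
  expect_lt(pc(cl, "C"), 0.05)
  expect_lt(pc(cl, "P"), 0.05)       # classic flags the parent too
  expect_lt(pc(el, "C"), 0.05)       # elim keeps the child
  expect_gt(pc(el, "P"), 0.05)       # ... and demotes the parent
  # the elim p for P equals classic Fisher with C's genes removed
  K <- length(setdiff(fx$graph$term_genes$P, fx$graph$term_genes$C))
  k <- length(setdiff(intersect(fx$graph$term_genes$P, fx$study),
                      fx$graph$term_genes$C))
  expect_equal(pc(el, "P"),
               fisher_exact_enrichment(k, length(fx$study), K,
                                       length(fx$graph$genes)),
               tolerance = 1e-12)
})

test_that("elim equals classic when nothing is significant", {
  fx <- elim_fixture
  study_flat <- fx$graph$genes[seq(1, 40, by = 5)]  # spread evenly
  cl <- go_enrichment(study_flat, fx$graph, "classic")
  el <- go_enrichment(study_flat, fx$graph, "elim")
  expect_true(all(cl$p >= 0.05))
  expect_equal(cl$p, el$p, tolerance = 1e-12)
})

test_that("weight is deterministic and demotes the explained parent", {
  fx <- elim_fixture
  w1 <- go_enrichment(fx$study, fx$graph, "weight")
  w2 <- go_enrichment(fx$study, fx$graph, "weight")
  expect_identical(w1, w2)
  pc <- function(d, t) d$p[d$term == t]
  expect_lt(pc(w1, "C"), 0.05)
  expect_gt(pc(w1, "P"), pc(go_enrichment(fx$study, fx$graph, "classic"), "P"))
  # a term with no study hits has p = 1 under all algorithms
  study_u <- fx$graph$term_genes$U[1:5]
  for (alg in c("classic", "elim", "weight")) {
    d <- go_enrichment(study_u, fx$graph, alg)
    expect_equal(d$p[d$term == "C"], 1)
  }
})

test_that("multi-set distribution: formula mean, m=2 hypergeometric, sums to 1", {
  d <- multiset_intersection_distribution(c(3, 4), 10)
  expect_equal(d, stats::dhyper(0:3, 3, 7, 4), tolerance = 1e-12)
  d3 <- multiset_intersection_distribution(c(4, 5, 6), 12)
  expect_equal(sum(d3), 1, tolerance = 1e-9)
  expect_equal(sum((seq_along(d3) - 1) * d3), 12 * (4 / 12) * (5 / 12) * (6 / 12),
               tolerance = 1e-9)
})

test_that("multi-set distribution matches full enumeration (small N)", {
  N <- 6; sizes <- c(2, 3, 4)
  d <- multiset_intersection_distribution(sizes, N)
  # enumerate all subset placements; by symmetry fix S1 = {1..n1}
  s1 <- seq_len(sizes[1])
  s2s <- utils::combn(N, sizes[2], simplify = FALSE)
  s3s <- utils::combn(N, sizes[3], simplify = FALSE)
  counts <- numeric(min(sizes) + 1)
  for (s2 in s2s) for (s3 in s3s) {
    k <- length(intersect(intersect(s1, s2), s3))
    counts[k + 1] <- counts[k + 1] + 1
  }
  expect_equal(d, counts / sum(counts), tolerance = 1e-12)
})

test_that("multi-set test matches Monte-Carlo at N = 500, m = 3", {
  N <- 500; sizes <- c(60, 80, 100)
  d <- multiset_intersection_distribution(sizes, N)
  set.seed(99)
  B <- 1e5
  ks <- replicate(B, {
    length(Reduce(intersect, lapply(sizes, function(n) sample.int(N, n))))
  })
  for (k in c(1, 2, 3)) {
    phat <- mean(ks >= k)
    pex <- sum(d[(k + 1):length(d)])
    se <- sqrt(phat * (1 - phat) / B)
    expect_lt(abs(phat - pex), 3 * se + 1e-12)
  }
})

test_that("the intersection test reports expectation, fold and p", {
  bg <- sprintf("g%03d", 1:500)
  A <- bg[1:50]
  tst <- multiset_intersection_test(list(A = A, B = A), bg)
  expect_identical(tst$observed, 50L)
  expect_equal(tst$expected, 500 * (50 / 500)^2)
  expect_equal(tst$fold_enrichment, 10)
  expect_lt(tst$p_value, 1e-10)
  # stated-formula example
  t2 <- multiset_intersection_test(list(x = bg[1:3], y = bg[4:7]), bg[1:10])
  expect_equal(t2$expected, 1.2)
  # fold enrichment from observed/expected
  expect_equal(multiset_intersection_test(
    list(x = bg[1:3], y = bg[1:3]), bg[1:10])$fold_enrichment, 3 / 0.9)
  expect_error(multiset_intersection_test(list(bg, "zz"), bg), "outside")
})
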