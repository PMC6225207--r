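test_that("distance_matrix: identical rows, bounds, hand-computed cases", {
  s <- protein_set(c("a", "b", "c"),
                   c("GGRRAACC", "GGRRAACC", "AACCGGRR"))
  cm <- composition_matrix(s)
  d <- as.matrix(distance_matrix(cm, "euclidean"))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 0)   # same composition, different order
  # hand-computed euclidean on a toy matrix
  m <- composition_matrix(protein_set(c("x", "y", "z"),
                                      c("GG", "RR", "GR")))
  dm <- as.matrix(distance_matrix(m, "euclidean"))
  expect_equal(dm["x", "y"], sqrt(2))
  expect_equal(dm["x", "z"], sqrt(0.5))
  # correlation distance of perfectly anti-correlated rows is 2:
  # compositions are base +/- the same single-residue swap
  others <- strrep(setdiff(AA_ALPHABET, c("A", "L")), 2)
  seqs <- c(paste0(strrep("A", 3), strrep("L", 1), paste(others, collapse = "")),
            paste0(strrep("A", 1), strrep("L", 3), paste(others, collapse = "")))
  m2 <- composition_matrix(protein_set(c("u", "v"), seqs))
  expect_equal(as.matrix(distance_matrix(m2, "correlation"))["u", "v"], 2)
  expect_error(distance_matrix(composition_matrix(
    protein_set(c("k", "l"), c("ACDEFGHIKLMNPQRSTVWY", "GGGG"))),
    "correlation"), "zero-variance.*GGGG|zero-variance")
})

test_that("average linkage reproduces hand-computed UPGMA merges", {
  d <- matrix(0, 3, 3, dimnames = list(c("s1", "s2", "s3"),
                                       c("s1", "s2", "s3")))
  d["s1", "s2"] <- d["s2", "s1"] <- 1
  d["s1", "s3"] <- d["s3", "s1"] <- 4
  d["s2", "s3"] <- d["s3", "s2"] <- 5
  tr <- average_linkage(stats::as.dist(d))
  expect_equal(sort(tr$heights), c(1, 4.5))
  first <- tr$clusters[[which.min(tr$heights)]]
  expect_identical(sort(tr$labels[first]), c("s1", "s2"))
  # n = 2: single merge at d(1,2)
  d2 <- stats::as.dist(matrix(c(0, 3, 3, 0), 2,
                              dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(average_linkage(d2)$heights, 3)
})

test_that("average linkage matches the brute-force O(n^3) oracle, n <= 8", {
  set.seed(42)
  for (rep in 1:12) {
    n <- sample(4:8, 1)
    x <- matrix(runif(n * 6), n)
    rownames(x) <- paste0("p", seq_len(n))
    d <- stats::dist(x)
    tr <- average_linkage(d)
    oracle <- upgma_oracle(d)
    got <- lapply(seq_along(tr$heights), function(i)
      list(leaves = tr$clusters[[i]], height = tr$heights[i]))
    got <- got[order(vapply(got, `[[`, 0, "height"))]
    oracle <- oracle[order(vapply(oracle, `[[`, 0, "height"))]
    for (i in seq_along(oracle)) {
      expect_equal(got[[i]]$height, oracle[[i]]$height, tolerance = 1e-12)
      expect_identical(got[[i]]$leaves, oracle[[i]]$leaves)
    }
  }
})

test_that("merge heights are non-decreasing (ultrametric agglomeration)", {
  cm <- composition_matrix(gen_background(synthetic_spec(25, 200, seed = 2)))
  tr <- average_linkage(distance_matrix(cm))
  expect_true(all(diff(tr$heights) >= -1e-12))
})

test_that("BP at scale 1 equals a direct-count oracle on the same replicates", {
  g <- gen_grouped(synthetic_spec(8, 500, seed = 3),
                   list(c(G = 0), c(G = 0.06)))
  cm <- composition_matrix(g$set)
  cfg <- bootstrap_config(n_boot = 1000, scales = 1, seed = 17,
                          distance = "euclidean")
  tr <- multiscale_bootstrap_support(cm, cfg)
  # oracle: replay the documented draw protocol (per-scale seed = seed + i)
  # and count cluster occurrences independently via cutree memberships
  x <- unclass(cm)
  sigs <- vapply(tr$clusters, function(cl)
    paste(sort(cl), collapse = ","), "")
  set.seed(cfg$seed + 1)
  counts <- integer(length(sigs))
  for (b in seq_len(cfg$per_scale)) {
    cols <- sample.int(20, 20, replace = TRUE)
    hb <- stats::hclust(stats::dist(x[, cols, drop = FALSE]),
                        method = "average")
    reps <- unique(unlist(lapply(seq_len(nrow(x) - 1L), function(k) {
      memb <- stats::cutree(hb, h = hb$height[k] + 1e-12)
      vapply(split(seq_along(memb), memb), function(ix)
        paste(sort(ix), collapse = ","), "")
    })))
    counts <- counts + (sigs %in% reps)
  }
  expect_equal(unname(tr$bp_table[, 1]), counts / cfg$per_scale)
})

test_that("planted two-group shift is recovered with AU >= 95", {
  g <- gen_grouped(synthetic_spec(10, 1000, seed = 1),
                   list(c(G = 0), c(G = 0.05)))
  cm <- composition_matrix(g$set)
  tr <- multiscale_bootstrap_support(cm, bootstrap_config(
    n_boot = 10000, seed = 2, distance = "euclidean"))
  picks <- cut_by_support(tr, min_au = 95)
  expect_length(picks$clusters, 2)
  got <- lapply(picks$clusters, sort)
  want <- lapply(split(names(g$labels), g$labels), sort)
  expect_setequal(vapply(got, paste, "", collapse = ","),
                  vapply(want, paste, "", collapse = ","))
  expect_true(all(picks$au >= 95))
  expect_length(picks$unassigned, 0)
})

test_that("support values are bounded and AU/BP relate through curvature", {
  g <- gen_grouped(synthetic_spec(6, 600, seed = 5),
                   list(c(R = 0), c(R = 0.06)))
  tr <- multiscale_bootstrap_support(composition_matrix(g$set),
                                     bootstrap_config(n_boot = 2000,
                                                      seed = 6,
                                                      distance = "euclidean"))
  expect_true(all(tr$au >= 0 & tr$au <= 100))
  expect_true(all(tr$bp >= 0 & tr$bp <= 100))
  fitted <- which(!tr$degenerate)
  pos_c <- fitted[tr$fit$c[fitted] > 0]
  expect_true(all(tr$au[pos_c] >= tr$bp[pos_c] - 1e-9))
  # root: always present in every replicate
  n_nodes <- length(tr$clusters)
  expect_equal(tr$au[n_nodes], 100)
  expect_true(tr$degenerate[n_nodes])
})

test_that("cut_by_support: root handling and threshold 0", {
  g <- gen_grouped(synthetic_spec(5, 400, seed = 8),
                   list(c(G = 0), c(G = 0.08)))
  tr <- multiscale_bootstrap_support(composition_matrix(g$set),
                                     bootstrap_config(n_boot = 1000,
                                                      seed = 9,
                                                      distance = "euclidean"))
  all_leaves <- cut_by_support(tr, min_au = 0, include_root = TRUE)
  expect_length(all_leaves$clusters, 1)
  expect_setequal(all_leaves$clusters[[1]], tr$labels)
  no_root <- cut_by_support(tr, min_au = 0)
  expect_true(all(lengths(no_root$clusters) < length(tr$labels)))
})

test_that("bootstrap support is deterministic given the seed", {
  cm <- composition_matrix(gen_background(synthetic_spec(8, 300, seed = 4)))
  cfg <- bootstrap_config(n_boot = 600, scales = c(0.6, 1, 1.3), seed = 30)
  t1 <- multiscale_bootstrap_support(cm, cfg)
  t2 <- multiscale_bootstrap_support(cm, cfg)
  expect_identical(t1$au, t2$au)
  expect_identical(t1$bp_table, t2$bp_table)
})

test_that("newick export round-trips topology, heights and labels", {
  skip_if_not_installed("ape")
  g <- gen_grouped(synthetic_spec(5, 400, seed = 10),
                   list(c(G = 0), c(G = 0.08)))
  cm <- composition_matrix(g$set)
  tr <- multiscale_bootstrap_support(cm, bootstrap_config(
    n_boot = 500, scales = c(0.7, 1, 1.2), seed = 12,
    distance = "euclidean"))
  nwk <- to_newick(tr)
  expect_match(nwk, ";$")
  expect_match(nwk, "\\)\\d+\\|\\d+")   # AU|BP internal labels
  ph <- ape::read.tree(text = nwk)
  expect_setequal(ph$tip.label, tr$labels)
  # leaf depths equal root height (ultrametric) and pairwise distances match
  # 2 * merge height of the smallest cluster containing both leaves
  dmat <- ape::cophenetic.phylo(ph)
  for (pair in list(c(1, 2), c(3, 9), c(5, 7))) {
    i <- tr$labels[pair[1]]; j <- tr$labels[pair[2]]
    k <- which(vapply(tr$clusters, function(cl)
      all(pair %in% cl), TRUE))
    h <- min(tr$heights[k])
    expect_equal(dmat[i, j], 2 * h, tolerance = 1e-6)
  }
  # two-leaf tree shape
  d2 <- stats::as.dist(matrix(c(0, 1, 1, 0), 2,
                              dimnames = list(c("a", "b"), c("a", "b"))))
  expect_match(to_newick(average_linkage(d2)), "^\\(a:1,b:1\\);$")
})
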