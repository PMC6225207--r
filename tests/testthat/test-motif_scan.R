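test_that("peptide_to_pwm follows the pseudo-probability rule", {
  m0 <- peptide_to_pwm("RG", pseudo_total = 0)
  expect_equal(unname(m0$prob[1, "R"]), 1)
  expect_equal(consensus(m0), "RG")
  m <- peptide_to_pwm("RG", pseudo_total = 0.01)
  expect_equal(unname(m$prob[1, "R"]), 0.99 + 0.01 * 0.05)
  expect_equal(unname(m$prob[1, "G"]), 0.0005)
  expect_equal(unname(rowSums(m$prob)), c(1, 1))
  fmr1 <- peptide_to_pwm(FMR1_MOTIF)
  expect_equal(fmr1$length, 26L)
  expect_error(peptide_to_pwm("RGX"), "non-canonical")
})

test_that("DP p-values equal brute-force enumeration for L <= 4", {
  for (pep in c("G", "RG", "RGD", "KRGW")) {
    motif <- peptide_to_pwm(pep, pseudo_total = 0.05)
    tb <- score_pvalue_table(motif, granularity = 0.001)
    S <- round(motif$log_odds / 0.001)
    L <- nchar(pep)
    combos <- as.matrix(expand.grid(rep(list(1:20), L)))
    sc <- rowSums(matrix(S[cbind(rep(seq_len(L), each = nrow(combos)),
                                 as.vector(combos))], ncol = L))
    for (s in sort(unique(sc)))
      expect_equal(quadbind:::.pvalue_at(tb, s), mean(sc >= s),
                   tolerance = 1e-12)
    # p at the minimum achievable score is 1
    expect_equal(quadbind:::.pvalue_at(tb, min(sc)), 1)
  }
})

test_that("single-position motif has p(max score) = background probability", {
  m <- peptide_to_pwm("W", pseudo_total = 0)
  tb <- score_pvalue_table(m)
  expect_equal(quadbind:::.pvalue_at(tb, tb$max_score), 0.05)
})

test_that("p-values are monotone non-increasing in score", {
  tb <- score_pvalue_table(peptide_to_pwm("RGRG"))
  expect_true(all(diff(tb$pvalue) <= 1e-15))
  expect_equal(tb$pvalue[1], 1)
})

test_that("scanning the consensus yields the maximal score at position 1", {
  motif <- peptide_to_pwm(NIQI_MOTIF)
  s <- protein_set("cons", NIQI_MOTIF)
  res <- scan_set(s, motif, p_threshold = 1)
  expect_equal(res$hits$start[which.max(res$hits$score)], 1)
  tb <- score_pvalue_table(motif)
  expect_equal(round(max(res$hits$score) / 0.001), tb$max_score)
})

test_that("background-only scan has no hits at tiny threshold", {
  s <- gen_background(synthetic_spec(10, 200, seed = 31))
  res <- scan_set(s, peptide_to_pwm(FMR1_MOTIF), p_threshold = 1e-12)
  expect_equal(nrow(res$hits), 0)
  expect_equal(res$n_windows, 10 * (200 - 26 + 1))
  expect_true(all(res$per_protein$n_hits == 0))
})

test_that("planted motif copies are recovered at their exact locations", {
  bg <- gen_background(synthetic_spec(8, 250, seed = 32))
  pl <- plant_motif(bg, FMR1_MOTIF, copies = 1, substitution_rate = 0,
                    seed = 33)
  res <- scan_set(pl$set, peptide_to_pwm(FMR1_MOTIF), p_threshold = 1e-8)
  found <- paste(res$hits$protein, res$hits$start)
  expect_true(all(paste(pl$truth$protein, pl$truth$start) %in% found))
  expect_gte(nrow(res$hits), nrow(pl$truth))
})

test_that("q-values are BH over all windows and per-protein best-q agrees", {
  bg <- gen_background(synthetic_spec(6, 120, seed = 34))
  pl <- plant_motif(bg, NIQI_MOTIF, copies = 1, substitution_rate = 0.1,
                    seed = 35)
  res <- scan_set(pl$set, peptide_to_pwm(NIQI_MOTIF), p_threshold = 0.05)
  # recompute BH from scratch over the same number of windows
  expect_true(all(res$hits$q_value >= res$hits$p_value))
  n <- res$n_windows
  for (i in seq_len(nrow(res$hits))) {
    p <- res$hits$p_value[i]
    # BH: q = min over hits with p' >= p of p' * n / rank(p'); spot-check
    # the defining inequality q <= p * n (rank >= 1)
    expect_lte(res$hits$q_value[i], min(1, p * n))
  }
  for (id in res$per_protein$protein) {
    qs <- res$hits$q_value[res$hits$protein == id]
    if (length(qs))
      expect_equal(res$per_protein$best_q[res$per_protein$protein == id],
                   min(qs))
  }
})

test_that("ambiguity codes score background-neutral, short proteins skip", {
  motif <- peptide_to_pwm("RGRG", pseudo_total = 0)
  s <- protein_set(c("amb", "short"), c("XXRGRGXX", "RG"))
  expect_warning(res <- scan_set(s, motif, p_threshold = 1), "short")
  # window RGRG must reach the maximal score despite X neighbours
  tb <- score_pvalue_table(motif)
  expect_equal(round(max(res$hits$score) / 0.001), tb$max_score)
  expect_false("short" %in% res$hits$protein)
})

test_that("hit counts are invariant to protein order", {
  bg <- gen_background(synthetic_spec(10, 150, seed = 36))
  pl <- plant_motif(bg, NIQI_MOTIF, copies = 1, substitution_rate = 0.2,
                    seed = 37)$set
  motif <- peptide_to_pwm(NIQI_MOTIF)
  r1 <- scan_set(pl, motif, p_threshold = 0.01)
  r2 <- scan_set(pl[rev(pl$ids)], motif, p_threshold = 0.01)
  expect_equal(nrow(r1$hits), nrow(r2$hits))
  h1 <- r1$hits[order(r1$hits$protein, r1$hits$start), ]
  h2 <- r2$hits[order(r2$hits$protein, r2$hits$start), ]
  expect_equal(h1$p_value, h2$p_value)
  expect_equal(h1$q_value, h2$q_value)
})

test_that("classify_by_q partitions every protein exactly once", {
  bg <- gen_background(synthetic_spec(12, 200, seed = 38))
  half <- plant_motif(bg[bg$ids[1:6]], NIQI_MOTIF, copies = 1,
                      substitution_rate = 0.05, seed = 39)$set
  s <- protein_set(c(half$ids, bg$ids[7:12]),
                   c(half$sequences, bg$sequences[7:12]))
  res <- scan_set(s, peptide_to_pwm(NIQI_MOTIF), p_threshold = 0.01)
  cls <- classify_by_q(res, c(0.05, 0.1))
  expect_equal(sum(cls$counts), 12)
  q <- res$per_protein$best_q
  expect_equal(unname(cls$counts[1]), sum(!is.na(q) & q <= 0.05))
  expect_equal(unname(cls$counts[3]),
               sum(is.na(q) | q > 0.1))
  # all-hit case: every protein lands in the first bin
  res2 <- scan_set(half, peptide_to_pwm(NIQI_MOTIF), p_threshold = 0.01)
  cls2 <- classify_by_q(res2)
  expect_equal(unname(cls2$counts[1]), 6L)
})

test_that("multi_hit_proteins reports sorted positions of repeat carriers", {
  bg <- gen_background(synthetic_spec(5, 300, seed = 40))
  pl <- plant_motif(bg, NIQI_MOTIF, copies = 3, substitution_rate = 0,
                    seed = 41)
  res <- scan_set(pl$set, peptide_to_pwm(NIQI_MOTIF), p_threshold = 1e-10)
  mh <- multi_hit_proteins(res, min_hits = 3)
  expect_setequal(mh$protein, pl$set$ids)
  for (i in seq_len(nrow(mh))) {
    pos <- mh$positions[[i]]
    expect_false(is.unsorted(pos))
    truth <- sort(pl$truth$start[pl$truth$protein == mh$protein[i]])
    expect_true(all(truth %in% pos))
  }
  all1 <- multi_hit_proteins(res, min_hits = 1)
  expect_setequal(all1$protein,
                  res$per_protein$protein[res$per_protein$n_hits > 0])
})

test_that("predict_candidates ranks the exact-consensus carrier first", {
  bg <- gen_background(synthetic_spec(20, 200, seed = 42))
  pl <- plant_motif(bg[bg$ids[1]], NIQI_MOTIF, copies = 1,
                    substitution_rate = 0, seed = 43)$set
  targets <- protein_set(c(pl$ids, bg$ids[2:20]),
                         c(pl$sequences, bg$sequences[2:20]))
  pred <- predict_candidates(targets, peptide_to_pwm(NIQI_MOTIF),
                             p_threshold = 0.1, top_n = 100)
  expect_identical(pred$protein[1], bg$ids[1])
  expect_lte(nrow(pred), 100)
  expect_true(all(diff(pred$best_p) >= 0))
  # excluded known binders never appear
  pred2 <- predict_candidates(targets, peptide_to_pwm(NIQI_MOTIF),
                              exclude = bg$ids[1])
  expect_false(bg$ids[1] %in% pred2$protein)
  # empty targets
  expect_equal(nrow(predict_candidates(protein_set(character(),
                                                   character()),
                                       peptide_to_pwm(NIQI_MOTIF))), 0)
})

test_that("MEME minimal format round-trips the motif", {
  motif <- peptide_to_pwm(NIQI_MOTIF, background = shifted_freqs("G", 0.08),
                          name = "NIQI")
  path <- withr::local_tempfile(fileext = ".meme")
  write_meme(motif, path)
  m2 <- read_meme(path)
  expect_identical(m2$name, "NIQI")
  expect_equal(m2$prob, motif$prob, tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(m2$background, motif$background, tolerance = 1e-5)
  expect_identical(consensus(m2), consensus(motif))
})
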