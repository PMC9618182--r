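make_ratio_table <- function(per_cmp) {
  do.call(rbind, lapply(names(per_cmp), function(cmp) {
    d <- per_cmp[[cmp]]
    data.frame(accession = names(d), symbol = names(d), comparison = cmp,
               raw_ratio = unname(d), norm_ratio = unname(d),
               log2_ratio = log2(unname(d)),
               change_class = classify_change(unname(d)),
               stringsAsFactors = FALSE)
  }))
}

test_that("altered sets mirror change classes and planted truth", {
  r <- make_ratio_table(list(
    A = c(p1 = 1.5, p2 = 0.7, p3 = 1.0, p4 = 1.2),
    B = c(p1 = 1.0, p2 = 1.0, p3 = 1.0, p4 = 1.0)
  ))
  s <- altered_sets(r)
  expect_equal(s$A$up, c("p1", "p4"))
  expect_equal(s$A$down, "p2")
  expect_equal(s$A$altered, c("p1", "p2", "p4"))
  expect_equal(s$B$altered, character(0))

  cfg <- effect_config(n_proteins = 300, frac_altered = 0.2, noise_cv = 0,
                       frac_missing = 0, frac_low_peptide = 0,
                       fold_up = c(1.5, 2), fold_down = c(0.5, 0.67),
                       seed = 4)
  d <- pool_design()
  sim <- simulate_pool_table(d, cfg)
  sets <- altered_sets(ratiometric_normalize(sim$table, d))
  tr <- sim$truth[sim$truth$comparison == "ALS_BA4", ]
  expect_setequal(sets$ALS_BA4$up, tr$accession[tr$class == "UP"])
  expect_setequal(sets$ALS_BA4$down, tr$accession[tr$class == "DOWN"])
})

test_that("specificity partitions the target altered set", {
  r <- make_ratio_table(list(
    A = c(p1 = 1.5, p2 = 1.5, p3 = 0.6),
    B = c(p1 = 1.0, p2 = 1.6, p3 = 1.0)
  ))
  s <- altered_sets(r)
  res <- specific_set("A", "B", s)
  expect_equal(res$specific, c("p1", "p3"))
  expect_equal(res$shared, "p2")
  expect_error(specific_set("A", c("A", "B"), s), "among others")
  expect_error(specific_set("Z", "B", s), "unknown")

  # empty-others edge: everything is specific
  s2 <- altered_sets(make_ratio_table(list(
    A = c(p1 = 1.3, p2 = 0.7), B = c(p1 = 1, p2 = 1)
  )))
  expect_equal(specific_set("A", "B", s2)$specific, c("p1", "p2"))

  # sizes mirror a two-group contrast: 453 altered, 330 specific -> 123 shared
  alt_a <- sprintf("q%03d", 1:453)
  alt_b <- c(sprintf("q%03d", 331:453), sprintf("r%03d", 1:134))
  sets <- list(A = list(up = alt_a, down = character(0), altered = alt_a),
               B = list(up = alt_b, down = character(0), altered = alt_b))
  res2 <- specific_set("A", "B", sets)
  expect_equal(length(res2$specific), 330L)
  expect_equal(length(res2$shared), 123L)
  expect_equal(length(res2$shared), length(intersect(alt_a, alt_b)))
})

test_that("specificity partition holds on randomized sets", {
  set.seed(21)
  for (i in 1:20) {
    ids <- sprintf("p%02d", 1:40)
    sets <- lapply(1:4, function(j) {
      alt <- sort(sample(ids, sample(0:25, 1)))
      list(up = alt, down = character(0), altered = alt)
    })
    names(sets) <- c("A", "B", "C", "D")
    res <- specific_set("A", c("B", "C", "D"), sets)
    expect_setequal(c(res$specific, res$shared), sets$A$altered)
    expect_length(intersect(res$specific, res$shared), 0)
    expect_setequal(res$specific,
                    setdiff(sets$A$altered,
                            Reduce(union, lapply(sets[-1], `[[`,
                                                 "altered"))))
  }
})

test_that("venn counts equal brute-force membership enumeration", {
  expect_equal(venn_counts(list(A = "a", B = "b")),
               c(A = 1L, B = 1L, "A&B" = 0L))
  same <- list(A = c("x", "y"), B = c("x", "y"))
  vc <- venn_counts(same)
  expect_equal(vc[["A&B"]], 2L)
  expect_equal(sum(vc), 2L)

  set.seed(13)
  for (i in 1:10) {
    sets <- lapply(1:3, function(j) sample(letters, sample(3:15, 1)))
    names(sets) <- c("A", "B", "C")
    vc <- venn_counts(sets)
    expect_equal(vc[names(venn_oracle(sets))], venn_oracle(sets))
    expect_equal(sum(vc), length(unique(unlist(sets))))
  }
  expect_error(venn_counts(list(a = "x")), "2 to 4")
  expect_error(venn_counts(rep(list("x"), 5)), "2 to 4")
})

test_that("top-k ranking is deterministic with lexicographic tie-break", {
  r <- make_ratio_table(list(A = c(B = 1.5, A = 1.5, C = 0.4, D = 2.0)))
  expect_equal(top_k(r, "A", k = 2, direction = "up"), c("D", "A"))
  expect_equal(top_k(r, "A", k = 1, direction = "up")[1], "D")
  # tie at 1.5: accession order decides
  expect_equal(top_k(r, "A", k = 3, direction = "up"), c("D", "A", "B"))
  expect_equal(top_k(r, "A", k = 2, direction = "down"), c("C", "A"))
  expect_equal(top_k(r, "A", k = 99, direction = "up"),
               c("D", "A", "B", "C"))
  expect_error(top_k(r, "A", k = 0), ">= 1")
  expect_error(top_k(r, "missing"), "unknown comparison")
})

test_that("raising the up threshold never grows an up set", {
  set.seed(17)
  ratios <- runif(200, 0.3, 3)
  names(ratios) <- sprintf("p%03d", 1:200)
  prev <- Inf
  for (thr in c(1.1, 1.2, 1.5, 2)) {
    n_up <- sum(classify_change(ratios, up_threshold = thr) == "UP")
    expect_lte(n_up, prev)
    prev <- n_up
  }
})
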