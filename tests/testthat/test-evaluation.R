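test_that("overlap metrics match set-counting oracles", {
  a <- array(FALSE, c(4, 2, 1)); a[1:4] <- TRUE
  b <- array(FALSE, c(4, 2, 1)); b[3:6] <- TRUE
  expect_identical(jaccard_index(a, a), 1)
  expect_identical(dice_coefficient(a, a), 1)
  disj <- array(FALSE, c(4, 2, 1)); disj[5:8] <- TRUE
  expect_identical(jaccard_index(a, disj), 0)
  expect_identical(dice_coefficient(a, disj), 0)
  expect_equal(jaccard_index(a, b), 1 / 3)   # |A|=|B|=4, 2 shared
  expect_equal(dice_coefficient(a, b), 1 / 2)
  e <- array(FALSE, c(2, 2, 1))
  expect_identical(jaccard_index(e, e), 1)   # both-empty convention
  expect_identical(dice_coefficient(e, e), 1)
  expect_error(jaccard_index(a, e), "shape")
})

test_that("Dice and Jaccard obey D = 2J/(1+J) and symmetry", {
  set.seed(5)
  for (i in 1:25) {
    a <- array(runif(48) < 0.4, c(4, 4, 3))
    b <- array(runif(48) < 0.4, c(4, 4, 3))
    J <- jaccard_index(a, b)
    D <- dice_coefficient(a, b)
    expect_lt(abs(D - 2 * J / (1 + J)), 1e-12)
    expect_identical(J, jaccard_index(b, a))
    expect_identical(D, dice_coefficient(b, a))
    # invariance under a common voxel permutation
    perm <- sample(48)
    ap <- array(a[perm], dim(a)); bp <- array(b[perm], dim(b))
    expect_identical(jaccard_index(ap, bp), J)
    expect_identical(dice_coefficient(ap, bp), D)
  }
})

test_that("fold assignment is balanced, exhaustive and reproducible", {
  ids <- sprintf("P%03d", 1:151)
  fa <- make_folds(ids, k = 5, seed = 9)
  expect_identical(sort(as.integer(table(fa$assignment)), decreasing = TRUE),
                   c(31L, 30L, 30L, 30L, 30L))
  expect_identical(sort(names(fa$assignment)), sort(ids))
  fa2 <- make_folds(ids, k = 5, seed = 9)
  expect_identical(fa$assignment, fa2$assignment)
  # exact division
  fa10 <- make_folds(sprintf("Q%02d", 1:10), k = 5, seed = 1)
  expect_true(all(table(fa10$assignment) == 2))
  expect_error(make_folds(c("a", "b"), k = 5), "config error")
  # balance property across (n, k) combinations
  set.seed(1)
  for (case in list(c(7L, 3L), c(23L, 4L), c(9L, 9L), c(40L, 6L))) {
    f <- make_folds(paste0("x", seq_len(case[1])), k = case[2], seed = 3)
    sizes <- as.integer(table(factor(f$assignment, levels = seq_len(case[2]))))
    expect_identical(sum(sizes), case[1])
    expect_lte(max(sizes) - min(sizes), 1L)
  }
})

test_that("cross-validation is paired across variants and supports stubs", {
  studies <- lapply(1:10, function(i) {
    set.seed(i)
    list(patient_id = sprintf("P%02d", i),
         lesion_label = if (i %% 2 == 0) "benign" else "malignant",
         pre = array(0, c(8, 8, 2)), early = array(0, c(8, 8, 2)),
         diff = array(0, c(8, 8, 2)),
         mask = array(runif(128) < 0.3, c(8, 8, 2)))
  })
  tmpl <- tiny_model_config(input_shape = c(8L, 8L, 2L))
  sc <- cross_validate(studies, c("baseline", "dual_enc_temporal_attention"),
                       tmpl, train_config(), k = 5, seed = 2,
                       trainer = oracle_trainer)
  expect_identical(nrow(sc), 20L)
  expect_identical(as.integer(table(sc$variant)), c(10L, 10L))
  # every patient appears exactly once per variant, in the same fold
  for (v in unique(sc$variant)) {
    sv <- sc[sc$variant == v, ]
    expect_identical(sort(sv$patient_id), sprintf("P%02d", 1:10))
  }
  wide <- merge(sc[sc$variant == "baseline", c("patient_id", "fold")],
                sc[sc$variant != "baseline", c("patient_id", "fold")],
                by = "patient_id")
  expect_identical(wide$fold.x, wide$fold.y)
  # the ground-truth stub scores perfectly
  expect_true(all(sc$jaccard == 1) && all(sc$dice == 1))
})

test_that("aggregation reports mean and n-1 SD by subgroup", {
  sc <- data.frame(patient_id = c("a", "b", "c", "d"),
                   variant = "v", fold = 1,
                   label = c("benign", "benign", "malignant", "malignant"),
                   jaccard = c(0.5, 0.7, 0.5, 0.7),
                   dice = c(0.5, 0.7, 0.5, 0.7),
                   stringsAsFactors = FALSE)
  agg <- aggregate_scores(sc)
  all_dice <- agg[agg$subgroup == "all" & agg$metric == "dice", ]
  expect_equal(all_dice$mean, 0.6)
  expect_equal(all_dice$sd, sd(c(0.5, 0.7, 0.5, 0.7)))
  ben <- agg[agg$subgroup == "benign" & agg$metric == "jaccard", ]
  expect_equal(ben$mean, 0.6)
  expect_equal(ben$sd, sd(c(0.5, 0.7)), tolerance = 1e-12)
  # all-case mean equals the weighted mean of the subgroup means
  mal <- agg[agg$subgroup == "malignant" & agg$metric == "jaccard", ]
  expect_equal(all_dice$mean,
               (ben$mean * ben$n + mal$mean * mal$n) / (ben$n + mal$n))
  # constant scores: SD 0
  sc2 <- sc; sc2$jaccard <- 0.4; sc2$dice <- 0.4
  agg2 <- aggregate_scores(sc2)
  expect_true(all(agg2$sd == 0))
  expect_true(all(agg2$mean == 0.4))
})

test_that("signed-rank test matches exact enumeration and handles edge cases", {
  # n = 6, all positive differences: exact two-sided p = 2 / 2^6
  x <- c(2, 3, 4, 5, 6, 7); y <- c(1, 2, 3, 4, 5, 6)
  wt <- nmeseg:::wilcoxon_signed_rank(x, y)
  expect_equal(wt$p, 0.03125)
  # identical samples
  expect_warning(res <- nmeseg:::wilcoxon_signed_rank(x, x), "zero")
  expect_identical(res$p, 1)
  # exact enumeration oracle for small continuous samples
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(4:9, 1)
    d <- rnorm(n)
    while (anyDuplicated(abs(d)) > 0 || any(d == 0)) d <- rnorm(n)
    wt <- nmeseg:::wilcoxon_signed_rank(d, rep(0, n))
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wnull <- signs %*% r
    p_exact <- min(1, 2 * min(mean(Wnull <= W), mean(Wnull >= W)))
    expect_equal(wt$p, p_exact)
    # agreement with the reference implementation
    expect_equal(wt$p, stats::wilcox.test(d, exact = TRUE)$p.value)
  }
})

test_that("Holm adjustment is monotone and dominates the raw p-values", {
  raw <- c(0.01, 0.04, 0.03)
  # step-down formula computed directly
  o <- order(raw)
  stepdown <- cummax((length(raw) - seq_along(raw) + 1) * raw[o])
  want <- pmin(1, stepdown)[order(o)]
  expect_equal(p.adjust(raw, "holm"), want)
  sc <- do.call(rbind, lapply(c("a", "b", "c", "ref"), function(v) {
    set.seed(match(v, c("a", "b", "c", "ref")))
    data.frame(patient_id = sprintf("P%02d", 1:12), variant = v, fold = 1,
               label = "malignant", jaccard = runif(12),
               dice = runif(12), stringsAsFactors = FALSE)
  }))
  wh <- wilcoxon_holm(sc, reference = "ref")
  expect_true(all(wh$p_holm >= wh$p_raw))
  for (m in unique(wh$metric)) {
    sub <- wh[wh$metric == m, ]
    o <- order(sub$p_raw)
    expect_true(all(diff(sub$p_holm[o]) >= -1e-12))
  }
  expect_error(wilcoxon_holm(sc, reference = "missing"), "reference")
})
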