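test_that("confusion counts use an inclusive threshold", {
  cc <- confusion_at(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0), 0.5)
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  low <- confusion_at(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0), 0.1)
  expect_equal(low$fn + low$tn, 0L)
  high <- confusion_at(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0), 0.95)
  expect_equal(high$tp + high$fp, 0L)
  boundary <- confusion_at(c(0.5, 0.4), c(TRUE, TRUE), 0.5)
  expect_equal(boundary$tp, 1L)           # score == threshold counts positive
  expect_error(confusion_at(1:3, c(TRUE, FALSE), 0.5), "length")
})

test_that("rates implement TPR/FPR/PPV/FDR with undefined flags", {
  r <- rates(list(tp = 3, fn = 1, fp = 1, tn = 5))
  expect_equal(r$tpr, 0.75)
  expect_equal(r$fpr, 1 / 6)
  expect_equal(r$ppv, 0.75)
  expect_equal(r$fdr, 0.25)
  expect_equal(rates(list(tp = 2, fn = 2, fp = 0, tn = 4))$fpr, 0)
  expect_equal(rates(list(tp = 2, fn = 2, fp = 0, tn = 4))$fdr, 0)
  expect_true(is.na(rates(list(tp = 0, fn = 0, fp = 1, tn = 1))$tpr))
})

test_that("rate identities hold on enumerated confusion matrices", {
  for (tp in 0:3) for (fp in 0:3) for (tn in 0:3) for (fn in 0:3) {
    if (tp + fp + tn + fn == 0) next
    r <- rates(list(tp = tp, fp = fp, tn = tn, fn = fn))
    if (!is.na(r$ppv)) expect_equal(r$fdr, 1 - r$ppv)
    if (!is.na(r$tpr)) expect_true(r$tpr >= 0 && r$tpr <= 1)
    if (!is.na(r$fpr)) expect_true(r$fpr >= 0 && r$fpr <= 1)
  }
})

test_that("ROC curves behave at the extremes and on the worked example", {
  sep <- roc_curve(c(10, 9, 8, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
  expect_equal(sep$auc, 1.0)
  tie <- roc_curve(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(tie$auc, 0.5)
  ex <- roc_curve(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))
  expect_equal(ex$auc, 0.75)
  # endpoints present; curve monotone
  expect_equal(ex$fpr[1L], 0); expect_equal(ex$tpr[1L], 0)
  expect_equal(ex$fpr[length(ex$fpr)], 1)
  expect_equal(ex$tpr[length(ex$tpr)], 1)
  expect_false(is.unsorted(ex$tpr)); expect_false(is.unsorted(ex$fpr))
  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "both")
})

test_that("trapezoidal AUC equals the concordant-pair statistic (oracle, 100 instances)", {
  for (seed in 1:100) {
    n <- withr::with_seed(seed, sample(10:200, 1))
    withr::with_seed(seed * 7L, {
      scores <- round(runif(n), 2)          # rounding forces ties
      labels <- runif(n) < 0.4
    })
    if (length(unique(labels)) < 2L) labels[1:2] <- c(TRUE, FALSE)
    expect_equal(roc_curve(scores, labels)$auc,
                 brute_force_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC of negated scores complements the original", {
  withr::with_seed(9, {
    s <- runif(50); l <- runif(50) < 0.5
  })
  l[1:2] <- c(TRUE, FALSE)
  expect_equal(roc_curve(-s, l)$auc, 1 - roc_curve(s, l)$auc,
               tolerance = 1e-12)
})

test_that("AUC agrees with pROC on random instances (independent library check)", {
  skip_if_not_installed("pROC")
  for (seed in c(3, 17, 56)) {
    withr::with_seed(seed, {
      s <- runif(80); l <- runif(80) < 0.5
    })
    l[1:2] <- c(TRUE, FALSE)
    ref <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_curve(s, l)$auc, ref, tolerance = 1e-10)
  }
})

test_that("operating points use conservative step interpolation", {
  perfect <- roc_curve(c(10, 9, 1, 2), c(1, 1, 0, 0))
  expect_equal(tpr_at_fpr(perfect, 0.01), 1.0)
  ex <- roc_curve(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))
  expect_equal(tpr_at_fpr(ex, 0.5), 1.0)
  expect_equal(tpr_at_fpr(ex, 0.4), 0.5)
  tie <- roc_curve(rep(1, 4), c(1, 0, 1, 0))
  expect_equal(tpr_at_fpr(tie, 0), 0)      # only the origin sentinel qualifies
})

test_that("success rate counts DockQ >= threshold, monotone in threshold", {
  expect_equal(success_rate(c(0.5, 0.1, 0.23)), 2 / 3)
  expect_equal(success_rate(c(0.1, 0.2)), 0)
  planted <- c(rep(0.6, 856), rep(0.1, 1481 - 856))
  expect_equal(success_rate(planted), 856 / 1481)
  expect_equal(round(success_rate(planted), 3), 0.578)
  thr <- seq(0, 1, by = 0.05)
  sr <- sapply(thr, function(t) success_rate(planted, t))
  expect_false(is.unsorted(rev(sr)))
})

test_that("top-N coupling precision matches an exhaustive sort (oracle)", {
  # planted perfect and disjoint cases
  m <- matrix(0, 4, 4); m[1, 2] <- 5; m[3, 4] <- 4
  perfect <- dca_interface_ppv(m, rbind(c(1, 2), c(3, 4)))
  expect_equal(perfect$ppv, 1.0)
  disjoint <- dca_interface_ppv(m, rbind(c(2, 2), c(4, 4)))
  expect_equal(disjoint$ppv, 0.0)
  half <- dca_interface_ppv(m, rbind(c(1, 2), c(2, 2)))
  expect_equal(half$ppv, 0.5)

  for (seed in 1:30) {
    withr::with_seed(seed, {
      nr <- sample(3:20, 1); nc <- sample(3:20, 1)
      cm <- matrix(round(rnorm(nr * nc), 1), nr, nc)   # ties likely
      n_true <- sample(1:6, 1)
      truth <- unique(cbind(sample(nr, n_true, replace = TRUE),
                            sample(nc, n_true, replace = TRUE)))
    })
    res <- dca_interface_ppv(cm, truth)
    # oracle: full sort of all cells with the documented row-major tie rule
    cells <- data.frame(i = as.vector(row(cm)), j = as.vector(col(cm)),
                        s = as.vector(cm))
    cells <- cells[order(-cells$s, cells$i, cells$j), ]
    top <- cells[seq_len(nrow(truth)), ]
    expected <- sum(paste(top$i, top$j) %in% paste(truth[, 1], truth[, 2]))
    expect_equal(res$n_correct_in_top_n, expected)
    expect_equal(res$ppv, expected / nrow(truth))
    # invariant under strictly monotone transform of scores
    res2 <- dca_interface_ppv(exp(3 * cm), truth)
    expect_equal(res2$ppv, res$ppv)
  }
  expect_error(dca_interface_ppv(m, matrix(numeric(0), 0, 2)), "empty")
})

test_that("DSSP states collapse to helix/sheet/loop with structured tie-break", {
  expect_equal(interface_ss_class("HHHHGG"), "helix")
  expect_equal(interface_ss_class("EEBTTS"), "sheet")   # 3 sheet vs 3 loop
  expect_equal(interface_ss_class("TTSS--"), "loop")
  expect_equal(interface_ss_class(c("H", "E", "E")), "sheet")
  expect_equal(interface_ss_class("HHEE"), "helix")     # tie toward helix
  expect_error(interface_ss_class("HHXX"), "unknown")
  expect_error(interface_ss_class(""), "empty")
})

test_that("tertile split balances bins and flags degenerate input", {
  t1 <- tertile_split(1:9)
  expect_equal(t1$bins$low, 1:3)
  expect_equal(t1$bins$mid, 4:6)
  expect_equal(t1$bins$high, 7:9)
  t2 <- tertile_split(c(1, 1, 2, 3, 5, 8))
  expect_equal(lengths(t2$bins), c(low = 2L, mid = 2L, high = 2L))
  t3 <- tertile_split(rep(4, 10))
  expect_true(t3$degenerate)
  expect_equal(length(t3$bins$low), 10L)
  expect_error(tertile_split(c(1, 2)), "at least 3")
})
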